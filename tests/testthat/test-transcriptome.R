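make_es <- function(vals_n, vals_h) {
  vals <- cbind(vals_n, vals_h)
  colnames(vals) <- c(paste0("n", seq_len(ncol(vals_n))),
                      paste0("h", seq_len(ncol(vals_h))))
  expression_set(vals, rep(c("normoxia", "hypoxia"),
                           c(ncol(vals_n), ncol(vals_h))))
}

test_that("signed fold change follows the field's reporting convention", {
  expect_equal(signed_fc(1), 2)
  expect_equal(signed_fc(-1.321928094887362), -2.5, tolerance = 1e-12)
  expect_equal(signed_fc(0), 1)
  expect_true(all(abs(signed_fc(rnorm(100))) >= 1))
})

test_that("differential expression computes the documented statistics and flags", {
  set.seed(61)
  vals_n <- matrix(rnorm(30, 8, 0.1), 10, 3)
  vals_h <- matrix(rnorm(30, 8, 0.1), 10, 3)
  vals_h[1, ] <- vals_n[1, ] + 1      # 2-fold up
  vals_h[2, ] <- vals_n[2, ] - 1.321928094887362  # 2.5-fold down
  es <- make_es(vals_n, vals_h)
  de <- differential_expression(es)
  expect_equal(de$fc[1], signed_fc(de$log2_diff[1]))
  expect_gt(de$fc[1], 1.8)
  expect_lt(de$fc[2], -2)
  expect_true(de$pass_strict[1] && de$pass_strict[2])
  # pass_strict implies pass_relaxed
  expect_true(all(!de$pass_strict | de$pass_relaxed))
  # identical groups: FC = 1, direction none
  es_id <- make_es(vals_n, vals_n)
  de_id <- differential_expression(es_id)
  expect_equal(de_id$fc, rep(1, 10))
  expect_true(all(de_id$direction == "none"))
  expect_equal(de_id$p, rep(1, 10))  # t = 0 with nonzero within-group variance
  expect_true(all(!de_id$pass_strict & !de_id$pass_relaxed))
})

test_that("differential expression agrees with stats::t.test on sampled rows", {
  sim <- simulate_expression(expr_sim_config(n_probesets = 50, n_per_group = 4,
                                             seed = 62))
  de_pooled <- differential_expression(sim$es)
  de_welch <- differential_expression(sim$es, var_equal = FALSE)
  hy <- sim$es$groups == "hypoxia"
  for (i in c(1, 17, 50)) {
    ref_p <- t.test(sim$es$values[i, hy], sim$es$values[i, !hy],
                    var.equal = TRUE)
    expect_equal(de_pooled$p[i], ref_p$p.value, tolerance = 1e-12)
    ref_w <- t.test(sim$es$values[i, hy], sim$es$values[i, !hy])
    expect_equal(de_welch$p[i], ref_w$p.value, tolerance = 1e-12)
    expect_equal(de_welch$df[i], unname(ref_w$parameter), tolerance = 1e-9)
  }
})

test_that("spiked simulations are recovered and nulls stay calibrated", {
  cfg <- expr_sim_config(n_probesets = 2000, n_per_group = 3,
                         spike_fraction_up = 0.025, spike_fraction_down = 0.025,
                         spike_effect_log2 = 1.5, seed = 63)
  sim <- simulate_expression(cfg)
  de <- differential_expression(sim$es)
  spiked <- sim$truth$label != "null"
  expect_gte(mean(de$pass_strict[spiked]), 0.80)
  expect_lte(mean(de$p[!spiked] <= 0.05), 0.07)
  # direction of passing spikes matches truth
  up <- sim$truth$label == "up" & de$pass_strict
  expect_true(all(de$direction[up] == "up"))
})

test_that("DE counts match a brute-force filter loop and label swap flips FC", {
  sim <- simulate_expression(expr_sim_config(n_probesets = 300, seed = 64))
  de <- differential_expression(sim$es)
  cnt <- de_summary(de)
  brute_strict_up <- 0L; brute_strict_down <- 0L
  for (i in seq_len(nrow(de))) {
    if (!is.na(de$p[i]) && abs(de$fc[i]) >= 2 && de$p[i] <= 0.05) {
      if (de$log2_diff[i] > 0) brute_strict_up <- brute_strict_up + 1L
      else brute_strict_down <- brute_strict_down + 1L
    }
  }
  strict <- cnt[cnt$stringency == "strict" & cnt$level == "probeset", ]
  expect_identical(strict$up, brute_strict_up)
  expect_identical(strict$down, brute_strict_down)
  expect_identical(strict$total, strict$up + strict$down)
  # antisymmetry under group relabeling
  swapped <- expression_set(sim$es$values,
                            ifelse(sim$es$groups == "hypoxia", "normoxia",
                                   "hypoxia"))
  de_sw <- differential_expression(swapped)
  expect_equal(de_sw$log2_diff, -de$log2_diff, tolerance = 1e-12)
  expect_equal(de_sw$p, de$p, tolerance = 1e-12)
  big <- abs(de$fc) > 1
  expect_equal(de_sw$fc[big], -de$fc[big], tolerance = 1e-12)
})

test_that("panel report restricts to panel probesets and lists missing symbols", {
  sim <- simulate_expression(expr_sim_config(n_probesets = 20, seed = 65))
  de <- differential_expression(sim$es)
  ann <- data.frame(probeset = de$probeset[1:4],
                    symbol = c("ADM", "ADM", "VEGFA", "TF"),
                    family = "hypoxia_panel", stringsAsFactors = FALSE)
  rep1 <- panel_report(de, ann, c("ADM"))
  expect_equal(nrow(rep1$table), 2)
  expect_equal(rep1$missing, character(0))
  rep2 <- panel_report(de, ann, c("ADM", "EPO", "LEP"))
  expect_setequal(rep2$missing, c("EPO", "LEP"))
  expect_equal(nrow(rep2$table), 2)
  expect_error(panel_report(de, ann, character(0)), "at least one")
})

test_that("bundled hypoxia panel fixture is complete", {
  pan <- hypoxia_panel()
  expect_setequal(unique(pan$symbol),
                  c("ADM", "EPO", "HIGD2A", "HILPDA", "LEP", "NOS3",
                    "PDGFB", "TF", "VEGFA", "VEGFB", "VEGFC"))
  expect_equal(nrow(pan), 17)
})

test_that("family extraction matches a naive filter and z-scores are standardized", {
  cfg <- expr_sim_config(n_probesets = 200, n_per_group = 4,
                         spike_fraction_up = 0.3, spike_effect_log2 = 2,
                         seed = 66)
  sim <- simulate_expression(cfg)
  de <- differential_expression(sim$es)
  fam <- rep(c("interleukin", "other"), length.out = 200)
  ann <- data.frame(probeset = de$probeset, symbol = paste0("G", 1:200),
                    family = fam, stringsAsFactors = FALSE)
  ex <- family_extract(de, ann, "interleukin", "relaxed", sim$es)
  naive <- de$probeset[de$pass_relaxed & fam == "interleukin"]
  expect_setequal(ex$table$probeset, naive)
  if (nrow(ex$zscores) > 0) {
    expect_equal(unname(rowMeans(ex$zscores)), rep(0, nrow(ex$zscores)),
                 tolerance = 1e-9)
    expect_equal(unname(apply(ex$zscores, 1, sd)), rep(1, nrow(ex$zscores)),
                 tolerance = 1e-9)
  }
  # a tag with no members gives an empty export
  ex0 <- family_extract(de, ann, "chemokine", "relaxed", sim$es)
  expect_equal(nrow(ex0$table), 0)
  expect_equal(nrow(ex0$zscores), 0)
})

test_that("over-representation p-values match exact enumeration", {
  bg <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5), cold = paste0("g", 6:10))
  res <- ora(paste0("g", 1:5), bg, sets)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hit$overlap, 5)
  cold <- res[res$set == "cold", ]
  expect_equal(cold$p, 1, tolerance = 1e-12)  # overlap 0: tail covers all
  # EASE decrements the overlap
  expect_equal(hit$p_ease, oracle_hyper_tail(4, 10, 5, 5), tolerance = 1e-12)
  # randomized small tables against brute-force enumeration
  set.seed(67)
  for (i in 1:50) {
    N <- sample(10:30, 1)
    bg <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    de_sym <- sample(bg, n)
    sets <- list(s = sample(bg, K))
    r <- ora(de_sym, bg, sets)
    expect_equal(r$p, oracle_hyper_tail(r$overlap, N, K, n),
                 tolerance = 1e-12)
  }
  expect_error(ora("x", character(0), sets), "empty")
  expect_error(ora("absent", bg, sets), "background")
})

test_that("GMT round-trip through the standard parser", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  gs <- read_gmt(path)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, c("g2", "g4"))
})

test_that("PCA QC separates simulated groups and honours its contracts", {
  seps <- 0L
  for (seed in 1:20) {
    cfg <- expr_sim_config(n_probesets = 300, n_per_group = 4,
                           spike_fraction_up = 0.2, spike_fraction_down = 0.2,
                           spike_effect_log2 = 2, seed = seed)
    sim <- simulate_expression(cfg)
    qc <- pca_qc(sim$es)
    pc1 <- split(qc$scores$PC1, qc$scores$group)
    if (max(pc1$normoxia) < min(pc1$hypoxia) ||
        max(pc1$hypoxia) < min(pc1$normoxia)) seps <- seps + 1L
  }
  expect_gte(seps / 20, 0.95)
  # duplicated sample: identical scores
  sim <- simulate_expression(expr_sim_config(n_probesets = 100, seed = 70))
  vals <- sim$es$values
  vals[, 2] <- vals[, 1]
  es_dup <- expression_set(vals, sim$es$groups)
  qc <- pca_qc(es_dup)
  expect_equal(qc$scores$PC1[1], qc$scores$PC1[2], tolerance = 1e-9)
  expect_equal(qc$scores$PC2[1], qc$scores$PC2[2], tolerance = 1e-9)
  # centering contract: shifting one probeset row leaves scores unchanged
  vals2 <- sim$es$values
  vals2[5, ] <- vals2[5, ] + 100
  qc_ref <- pca_qc(sim$es)
  qc_shift <- pca_qc(expression_set(vals2, sim$es$groups))
  expect_equal(abs(qc_shift$scores$PC1), abs(qc_ref$scores$PC1),
               tolerance = 1e-9)
  expect_error(pca_qc(expression_set(matrix(5, 10, 4,
    dimnames = list(NULL, c("n1", "n2", "h1", "h2"))),
    rep(c("normoxia", "hypoxia"), each = 2))), "constant")
})

test_that("expression set construction validates groups and missing values", {
  vals <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_error(expression_set(vals, rep("normoxia", 4)), "2 samples")
  expect_error(expression_set(vals, c("a", "b", "a", "b")), "normoxia")
  vals[1, 1] <- NA
  expect_error(expression_set(vals, rep(c("normoxia", "hypoxia"), 2)),
               "missing")
})
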