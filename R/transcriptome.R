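#' Construct a two-group expression set
#'
#' @param values numeric matrix of log2 normalized intensities, probesets
#'   in rows, samples in columns (named).
#' @param groups character/factor mapping each sample (by name or
#'   position) to `"normoxia"` or `"hypoxia"`; at least 2 samples per
#'   group; no missing values allowed.
#' @return An `expression_set` list with `values` and `groups`.
#' @export
expression_set <- function(values, groups) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression matrix must not contain missing values")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("PS", seq_len(nrow(values)))
  groups <- stats::setNames(as.character(groups),
                            if (is.null(names(groups))) colnames(values)
                            else names(groups))
  if (!setequal(names(groups), colnames(values)))
    stop("group labels must cover exactly the sample names")
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("normoxia", "hypoxia")))
    stop("groups must be 'normoxia' or 'hypoxia'")
  if (any(table(factor(groups, c("normoxia", "hypoxia"))) < 2))
    stop("need at least 2 samples per group")
  structure(list(values = values, groups = groups), class = "expression_set")
}

#' Signed linear fold change from a log2 difference
#'
#' The field's reporting convention: a log2 difference `d >= 0` maps to
#' `2^d`, a negative one to `-2^(-d)`, so a 2.5-fold downregulation is
#' written -2.5 and `|FC| >= 1` always.
#'
#' @param d numeric vector of log2 differences.
#' @return Signed linear fold changes.
#' @export
signed_fc <- function(d) ifelse(d >= 0, 2^d, -(2^(-d)))

#' Per-probeset differential expression (hypoxia vs normoxia)
#'
#' For each probeset: mean log2 difference `d = mean(hypoxia) -
#' mean(normoxia)`, two-sided two-sample t-test p-value on the log2
#' values, the signed linear fold change, and the two stringency flags
#' used for reporting: strict `|FC| >= 2 & p <= 0.05` and relaxed
#' `|FC| > 1.2 & p <= 0.05`. The default statistic is the pooled
#' (Student) t, which is exactly calibrated at the small equal-n
#' designs typical of these experiments; `var_equal = FALSE` switches
#' to Welch, which is conservative below about n = 5 per group.
#' P-values are flagged unreliable when a group has zero variance with
#' fewer than 3 replicates; no multiple-testing correction is applied
#' by default (filtering is on raw p), but `adjust = TRUE` adds a
#' Benjamini-Hochberg column.
#'
#' @param es an [expression_set()].
#' @param adjust add a `p_adj` (BH) column.
#' @param var_equal use the pooled-variance t (default) rather than
#'   Welch.
#' @return Data frame with one row per probeset: `probeset`,
#'   `log2_diff`, `fc`, `t`, `df`, `p`, `p_unreliable`, `pass_strict`,
#'   `pass_relaxed`, `direction`.
#' @export
differential_expression <- function(es, adjust = FALSE, var_equal = TRUE) {
  stopifnot(inherits(es, "expression_set"))
  xh <- es$values[, es$groups == "hypoxia", drop = FALSE]
  xn <- es$values[, es$groups == "normoxia", drop = FALSE]
  nh <- ncol(xh); nn <- ncol(xn)
  mh <- rowMeans(xh); mn <- rowMeans(xn)
  vh <- rowSums((xh - mh)^2) / (nh - 1)
  vn <- rowSums((xn - mn)^2) / (nn - 1)
  d <- mh - mn
  if (var_equal) {
    sp2 <- ((nh - 1) * vh + (nn - 1) * vn) / (nh + nn - 2)
    se2 <- sp2 * (1 / nh + 1 / nn)
    df <- rep(nh + nn - 2, length(d))
  } else {
    se2 <- vh / nh + vn / nn
    df <- ifelse(se2 > 0,
                 se2^2 / ((vh / nh)^2 / (nh - 1) + (vn / nn)^2 / (nn - 1)),
                 NA_real_)
  }
  tt <- ifelse(se2 > 0, d / sqrt(se2), NA_real_)
  p <- 2 * stats::pt(-abs(tt), df)
  unreliable <- (vh == 0 & nh < 3) | (vn == 0 & nn < 3) | is.na(p)
  fc <- signed_fc(d)
  res <- data.frame(
    probeset = rownames(es$values), log2_diff = d, fc = fc, t = tt, df = df,
    p = p, p_unreliable = unreliable,
    pass_strict = !is.na(p) & abs(fc) >= 2 & p <= 0.05,
    pass_relaxed = !is.na(p) & abs(fc) > 1.2 & p <= 0.05,
    direction = ifelse(d > 0, "up", ifelse(d < 0, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Count differentially expressed probesets at both stringencies
#'
#' @param results a [differential_expression()] data frame.
#' @param annotation optional probeset -> gene symbol annotation (see
#'   [read_annotation()]); when given, counts of unique gene symbols are
#'   reported alongside probeset counts (a gene counts as up/down if any
#'   of its passing probesets is).
#' @return Data frame with columns `stringency`, `level`, `total`,
#'   `up`, `down`.
#' @export
de_summary <- function(results, annotation = NULL) {
  count_level <- function(pass, level, stringency) {
    sub <- results[pass, , drop = FALSE]
    if (level == "gene" && !is.null(annotation)) {
      sym <- annotation$symbol[match(sub$probeset, annotation$probeset)]
      up <- length(unique(sym[sub$direction == "up" & !is.na(sym)]))
      down <- length(unique(sym[sub$direction == "down" & !is.na(sym)]))
    } else {
      up <- sum(sub$direction == "up")
      down <- sum(sub$direction == "down")
    }
    data.frame(stringency = stringency, level = level, total = up + down,
               up = up, down = down, stringsAsFactors = FALSE)
  }
  out <- rbind(count_level(results$pass_strict, "probeset", "strict"),
               count_level(results$pass_relaxed, "probeset", "relaxed"))
  if (!is.null(annotation))
    out <- rbind(out,
                 count_level(results$pass_strict, "gene", "strict"),
                 count_level(results$pass_relaxed, "gene", "relaxed"))
  out
}

#' Read a probeset annotation table
#'
#' Tab-separated with columns `probeset`, `symbol` and optionally
#' `family` (one of `interleukin`, `chemokine`, `mmp_timp_adam`,
#' `hypoxia_panel`, `other`).
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("probeset", "symbol") %in% names(ann)))
    stop("annotation needs 'probeset' and 'symbol' columns")
  if (is.null(ann$family)) ann$family <- "other"
  ann
}

#' The bundled hypoxia-inducible reporting panel
#'
#' A published panel of hypoxia-inducible transcripts (adrenomedullin,
#' erythropoietin, HIG1-domain, lipid-droplet, leptin, eNOS, PDGF-B,
#' transferrin and VEGF family genes) shipped with the package, used to
#' confirm that a hypoxic response was induced.
#'
#' @return Data frame with `probeset` and `symbol` columns.
#' @export
hypoxia_panel <- function() {
  read_annotation(system.file("extdata", "hypoxia_panel.tsv",
                              package = "hypoflux", mustWork = TRUE))
}

#' Report fold changes for a gene panel
#'
#' Restricts differential-expression results to the probesets annotated
#' with the panel's gene symbols. Symbols with no annotated probeset are
#' reported in `missing`, never silently dropped.
#'
#' @param results a [differential_expression()] data frame.
#' @param annotation annotation data frame (`probeset`, `symbol`).
#' @param panel character vector of gene symbols (non-empty).
#' @return List with `table` (probeset, symbol, fc, p, flags) and
#'   `missing` (symbols absent from the annotation).
#' @export
panel_report <- function(results, annotation, panel) {
  if (length(panel) == 0) stop("panel must contain at least one symbol")
  missing <- setdiff(panel, annotation$symbol)
  ann <- annotation[annotation$symbol %in% panel, , drop = FALSE]
  idx <- match(ann$probeset, results$probeset)
  keep <- !is.na(idx)
  tab <- data.frame(probeset = ann$probeset[keep],
                    symbol = ann$symbol[keep],
                    fc = results$fc[idx[keep]], p = results$p[idx[keep]],
                    pass_strict = results$pass_strict[idx[keep]],
                    pass_relaxed = results$pass_relaxed[idx[keep]],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$symbol, tab$probeset), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, missing = missing)
}

#' Extract a gene family passing a stringency, with z-scored export
#'
#' Selects probesets carrying a family tag (e.g. `interleukin`,
#' `chemokine`, `mmp_timp_adam`) that pass the chosen stringency, and
#' z-scores each selected probeset's expression across samples for
#' heat-map rendering. An empty subset is allowed.
#'
#' @param results a [differential_expression()] data frame.
#' @param annotation annotation with a `family` column.
#' @param family family tag to extract.
#' @param stringency `"relaxed"` (default, `|FC| > 1.2 & p <= 0.05`) or
#'   `"strict"`.
#' @param es the [expression_set()] the results came from.
#' @return List with `table` (the passing subset of `results`) and
#'   `zscores` (probesets x samples matrix; rows have mean 0, SD 1).
#' @export
family_extract <- function(results, annotation, family,
                           stringency = c("relaxed", "strict"), es) {
  stringency <- match.arg(stringency)
  tagged <- annotation$probeset[annotation$family == family]
  pass <- if (stringency == "strict") results$pass_strict else
    results$pass_relaxed
  keep <- results$probeset[pass & results$probeset %in% tagged]
  tab <- results[results$probeset %in% keep, , drop = FALSE]
  rownames(tab) <- NULL
  z <- es$values[keep, , drop = FALSE]
  if (nrow(z) > 0) {
    mu <- rowMeans(z)
    s <- apply(z, 1, sd)
    z <- (z - mu) / s
  }
  list(table = tab, zscores = z)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Over-representation analysis (hypergeometric / EASE)
#'
#' For each gene set, tests whether the differentially expressed list
#' overlaps the set more than expected by chance against the array
#' background. `p` is the exact hypergeometric upper tail
#' `P(X >= k)` with `N` background genes, `K` set members in the
#' background, and `n` DE genes; `p_ease` is the conservative EASE
#' variant that decrements the observed overlap by one before taking the
#' tail.
#'
#' @param de_symbols differentially expressed gene symbols (must be a
#'   subset of the background).
#' @param background_symbols background (all assayed) gene symbols.
#' @param gene_sets named list of symbol vectors (see [read_gmt()]).
#' @return Data frame sorted by `p`: `set`, `overlap`, `set_size`,
#'   `de_size`, `background_size`, `p`, `p_ease`.
#' @export
ora <- function(de_symbols, background_symbols, gene_sets) {
  background_symbols <- unique(background_symbols)
  de_symbols <- unique(de_symbols)
  if (length(background_symbols) == 0) stop("background is empty")
  stray <- setdiff(de_symbols, background_symbols)
  if (length(stray) > 0)
    stop("DE symbols not in background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  bigN <- length(background_symbols)
  n <- length(de_symbols)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_symbols)
    k <- length(intersect(set, de_symbols))
    K <- length(set)
    p <- stats::phyper(k - 1, K, bigN - K, n, lower.tail = FALSE)
    ke <- max(k - 1, 0)
    p_ease <- stats::phyper(ke - 1, K, bigN - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, de_size = n,
               background_size = bigN, p = p, p_ease = p_ease,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PCA sample quality control
#'
#' Projects samples onto the first two principal components of the
#' probeset-centered matrix (via singular-value decomposition) to check
#' group separation and flag outlying samples. A sample is flagged when
#' its PC1-PC2 distance from its group centroid, standardized by the
#' pooled within-group axis SDs, exceeds `sd_threshold`.
#'
#' @param es an [expression_set()] (or a plain matrix plus `groups`).
#' @param groups optional group labels when `es` is a matrix.
#' @param sd_threshold outlier cutoff in pooled-SD units (default 3).
#' @return List with `scores` (sample, group, PC1, PC2),
#'   `var_explained` (length 2), and `outlier` (named logical).
#' @export
pca_qc <- function(es, groups = NULL, sd_threshold = 3) {
  if (inherits(es, "expression_set")) {
    x <- es$values; groups <- es$groups
  } else {
    x <- as.matrix(es)
    if (is.null(groups)) groups <- rep("all", ncol(x))
    groups <- stats::setNames(as.character(groups), colnames(x))
  }
  if (ncol(x) < 3) stop("PCA QC requires at least 3 samples")
  if (all(apply(x, 1, sd) == 0)) stop("matrix is constant; PCA undefined")
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  sc <- pr$x[, 1:2, drop = FALSE]
  scores <- data.frame(sample = colnames(x), group = unname(groups[colnames(x)]),
                       PC1 = sc[, 1], PC2 = if (ncol(sc) > 1) sc[, 2] else 0,
                       stringsAsFactors = FALSE, row.names = NULL)
  var_explained <- (pr$sdev^2 / sum(pr$sdev^2))[1:2]
  cent <- do.call(rbind, lapply(split(scores[, c("PC1", "PC2")], scores$group),
                                colMeans))
  dev1 <- scores$PC1 - cent[scores$group, "PC1"]
  dev2 <- scores$PC2 - cent[scores$group, "PC2"]
  s1 <- sqrt(mean(dev1^2)); s2 <- sqrt(mean(dev2^2))
  dstd <- sqrt((if (s1 > 0) (dev1 / s1)^2 else 0) +
               (if (s2 > 0) (dev2 / s2)^2 else 0))
  outlier <- stats::setNames(as.vector(dstd) > sd_threshold, scores$sample)
  list(scores = scores, var_explained = var_explained, outlier = outlier)
}

#' Write a matrix or table as TSV
#'
#' Convenience exporter for profile tables, DE results and z-scored
#' family matrices.
#'
#' @param x data frame or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(x, path) {
  if (is.matrix(x)) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = TRUE,
                col.names = NA)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
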