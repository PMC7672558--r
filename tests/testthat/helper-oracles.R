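# Independent oracles and fixture builders shared across tests.
# These re-derive results by a different route than the package code:
# naive per-formula arithmetic, exact combinatorial sums, and direct
# re-simulation.

# noise-free generator configuration (every stochastic knob off)
noise_free_config <- function(...) {
  flux_sim_config(well_cv = 0, cycle_noise_sd = 0, cell_count_sd = 0, ...)
}

# naive derived-metric oracle: recompute each metric one arithmetic
# step at a time from named per-phase values
oracle_profile <- function(ocr, ecar) {
  mr <- ocr[["glucose"]] - ocr[["rot_aa"]]
  pl <- ocr[["oligomycin"]] - ocr[["rot_aa"]]
  cr <- ocr[["glucose"]] - ocr[["oligomycin"]]
  src <- ocr[["fccp"]] - (ocr[["glucose"]] - ocr[["rot_aa"]])
  ng <- ecar[["pre_glucose"]]
  glyco <- ecar[["glucose"]] - ecar[["pre_glucose"]]
  cap <- ecar[["oligomycin"]] - ecar[["glucose"]]
  res <- ecar[["oligomycin"]] - (ecar[["glucose"]] - ecar[["pre_glucose"]])
  c(MR = mr, CR = cr, PL = pl, SRC = src, NG_ECAR = ng, GLYCO_ECAR = glyco,
    GLYCO_CAP = cap, GLYCO_RES = res,
    CR_pct_MR = 100 * cr / mr, PL_pct_MR = 100 * pl / mr,
    SRC_pct_MR = 100 * src / mr,
    ratio_PrG = ocr[["pre_glucose"]] / ecar[["pre_glucose"]],
    ratio_PsG = ocr[["glucose"]] / ecar[["glucose"]],
    ratio_FCCP = ocr[["fccp"]] / ecar[["fccp"]])
}

# exact hypergeometric upper tail by combinatorial enumeration of the
# overlap distribution (no phyper)
oracle_hyper_tail <- function(k, N, K, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# build a small hand-made plate for io/correction tests
make_plate <- function(condition = "hypoxia", ocr, ecar = NULL,
                       roles = NULL, fluor = NULL, cycles_per_phase = 1L,
                       groups = NULL) {
  nw <- nrow(ocr)
  if (is.null(ecar)) ecar <- matrix(1, nw, ncol(ocr))
  if (is.null(roles)) roles <- rep("sample", nw)
  if (is.null(fluor)) fluor <- rep(1000, nw)
  if (is.null(groups)) groups <- rep(condition, nw)
  wells <- data.frame(position = paste0("A", seq_len(nw)), role = roles,
                      group = groups, fluorescence = fluor,
                      stringsAsFactors = FALSE)
  plate_run("test_plate", condition, injection_schedule(cycles_per_phase),
            wells, ocr, ecar)
}

# a phase summary row from named phase vectors
make_summary <- function(ocr, ecar) {
  s <- as.data.frame(as.list(c(
    stats::setNames(ocr[FLUX_PHASES], paste0("ocr_", FLUX_PHASES)),
    stats::setNames(ecar[FLUX_PHASES], paste0("ecar_", FLUX_PHASES)))))
  class(s) <- c("phase_summary", "data.frame")
  s
}

# random phase summaries for property tests
random_summaries <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    make_summary(stats::setNames(runif(5, 0, 150), FLUX_PHASES),
                 stats::setNames(runif(5, 0.5, 30), FLUX_PHASES))
  })
}
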