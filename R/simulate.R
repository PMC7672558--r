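#' Default astrocyte-like phase-mean preset
#'
#' Per-condition true phase means (rate units) used by default in
#' [flux_sim_config()]. The constants are chosen so that the derived
#' metric contrasts between conditions have the directions and, where the
#' metric definitions allow, the approximate magnitudes observed in
#' hypoxic astrocyte cultures: mitochondrial respiration strongly reduced
#' (about -81%), coupled fraction falling from ~84% to ~67% of MR,
#' spare capacity from ~136% to ~92% of MR, glycolytic ECAR up ~38%,
#' glycolytic capacity down ~52%, and the OCR/ECAR ratio reduced in the
#' pre-glucose, glucose and FCCP phases. They are documented generator
#' constants, not measurements.
#'
#' @return List with `ocr` and `ecar`, each a condition -> phase -> mean
#'   nested list.
#' @export
flux_phase_preset <- function() {
  list(
    ocr = list(
      normoxia = c(pre_glucose = 55, glucose = 65, oligomycin = 14.42,
                   fccp = 141.3, rot_aa = 5),
      hypoxia = c(pre_glucose = 9.57, glucose = 18.2, oligomycin = 10.48,
                  fccp = 22.26, rot_aa = 6.62)),
    ecar = list(
      normoxia = c(pre_glucose = 4, glucose = 10, oligomycin = 18,
                   fccp = 16, rot_aa = 12),
      hypoxia = c(pre_glucose = 3.2, glucose = 11.48, oligomycin = 15.32,
                  fccp = 14, rot_aa = 10)))
}

check_phase_means <- function(pm, what) {
  for (cond in c("normoxia", "hypoxia")) {
    v <- pm[[cond]]
    if (is.null(v) || !setequal(names(v), FLUX_PHASES))
      stop(what, " means for ", cond, " must name exactly the phases {",
           paste(FLUX_PHASES, collapse = ", "), "}")
    if (any(v < 0)) stop(what, " means must be non-negative")
  }
  lapply(pm, function(v) v[FLUX_PHASES])
}

#' Configuration for the flux-plate generator
#'
#' @param wells_per_group sample wells per plate (default 9, a typical
#'   per-plate replicate count on a 24-well cartridge).
#' @param cycles_per_phase measurement cycles per injection phase
#'   (instrument convention 3).
#' @param phase_means_ocr,phase_means_ecar condition -> phase -> true
#'   mean rate; defaults from [flux_phase_preset()].
#' @param well_cv lognormal well-to-well coefficient of variation (sdlog
#'   of the multiplicative well level), in `[0, 1)`. Multiplicative
#'   because rates are positive and scale with seeded cell number.
#' @param cycle_noise_sd additive per-cycle measurement noise SD (rate
#'   units).
#' @param sulphite_wells,blank_wells numbers of sulphite reference and
#'   blank wells per plate.
#' @param sulphite_offset apparent OCR at zero respiration under low
#'   oxygen tension (the artifact the sulphite-referenced correction
#'   removes); added to every non-blank well of the hypoxia plate and
#'   read directly by sulphite wells.
#' @param cell_count_mean,cell_count_sd per-well DNA-fluorescence
#'   distribution (truncated at 0).
#' @param blank_fluor background fluorescence of blank wells.
#' @param seed integer RNG seed.
#' @return Validated `flux_sim_config` list.
#' @export
flux_sim_config <- function(wells_per_group = 9L, cycles_per_phase = 3L,
                            phase_means_ocr = flux_phase_preset()$ocr,
                            phase_means_ecar = flux_phase_preset()$ecar,
                            well_cv = 0.1, cycle_noise_sd = 0.5,
                            sulphite_wells = 2L, sulphite_offset = 5,
                            blank_wells = 1L,
                            cell_count_mean = 10000, cell_count_sd = 800,
                            blank_fluor = 500, seed = 1L) {
  if (wells_per_group < 1) stop("wells_per_group must be positive")
  if (cycles_per_phase < 1) stop("cycles_per_phase must be positive")
  if (well_cv < 0 || well_cv >= 1) stop("well_cv must lie in [0, 1)")
  if (cycle_noise_sd < 0) stop("cycle_noise_sd must be non-negative")
  if (sulphite_wells < 0 || blank_wells < 0)
    stop("well counts must be non-negative")
  if (sulphite_offset < 0) stop("sulphite_offset must be non-negative")
  if (cell_count_mean < 0 || cell_count_sd < 0)
    stop("cell count parameters must be non-negative")
  phase_means_ocr <- check_phase_means(phase_means_ocr, "OCR")
  phase_means_ecar <- check_phase_means(phase_means_ecar, "ECAR")
  structure(list(wells_per_group = as.integer(wells_per_group),
                 cycles_per_phase = as.integer(cycles_per_phase),
                 phase_means_ocr = phase_means_ocr,
                 phase_means_ecar = phase_means_ecar,
                 well_cv = well_cv, cycle_noise_sd = cycle_noise_sd,
                 sulphite_wells = as.integer(sulphite_wells),
                 sulphite_offset = sulphite_offset,
                 blank_wells = as.integer(blank_wells),
                 cell_count_mean = cell_count_mean,
                 cell_count_sd = cell_count_sd,
                 blank_fluor = blank_fluor, seed = as.integer(seed)),
            class = "flux_sim_config")
}

well_positions <- function(n) {
  rows <- rep(LETTERS[1:4], each = 6)
  cols <- rep(1:6, times = 4)
  paste0(rows, cols)[seq_len(n)]
}

simulate_one_plate <- function(cfg, condition, plate_id) {
  sched <- injection_schedule(cfg$cycles_per_phase)
  nc <- 5L * cfg$cycles_per_phase
  phase_of <- rep(FLUX_PHASES, each = cfg$cycles_per_phase)
  n_wells <- cfg$wells_per_group + cfg$sulphite_wells + cfg$blank_wells
  pos <- well_positions(n_wells)
  role <- c(rep("sample", cfg$wells_per_group),
            rep("sulphite_reference", cfg$sulphite_wells),
            rep("blank", cfg$blank_wells))
  artifact <- if (condition == "hypoxia") cfg$sulphite_offset else 0
  mu_o <- cfg$phase_means_ocr[[condition]][phase_of]
  mu_e <- cfg$phase_means_ecar[[condition]][phase_of]
  ocr <- matrix(0, n_wells, nc)
  ecar <- matrix(0, n_wells, nc)
  levels <- rep(NA_real_, n_wells)
  fluor <- rep(NA_real_, n_wells)
  for (w in seq_len(n_wells)) {
    if (role[w] == "sample") {
      lw <- if (cfg$well_cv > 0) rlnorm(1, 0, cfg$well_cv) else 1
      levels[w] <- lw
      ocr[w, ] <- mu_o * lw + artifact +
        rnorm(nc, 0, cfg$cycle_noise_sd)
      ecar[w, ] <- mu_e * lw + rnorm(nc, 0, cfg$cycle_noise_sd)
      fluor[w] <- max(0, rnorm(1, cfg$cell_count_mean, cfg$cell_count_sd))
    } else if (role[w] == "sulphite_reference") {
      # zero true respiration: apparent OCR is the low-tension artifact
      ocr[w, ] <- cfg$sulphite_offset + rnorm(nc, 0, cfg$cycle_noise_sd)
      ecar[w, ] <- rnorm(nc, 0, cfg$cycle_noise_sd)
      fluor[w] <- max(0, rnorm(1, cfg$cell_count_mean, cfg$cell_count_sd))
    } else {
      fluor[w] <- cfg$blank_fluor
    }
  }
  wells <- data.frame(position = pos, role = role, group = condition,
                      fluorescence = fluor, stringsAsFactors = FALSE)
  plate <- plate_run(plate_id, condition, sched, wells, ocr, ecar)
  list(plate = plate, levels = levels)
}

#' Simulate a paired normoxia/hypoxia flux-plate experiment
#'
#' Generates one plate per condition. Sample wells draw a multiplicative
#' well level `L_w ~ lognormal(0, well_cv)`; every cycle value is
#' `phase_mean * L_w + Normal(0, cycle_noise_sd)`. On the hypoxia plate
#' an apparent OCR offset (`sulphite_offset`) is added to all non-blank
#' wells, emulating the plate-wide low-oxygen-tension artifact that the
#' sulphite-referenced correction is designed to remove; sulphite
#' reference wells read that offset alone (they have no respiration),
#' and blank wells have exactly zero rates. Identical configurations
#' (including seed) reproduce bit-identical plates.
#'
#' @param config a [flux_sim_config()].
#' @return List with `normoxia` and `hypoxia` [plate_run()]s and
#'   `truth`: the true phase means, per-well levels, and the true
#'   per-condition derived-metric profiles implied by the phase means.
#' @export
simulate_flux_plates <- function(config) {
  stopifnot(inherits(config, "flux_sim_config"))
  set.seed(config$seed)
  norm <- simulate_one_plate(config, "normoxia",
                             sprintf("normoxia_s%d", config$seed))
  hyp <- simulate_one_plate(config, "hypoxia",
                            sprintf("hypoxia_s%d", config$seed))
  truth_profiles <- do.call(rbind, lapply(c("normoxia", "hypoxia"), function(cond) {
    s <- as.data.frame(as.list(c(
      stats::setNames(config$phase_means_ocr[[cond]],
                      paste0("ocr_", FLUX_PHASES)),
      stats::setNames(config$phase_means_ecar[[cond]],
                      paste0("ecar_", FLUX_PHASES)))))
    cbind(data.frame(condition = cond, stringsAsFactors = FALSE),
          bioenergetic_profile(s))
  }))
  list(normoxia = norm$plate, hypoxia = hyp$plate,
       truth = list(phase_means_ocr = config$phase_means_ocr,
                    phase_means_ecar = config$phase_means_ecar,
                    well_levels = list(normoxia = norm$levels,
                                       hypoxia = hyp$levels),
                    profiles = truth_profiles,
                    artifact = config$sulphite_offset))
}

#' Configuration for the expression-matrix generator
#'
#' @param n_probesets number of probesets.
#' @param n_per_group samples per condition (default 3; at least 2 so a
#'   variance is estimable).
#' @param baseline_log2,baseline_sd_log2 per-probeset baseline log2
#'   intensity distribution.
#' @param null_sd_log2 residual SD of log2 intensities.
#' @param spike_fraction_up,spike_fraction_down fractions of probesets
#'   shifted up/down in the hypoxia group (their sum must be < 1).
#' @param spike_effect_log2 absolute log2 shift of spiked probesets.
#' @param seed integer RNG seed.
#' @return Validated `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_probesets = 1000L, n_per_group = 3L,
                            baseline_log2 = 8, baseline_sd_log2 = 1.5,
                            null_sd_log2 = 0.35,
                            spike_fraction_up = 0.05,
                            spike_fraction_down = 0.05,
                            spike_effect_log2 = 1.5, seed = 1L) {
  if (n_probesets < 1) stop("n_probesets must be positive")
  if (n_per_group < 2) stop("n_per_group must be >= 2 (variance needed)")
  if (null_sd_log2 <= 0) stop("null_sd_log2 must be > 0")
  if (spike_fraction_up < 0 || spike_fraction_down < 0 ||
      spike_fraction_up + spike_fraction_down >= 1)
    stop("spike fractions must be non-negative and sum to < 1")
  if (spike_effect_log2 <= 0) stop("spike_effect_log2 must be > 0")
  structure(list(n_probesets = as.integer(n_probesets),
                 n_per_group = as.integer(n_per_group),
                 baseline_log2 = baseline_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 null_sd_log2 = null_sd_log2,
                 spike_fraction_up = spike_fraction_up,
                 spike_fraction_down = spike_fraction_down,
                 spike_effect_log2 = spike_effect_log2,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a two-group log2 expression matrix with spiked truth
#'
#' Null probesets are Normal around their baseline in both groups;
#' spiked probesets are shifted by `+/- spike_effect_log2` in the
#' hypoxia group. Spike positions are randomized over probesets.
#'
#' @param config an [expr_sim_config()].
#' @return List with `es` (an [expression_set()]) and `truth`: data
#'   frame of per-probeset labels (`up`/`down`/`null`), true log2
#'   effects and true signed linear fold changes.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  n <- config$n_probesets
  ids <- sprintf("PS%06d", seq_len(n))
  n_up <- round(config$spike_fraction_up * n)
  n_down <- round(config$spike_fraction_down * n)
  label <- rep("null", n)
  idx <- sample.int(n, n_up + n_down)
  label[idx[seq_len(n_up)]] <- "up"
  label[idx[seq_len(n_down) + n_up]] <- "down"
  effect <- ifelse(label == "up", config$spike_effect_log2,
                   ifelse(label == "down", -config$spike_effect_log2, 0))
  m <- config$n_per_group
  samples <- c(paste0("normoxia_", seq_len(m)), paste0("hypoxia_", seq_len(m)))
  groups <- stats::setNames(rep(c("normoxia", "hypoxia"), each = m), samples)
  baseline <- rnorm(n, config$baseline_log2, config$baseline_sd_log2)
  vals <- matrix(rnorm(n * 2 * m, 0, config$null_sd_log2), n, 2 * m,
                 dimnames = list(ids, samples))
  vals <- vals + baseline
  vals[, groups == "hypoxia"] <- vals[, groups == "hypoxia"] + effect
  truth <- data.frame(probeset = ids, label = label,
                      true_log2_effect = effect,
                      true_signed_fc = signed_fc(effect),
                      stringsAsFactors = FALSE)
  list(es = expression_set(vals, groups), truth = truth)
}

#' Simulate a paired qPCR Ct table
#'
#' Each pair contributes one normoxia and one hypoxia sample. The
#' housekeeping gene is stable across conditions; the target gene's Ct
#' is shifted by `-true_log2_effect` under hypoxia (one cycle fewer per
#' doubling of transcript). A pair-level Ct shift (`pair_sd`) induces
#' the within-pair correlation that motivates paired testing; it cancels
#' exactly in each pair's delta-delta-Ct.
#'
#' @param n_pairs number of pairs (>= 2).
#' @param true_log2_effect true hypoxia/normoxia log2 expression ratio.
#' @param ct_sd technical Ct noise SD (>= 0).
#' @param seed integer RNG seed.
#' @param target,housekeeping gene names (housekeeping one of the usual
#'   reference genes, e.g. `"ACTB"` or `"GAPDH"`).
#' @param target_ct,hk_ct baseline Ct of target and housekeeping gene.
#' @param pair_sd SD of the pair-level Ct shift.
#' @return Data frame of qPCR records: `sample_id`, `condition`,
#'   `pair_id`, `target`, `housekeeping`, `ct_target`,
#'   `ct_housekeeping`.
#' @export
simulate_qpcr <- function(n_pairs, true_log2_effect, ct_sd, seed = 1L,
                          target = "TARGET", housekeeping = "ACTB",
                          target_ct = 26, hk_ct = 18, pair_sd = 0.5) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (ct_sd < 0) stop("ct_sd must be non-negative")
  set.seed(as.integer(seed))
  rows <- list()
  for (p in seq_len(n_pairs)) {
    shift <- if (pair_sd > 0) rnorm(1, 0, pair_sd) else 0
    for (cond in c("normoxia", "hypoxia")) {
      eff <- if (cond == "hypoxia") -true_log2_effect else 0
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("pair%02d_%s", p, cond), condition = cond,
        pair_id = sprintf("pair%02d", p), target = target,
        housekeeping = housekeeping,
        ct_target = target_ct + shift + eff + rnorm(1, 0, ct_sd),
        ct_housekeeping = hk_ct + rnorm(1, 0, ct_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
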