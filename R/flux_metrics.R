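#' Aggregate a well's cycle series into per-phase values
#'
#' @param well a list with numeric `ocr` and `ecar` cycle vectors (e.g.
#'   one element of [well_traces()]).
#' @param schedule an [injection_schedule()] partitioning the cycles.
#' @param method `"mean"` (default) averages the cycles of each phase;
#'   `"last_cycle"` takes the final cycle of each phase (the reading
#'   closest to steady state after an injection).
#' @return A `phase_summary`: one-row data frame with columns
#'   `ocr_<phase>` and `ecar_<phase>` for the five phases.
#' @export
summarize_phases <- function(well, schedule, method = c("mean", "last_cycle")) {
  method <- match.arg(method)
  nc <- length(well$ocr)
  if (length(well$ecar) != nc) stop("ocr and ecar must have equal length")
  validate_schedule(schedule, nc)
  agg <- function(v, i0, i1) {
    idx <- (i0:i1) + 1L
    if (length(idx) < 1) stop("empty phase range")
    if (method == "mean") mean(v[idx]) else v[idx[length(idx)]]
  }
  out <- as.data.frame(as.list(c(
    stats::setNames(mapply(agg, list(well$ocr), schedule$start, schedule$end),
                    paste0("ocr_", schedule$phase)),
    stats::setNames(mapply(agg, list(well$ecar), schedule$start, schedule$end),
                    paste0("ecar_", schedule$phase)))))
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' Extract per-well traces from a plate
#'
#' @param plate a [plate_run()].
#' @param roles which well roles to keep (default: sample wells only).
#' @return A list of well traces, each a list with `position`, `role`,
#'   `group`, `ocr`, `ecar`, `fluorescence`.
#' @export
well_traces <- function(plate, roles = "sample") {
  keep <- which(plate$wells$role %in% roles)
  lapply(keep, function(i) list(position = plate$wells$position[i],
                                role = plate$wells$role[i],
                                group = plate$wells$group[i],
                                ocr = plate$ocr[i, ],
                                ecar = plate$ecar[i, ],
                                fluorescence = plate$wells$fluorescence[i]))
}

#' Derived bioenergetic metrics for one well
#'
#' Computes the mitochondrial stress-test and glycolysis metrics from a
#' per-phase summary:
#' \describe{
#'   \item{MR}{mitochondrial respiration, `OCR_glucose - OCR_rot_aa`
#'     (rotenone/antimycin-A-sensitive OCR in the presence of glucose).}
#'   \item{PL}{proton leak, `OCR_oligomycin - OCR_rot_aa`.}
#'   \item{CR}{coupled (ATP-linked) respiration. Default
#'     (`cr_method = "self_consistent"`): `MR - PL = OCR_glucose -
#'     OCR_oligomycin`, which makes CR and PL an exact partition of MR.
#'     `cr_method = "literal"` instead uses `MR - OCR_oligomycin`.}
#'   \item{SRC}{spare respiratory capacity, `OCR_fccp - MR`.}
#'   \item{NG_ECAR}{non-glycolytic acidification, `ECAR_pre_glucose`.}
#'   \item{GLYCO_ECAR}{glycolytic acidification,
#'     `ECAR_glucose - ECAR_pre_glucose`.}
#'   \item{GLYCO_CAP}{glycolytic capacity,
#'     `ECAR_oligomycin - ECAR_glucose`.}
#'   \item{GLYCO_RES}{glycolytic reserve,
#'     `ECAR_oligomycin - GLYCO_ECAR` (note this equals
#'     `GLYCO_CAP + NG_ECAR`, a wider definition than the common
#'     capacity-minus-glycolytic convention).}
#'   \item{CR_pct_MR, PL_pct_MR, SRC_pct_MR}{the respiratory components
#'     as percentages of MR; `NA` with `pct_undefined = TRUE` when
#'     `MR == 0`. Under the default `cr_method` the coupled/leak split
#'     is constructed so `CR_pct_MR + PL_pct_MR` is exactly 100.}
#'   \item{ratio_PrG, ratio_PsG, ratio_FCCP}{OCR/ECAR metabolic
#'     equilibrium ratios in the pre-glucose, glucose (post-glucose) and
#'     FCCP phases; `NA`-flagged when the phase ECAR is 0.}
#' }
#'
#' @param summary a [summarize_phases()] result.
#' @param cr_method `"self_consistent"` (default) or `"literal"`, see
#'   above.
#' @return One-row data frame with the metric columns and logical
#'   undefined flags.
#' @export
bioenergetic_profile <- function(summary,
                                 cr_method = c("self_consistent", "literal")) {
  cr_method <- match.arg(cr_method)
  s <- summary
  if (!all(is.finite(unlist(s[paste0("ocr_", FLUX_PHASES)])),
           is.finite(unlist(s[paste0("ecar_", FLUX_PHASES)]))))
    stop("phase summary contains non-finite values")
  # identities (MR = CR + PL, RES = CAP + NG, CR% + PL% = 100) are made
  # exact by construction, not left to floating-point cancellation
  pl <- s$ocr_oligomycin - s$ocr_rot_aa
  cr_sc <- s$ocr_glucose - s$ocr_oligomycin
  mr <- cr_sc + pl
  cr <- if (cr_method == "self_consistent") cr_sc else mr - s$ocr_oligomycin
  src <- s$ocr_fccp - mr
  ng <- s$ecar_pre_glucose
  glyco <- s$ecar_glucose - s$ecar_pre_glucose
  cap <- s$ecar_oligomycin - s$ecar_glucose
  res <- cap + ng
  pct_undefined <- mr == 0
  pct <- function(x) if (pct_undefined) NA_real_ else 100 * x / mr
  pl_pct <- if (pct_undefined) NA_real_ else if (cr_method == "self_consistent")
    100 - 100 * cr / mr else 100 * pl / mr
  ratio <- function(o, e) if (e == 0) NA_real_ else o / e
  data.frame(
    MR = mr, CR = cr, PL = pl, SRC = src,
    NG_ECAR = ng, GLYCO_ECAR = glyco, GLYCO_CAP = cap, GLYCO_RES = res,
    CR_pct_MR = pct(cr), PL_pct_MR = pl_pct, SRC_pct_MR = pct(src),
    ratio_PrG = ratio(s$ocr_pre_glucose, s$ecar_pre_glucose),
    ratio_PsG = ratio(s$ocr_glucose, s$ecar_glucose),
    ratio_FCCP = ratio(s$ocr_fccp, s$ecar_fccp),
    pct_undefined = pct_undefined,
    ratio_PrG_undefined = s$ecar_pre_glucose == 0,
    ratio_PsG_undefined = s$ecar_glucose == 0,
    ratio_FCCP_undefined = s$ecar_fccp == 0)
}

#' Per-well bioenergetic profile table for a set of plates
#'
#' Summarizes phases and derives the bioenergetic profile for every
#' sample well of each plate (sulphite reference and blank wells are
#' excluded). Plates are expected to have been corrected/normalized
#' already (see [correct_hypoxia_rates()], [normalize_to_cell_count()],
#' or the [flux_pipeline()] convenience wrapper).
#'
#' @param plates a list of [plate_run()] objects.
#' @param method cycle aggregation, see [summarize_phases()].
#' @param cr_method see [bioenergetic_profile()].
#' @return Data frame, one row per sample well, with `plate_id`, `well`,
#'   `condition` and the profile columns.
#' @export
group_profile_table <- function(plates, method = "mean",
                                cr_method = "self_consistent") {
  if (inherits(plates, "plate_run")) plates <- list(plates)
  ncs <- vapply(plates, n_cycles, integer(1))
  if (length(unique(ncs)) != 1)
    stop("plates have mixed cycle structure: ",
         paste(unique(ncs), collapse = " vs "))
  rows <- lapply(plates, function(p) {
    tr <- well_traces(p, roles = "sample")
    do.call(rbind, lapply(tr, function(w) {
      prof <- bioenergetic_profile(summarize_phases(w, p$schedule, method),
                                   cr_method = cr_method)
      cbind(data.frame(plate_id = p$plate_id, well = w$position,
                       condition = p$condition, stringsAsFactors = FALSE),
            prof)
    }))
  })
  do.call(rbind, rows)
}

#' Correct, normalize and profile flux plates in one call
#'
#' Applies the sulphite-referenced correction to hypoxia plates and the
#' cell-count normalization to all plates, then builds the per-well
#' profile table.
#'
#' @param plates list of [plate_run()] objects.
#' @param correct apply [correct_hypoxia_rates()] to hypoxia plates.
#' @param normalize apply [normalize_to_cell_count()] to all plates.
#' @inheritParams group_profile_table
#' @return See [group_profile_table()].
#' @export
flux_pipeline <- function(plates, correct = TRUE, normalize = TRUE,
                          method = "mean", cr_method = "self_consistent") {
  if (inherits(plates, "plate_run")) plates <- list(plates)
  plates <- lapply(plates, function(p) {
    if (correct && p$condition == "hypoxia") p <- correct_hypoxia_rates(p)
    if (normalize) p <- normalize_to_cell_count(p)
    p
  })
  group_profile_table(plates, method = method, cr_method = cr_method)
}
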