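#' @importFrom stats median rnorm rlnorm runif sd var
#' @importFrom utils read.csv write.table
NULL

#' Injection phases of the combined mitochondrial/glycolysis stress test
#'
#' The assay runs five phases in fixed order: baseline in glucose-free
#' medium, then sequential injection of glucose, oligomycin, FCCP and
#' rotenone/antimycin A.
#'
#' @format Character vector of the five phase names, in injection order.
#' @export
FLUX_PHASES <- c("pre_glucose", "glucose", "oligomycin", "fccp", "rot_aa")

WELL_ROLES <- c("sample", "sulphite_reference", "blank")

#' Build an injection schedule
#'
#' Maps each assay phase to a contiguous, non-overlapping range of
#' 0-based measurement-cycle indices. The five phases must appear in
#' injection order and their ranges must partition the cycle axis.
#'
#' @param cycles_per_phase integer, measurement cycles in each phase
#'   (instrument convention is 3).
#' @return An `injection_schedule`: data frame with columns `phase`,
#'   `start`, `end` (inclusive, 0-based).
#' @export
injection_schedule <- function(cycles_per_phase = 3L) {
  cycles_per_phase <- as.integer(cycles_per_phase)
  if (is.na(cycles_per_phase) || cycles_per_phase < 1L)
    stop("cycles_per_phase must be a positive integer")
  start <- (seq_along(FLUX_PHASES) - 1L) * cycles_per_phase
  sched <- data.frame(phase = FLUX_PHASES, start = start,
                      end = start + cycles_per_phase - 1L,
                      stringsAsFactors = FALSE)
  class(sched) <- c("injection_schedule", "data.frame")
  sched
}

validate_schedule <- function(schedule, n_cycles) {
  if (!identical(schedule$phase, FLUX_PHASES))
    stop("schedule phases must be exactly {",
         paste(FLUX_PHASES, collapse = ", "), "} in that order")
  idx <- unlist(Map(seq, schedule$start, schedule$end))
  if (!identical(as.integer(idx), seq_len(n_cycles) - 1L))
    stop("schedule ranges must partition cycles 0..", n_cycles - 1L,
         " contiguously and without overlap")
  invisible(schedule)
}

#' Construct a plate run
#'
#' Container for one assay plate: per-well OCR and ECAR cycle series,
#' well metadata (position, role, group, cell-count fluorescence), the
#' injection schedule and the plate condition.
#'
#' @param plate_id plate identifier.
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @param schedule an [injection_schedule()].
#' @param wells data frame with columns `position`, `role`
#'   (`sample`/`sulphite_reference`/`blank`), `group`, `fluorescence`.
#' @param ocr,ecar numeric matrices, one row per well (same order as
#'   `wells`), one column per measurement cycle. Units: pmol O2/min and
#'   mpH/min.
#' @return A `plate_run` object.
#' @export
plate_run <- function(plate_id, condition, schedule, wells, ocr, ecar) {
  condition <- match.arg(condition, c("normoxia", "hypoxia"))
  stopifnot(is.data.frame(wells),
            all(c("position", "role", "group", "fluorescence") %in% names(wells)))
  bad <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad) > 0)
    stop("unknown well role(s): ", paste(bad, collapse = ", "))
  ocr <- as.matrix(ocr); ecar <- as.matrix(ecar)
  if (nrow(ocr) != nrow(wells) || nrow(ecar) != nrow(wells))
    stop("ocr/ecar must have one row per well")
  if (ncol(ocr) != ncol(ecar))
    stop("ocr and ecar must have the same number of cycles")
  if (!any(wells$role == "sample"))
    stop("plate must contain at least one sample well")
  if (any(wells$fluorescence < 0))
    stop("fluorescence must be non-negative")
  validate_schedule(schedule, ncol(ocr))
  rownames(ocr) <- rownames(ecar) <- wells$position
  structure(list(plate_id = as.character(plate_id), condition = condition,
                 schedule = schedule, wells = wells, ocr = ocr, ecar = ecar),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat("plate_run", x$plate_id, sprintf("(%s)", x$condition), "\n")
  cat("  wells:", nrow(x$wells),
      sprintf("(%d sample, %d sulphite, %d blank)",
              sum(x$wells$role == "sample"),
              sum(x$wells$role == "sulphite_reference"),
              sum(x$wells$role == "blank")), "\n")
  cat("  cycles:", ncol(x$ocr), "over", nrow(x$schedule), "phases\n")
  invisible(x)
}

n_cycles <- function(plate) ncol(plate$ocr)

#' Write a plate run to the flux CSV dialect
#'
#' The dialect has two key-value header lines (`plate_id`, `condition`)
#' followed by a long-format table with one row per well and cycle:
#' `well,role,group,cycle,phase,ocr,ecar,fluorescence`.
#'
#' @param plate a [plate_run()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_run"))
  nc <- n_cycles(plate)
  cyc <- 0:(nc - 1)
  phase_of <- character(nc)
  for (i in seq_len(nrow(plate$schedule)))
    phase_of[(plate$schedule$start[i]:plate$schedule$end[i]) + 1L] <-
      plate$schedule$phase[i]
  rows <- do.call(rbind, lapply(seq_len(nrow(plate$wells)), function(w) {
    data.frame(well = plate$wells$position[w], role = plate$wells$role[w],
               group = plate$wells$group[w], cycle = cyc, phase = phase_of,
               ocr = plate$ocr[w, ], ecar = plate$ecar[w, ],
               fluorescence = plate$wells$fluorescence[w],
               stringsAsFactors = FALSE)
  }))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("plate_id,", plate$plate_id),
               paste0("condition,", plate$condition)), con)
  write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate run from the flux CSV dialect
#'
#' Accepts LF or CRLF line endings and optionally quoted fields. The
#' injection schedule is reconstructed from the `phase` column and
#' validated (contiguous, complete, identical across wells). Ragged
#' cycle counts, unknown roles, or inconsistent phase assignments are
#' rejected with the offending well named.
#'
#' @param path path to a file written in the dialect of [write_plate()].
#' @return A [plate_run()].
#' @export
read_plate <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4) stop("file too short for the flux CSV dialect")
  hdr <- lapply(lines[1:2], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  if (length(hdr[[1]]) < 2 || hdr[[1]][1] != "plate_id")
    stop("missing 'plate_id' header line")
  if (length(hdr[[2]]) < 2 || hdr[[2]][1] != "condition")
    stop("missing 'condition' header line")
  plate_id <- gsub('"', "", hdr[[1]][2])
  condition <- gsub('"', "", hdr[[2]][2])
  tab <- read.csv(text = paste(lines[-(1:2)], collapse = "\n"),
                  stringsAsFactors = FALSE)
  need <- c("well", "role", "group", "cycle", "phase", "ocr", "ecar",
            "fluorescence")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  wells_seen <- unique(tab$well)
  counts <- table(tab$well)
  nc <- max(tab$cycle) + 1L
  ragged <- names(counts)[counts != nc]
  if (length(ragged) > 0)
    stop("well(s) with inconsistent cycle count: ",
         paste(ragged, collapse = ", "))
  # schedule from first well's phase column
  first <- tab[tab$well == wells_seen[1], ]
  first <- first[order(first$cycle), ]
  rle_ph <- rle(first$phase)
  ends <- cumsum(rle_ph$lengths)
  sched <- data.frame(phase = rle_ph$values,
                      start = c(0L, ends[-length(ends)]),
                      end = ends - 1L, stringsAsFactors = FALSE)
  class(sched) <- c("injection_schedule", "data.frame")
  validate_schedule(sched, nc)
  ocr <- matrix(NA_real_, length(wells_seen), nc)
  ecar <- matrix(NA_real_, length(wells_seen), nc)
  meta <- data.frame(position = wells_seen, role = NA_character_,
                     group = NA_character_, fluorescence = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(wells_seen)) {
    wt <- tab[tab$well == wells_seen[i], ]
    wt <- wt[order(wt$cycle), ]
    if (!identical(as.integer(wt$cycle), 0:(nc - 1L)))
      stop("well ", wells_seen[i], ": cycles must be 0..", nc - 1L)
    if (!identical(wt$phase, first$phase))
      stop("well ", wells_seen[i], ": phase assignment differs from plate schedule")
    ocr[i, ] <- wt$ocr; ecar[i, ] <- wt$ecar
    meta$role[i] <- wt$role[1]; meta$group[i] <- wt$group[1]
    meta$fluorescence[i] <- wt$fluorescence[1]
  }
  plate_run(plate_id, condition, sched, meta, ocr, ecar)
}

#' Sulphite-referenced low-oxygen rate correction
#'
#' Under low ambient oxygen the instrument registers an apparent,
#' plate-wide oxygen-consumption offset. Wells injected with sodium
#' sulphite (a chemical oxygen scavenger) have zero true respiration, so
#' their apparent OCR measures that artifact. The correction subtracts,
#' at each cycle, the median OCR over the sulphite reference wells from
#' every non-blank well's OCR. ECAR is left untouched (sulphite scavenges
#' oxygen; it does not acidify the medium).
#'
#' @param plate a hypoxia-condition [plate_run()] containing at least one
#'   sulphite reference well.
#' @return The corrected `plate_run`.
#' @export
correct_hypoxia_rates <- function(plate) {
  stopifnot(inherits(plate, "plate_run"))
  if (plate$condition != "hypoxia")
    stop("sulphite-referenced correction applies to hypoxia plates only")
  sul <- plate$wells$role == "sulphite_reference"
  if (!any(sul))
    stop("hypoxia plate has no sulphite reference wells; cannot correct")
  subtrahend <- apply(plate$ocr[sul, , drop = FALSE], 2, median)
  nonblank <- plate$wells$role != "blank"
  plate$ocr[nonblank, ] <- sweep(plate$ocr[nonblank, , drop = FALSE], 2,
                                 subtrahend, "-")
  plate
}

#' Cell-number normalization of well rates
#'
#' Corrects rate differences driven by per-well cell number using a
#' DNA-binding fluorescence readout (CyQUANT-type assay). Background is
#' the mean fluorescence of blank wells (0 if none). Each sample well's
#' OCR and ECAR series is multiplied by `M / (F_w - background)`, where
#' `F_w` is the well's fluorescence and `M` the mean background-subtracted
#' fluorescence over the plate's sample wells, so rates stay in their
#' original units at the plate's average cell density.
#'
#' @param plate a [plate_run()]; every sample well must fluoresce above
#'   background.
#' @return The normalized `plate_run`.
#' @export
normalize_to_cell_count <- function(plate) {
  stopifnot(inherits(plate, "plate_run"))
  blank <- plate$wells$role == "blank"
  background <- if (any(blank)) mean(plate$wells$fluorescence[blank]) else 0
  smp <- plate$wells$role == "sample"
  f <- plate$wells$fluorescence[smp] - background
  if (any(f <= 0))
    stop("sample well(s) at or below background fluorescence: ",
         paste(plate$wells$position[smp][f <= 0], collapse = ", "))
  fac <- mean(f) / f
  plate$ocr[smp, ] <- plate$ocr[smp, , drop = FALSE] * fac
  plate$ecar[smp, ] <- plate$ecar[smp, , drop = FALSE] * fac
  plate
}
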