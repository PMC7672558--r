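#' Read a qPCR record table
#'
#' CSV with one row per sample and target: `sample_id`, `condition`
#' (`normoxia`/`hypoxia`), `pair_id`, `target`, `housekeeping`,
#' `ct_target`, `ct_housekeeping`.
#'
#' @param path CSV path.
#' @return Data frame of qPCR records.
#' @export
read_qpcr <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "pair_id", "target", "housekeeping",
            "ct_target", "ct_housekeeping")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("missing qPCR column(s): ", paste(miss, collapse = ", "))
  rec
}

validate_qpcr <- function(records) {
  if (length(unique(records$target)) != 1)
    stop("records must cover exactly one target gene; got: ",
         paste(unique(records$target), collapse = ", "))
  if (any(records$ct_target <= 0) || any(records$ct_housekeeping <= 0))
    stop("Ct values must be positive")
  split_rec <- split(records, records$pair_id)
  for (pid in names(split_rec)) {
    conds <- sort(split_rec[[pid]]$condition)
    if (!identical(conds, c("hypoxia", "normoxia")))
      stop("pair ", pid, " must have exactly one record per condition")
  }
  if (length(split_rec) < 2) stop("need at least 2 complete pairs")
  split_rec
}

#' Delta-delta-Ct relative quantification
#'
#' Per sample, the target Ct is normalized to the housekeeping gene
#' (`dCt = Ct_target - Ct_housekeeping`); per pair, the hypoxia dCt is
#' contrasted with the normoxia dCt (`ddCt = dCt_hypoxia -
#' dCt_normoxia`) and expressed as a relative quantity `RQ = 2^-ddCt`
#' (amplification efficiency fixed at 2, the standard assumption of the
#' method).
#'
#' @param records qPCR records for one target gene (see [read_qpcr()]
#'   or [simulate_qpcr()]); every pair must be complete.
#' @return A `ddct_result` list: `target`, `n_pairs`, `per_pair` (data
#'   frame with `pair_id`, `dct_normoxia`, `dct_hypoxia`, `ddct`, `rq`),
#'   and group summaries `mean_rq`, `sd_rq`, `mean_ddct`, `sd_ddct`.
#' @export
delta_delta_ct <- function(records) {
  split_rec <- validate_qpcr(records)
  per_pair <- do.call(rbind, lapply(names(split_rec), function(pid) {
    pr <- split_rec[[pid]]
    dct <- pr$ct_target - pr$ct_housekeeping
    names(dct) <- pr$condition
    ddct <- unname(dct["hypoxia"] - dct["normoxia"])
    data.frame(pair_id = pid, dct_normoxia = unname(dct["normoxia"]),
               dct_hypoxia = unname(dct["hypoxia"]), ddct = ddct,
               rq = 2^(-ddct), stringsAsFactors = FALSE)
  }))
  rownames(per_pair) <- NULL
  structure(list(target = records$target[1], n_pairs = nrow(per_pair),
                 per_pair = per_pair,
                 mean_rq = mean(per_pair$rq), sd_rq = sd(per_pair$rq),
                 mean_ddct = mean(per_pair$ddct),
                 sd_ddct = sd(per_pair$ddct)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt quantification of %s over %d pairs\n", x$target,
              x$n_pairs))
  cat(sprintf("  mean RQ = %.3f (SD %.3f); mean -ddCt = %.3f (SD %.3f)\n",
              x$mean_rq, x$sd_rq, -x$mean_ddct, x$sd_ddct))
  invisible(x)
}

#' Paired test of a ddCt quantification
#'
#' Student's paired t-test of the per-pair hypoxia dCt against the
#' normoxia dCt (equivalently, of ddCt against 0). Direction is the
#' sign of the mean recovered log2 effect `-ddCt`. With zero variance
#' of the pair differences the p-value is undefined and flagged, never
#' silently reported.
#'
#' @param x a `ddct_result` from [delta_delta_ct()], or a qPCR record
#'   table.
#' @return List with `statistic`, `df`, `p`, `p_defined`, `direction`
#'   (`up`/`down`/`none`) and `mean_log2_effect`.
#' @export
qpcr_test <- function(x) {
  if (!inherits(x, "ddct_result")) x <- delta_delta_ct(x)
  pp <- x$per_pair
  if (nrow(pp) < 2) stop("need at least 2 pairs")
  eff <- mean(-pp$ddct)
  direction <- if (eff > 0) "up" else if (eff < 0) "down" else "none"
  if (sd(pp$ddct) == 0) {
    return(list(statistic = NA_real_, df = nrow(pp) - 1L, p = NA_real_,
                p_defined = FALSE, direction = direction,
                mean_log2_effect = eff))
  }
  ht <- stats::t.test(pp$dct_hypoxia, pp$dct_normoxia, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), p_defined = TRUE, direction = direction,
       mean_log2_effect = eff)
}
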