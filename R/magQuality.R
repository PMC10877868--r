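#' Assign MIMAG-style quality tiers to MAGs
#'
#' Gating, with the strict/non-strict inequalities exactly as in the MIMAG
#' convention:
#' \itemize{
#'   \item HQ: completeness > 90, contamination < 5, 5S + 16S + 23S rRNA
#'     genes present, and >= 18 tRNAs;
#'   \item NEAR_COMPLETE: completeness > 90 and contamination < 5 but the
#'     rRNA/tRNA requirements unmet — genomically equivalent to HQ and
#'     commonly pooled with it downstream;
#'   \item MQ: completeness >= 50 and contamination < 10;
#'   \item LQ: everything else.
#' }
#' So completeness exactly 90 is at best MQ, completeness exactly 50 is
#' MQ, contamination exactly 5 blocks HQ/NEAR_COMPLETE and contamination
#' exactly 10 blocks MQ.
#'
#' @param mag_stats data.frame with columns `mag_id`, `completeness`
#'   (percent), `contamination` (percent), `rrna_5s`, `rrna_16s`,
#'   `rrna_23s` (logical), `trna_count` (integer); see [readMagStats()].
#' @return The input with a `tier` column added (factor levels HQ,
#'   NEAR_COMPLETE, MQ, LQ).
#' @export
#' @examples
#' assignQualityTier(data.frame(
#'   mag_id = "m1", completeness = 95, contamination = 2,
#'   rrna_5s = TRUE, rrna_16s = TRUE, rrna_23s = TRUE, trna_count = 20))
assignQualityTier <- function(mag_stats) {
  req <- c("mag_id", "completeness", "contamination", "rrna_5s", "rrna_16s",
           "rrna_23s", "trna_count")
  missing_cols <- setdiff(req, names(mag_stats))
  if (length(missing_cols) > 0) {
    stop("mag_stats missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  comp <- mag_stats$completeness
  cont <- mag_stats$contamination
  if (anyNA(comp) || any(comp < 0 | comp > 100)) {
    stop("completeness must lie in [0, 100]")
  }
  if (anyNA(cont) || any(cont < 0)) stop("contamination must be >= 0")
  if (any(mag_stats$trna_count > 100)) {
    warning("trna_count above 100 looks implausible")
  }
  rrna_all <- mag_stats$rrna_5s & mag_stats$rrna_16s & mag_stats$rrna_23s
  hq <- comp > 90 & cont < 5 & rrna_all & mag_stats$trna_count >= 18
  nc <- !hq & comp > 90 & cont < 5
  mq <- !hq & !nc & comp >= 50 & cont < 10
  tier <- ifelse(hq, "HQ", ifelse(nc, "NEAR_COMPLETE", ifelse(mq, "MQ", "LQ")))
  mag_stats$tier <- factor(tier, levels = c("HQ", "NEAR_COMPLETE", "MQ", "LQ"))
  mag_stats
}

#' Summarize MAG quality tiers
#'
#' Tier histogram plus the pooled "HQ or near-complete" count that
#' downstream analyses treat as high quality.
#'
#' @param mag_stats data.frame as for [assignQualityTier()]; a `tier`
#'   column is computed when absent.
#' @param pool_near_complete Also report `HQ_POOLED` = HQ +
#'   NEAR_COMPLETE (default TRUE).
#' @return Named integer vector of tier counts.
#' @export
summarizeTiers <- function(mag_stats, pool_near_complete = TRUE) {
  if (nrow(mag_stats) == 0) stop("empty MAG stats table")
  if (is.null(mag_stats$tier)) mag_stats <- assignQualityTier(mag_stats)
  counts <- table(factor(mag_stats$tier,
                         levels = c("HQ", "NEAR_COMPLETE", "MQ", "LQ")))
  out <- setNames(as.integer(counts), names(counts))
  if (pool_near_complete) {
    out <- c(out, HQ_POOLED = out[["HQ"]] + out[["NEAR_COMPLETE"]])
  }
  out
}
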