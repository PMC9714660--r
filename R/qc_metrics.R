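#' Valid sampling rate of one clip
#'
#' The fraction of raw sampling points in a clip where both pupils were
#' detected. Computed on the raw validity flags before any gap filling;
#' interpolated samples never count as valid.
#'
#' @param samples Gaze-sample tibble (raw, pre-gap-fill).
#' @param clip_id Clip to evaluate.
#' @return Fraction in `[0, 1]`.
#' @export
clip_valid_sampling_rate <- function(samples, clip_id) {
  s <- samples[samples$clip_id == clip_id, , drop = FALSE]
  if (nrow(s) == 0) stop("no samples for clip ", clip_id, call. = FALSE)
  mean(s$validL & s$validR & !s$interpolated)
}

#' Average valid sampling rate over the protocol's clips
#'
#' Unweighted mean of the per-clip rates by default; clips differ in
#' length (5-7 s), so a duration-weighted mean is available behind
#' `weights`.
#'
#' @param rates_by_clip Named numeric vector of per-clip rates.
#' @param weights Optional weights (e.g. clip durations); unweighted if
#'   `NULL`.
#' @return Fraction in `[0, 1]`.
#' @export
average_valid_sampling_rate <- function(rates_by_clip, weights = NULL) {
  if (length(rates_by_clip) == 0) stop("no per-clip rates", call. = FALSE)
  if (is.null(weights)) mean(rates_by_clip)
  else stats::weighted.mean(rates_by_clip, weights)
}

#' Per-participant QC result
#'
#' Computes the per-clip and average valid sampling rates for one
#' participant and applies the inclusion rule: included iff the average
#' rate is strictly above the threshold.
#'
#' @param samples Gaze-sample tibble for one participant (raw).
#' @param clip_ids Clips to evaluate (default: those present).
#' @param threshold Inclusion threshold on the average rate; the
#'   boundary value itself is excluded (strictly "above").
#' @return One-row tibble: `participant_id`, `avg_rate`, `included`,
#'   plus a list-column `rate_by_clip`.
#' @export
qc_participant <- function(samples, clip_ids = unique(samples$clip_id),
                           threshold = 0.60) {
  rates <- vapply(clip_ids, function(cl) clip_valid_sampling_rate(samples, cl),
                  numeric(1))
  names(rates) <- clip_ids
  avg <- average_valid_sampling_rate(rates)
  tibble::tibble(
    participant_id = samples$participant_id[1],
    avg_rate = avg,
    included = avg > threshold,
    rate_by_clip = list(rates)
  )
}

#' Partition participants by the QC inclusion rule
#'
#' @param qc_results Tibble of QC rows ([qc_participant()] output,
#'   row-bound).
#' @param threshold Strict lower bound on the average valid sampling
#'   rate (default 0.60).
#' @return List with tibbles `included` and `excluded`; the partition is
#'   exhaustive and disjoint.
#' @export
filter_participants <- function(qc_results, threshold = 0.60) {
  keep <- qc_results$avg_rate > threshold
  list(included = qc_results[keep, , drop = FALSE],
       excluded = qc_results[!keep, , drop = FALSE])
}
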