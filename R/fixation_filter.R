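#' I-VT fixation filter configuration
#'
#' Parameters of the velocity-threshold (I-VT) fixation classifier.
#' Defaults are the vendor-standard I-VT settings used with remote
#' eye trackers: 30 deg/s threshold, 20 ms velocity window, 75 ms
#' maximum gap fill, 60 ms minimum fixation duration, and merging of
#' adjacent fixations separated by at most 75 ms and 0.5 degrees.
#' No noise-reduction smoothing is applied.
#'
#' @param velocity_threshold_deg_s Velocity threshold in degrees/second.
#'   Samples with angular velocity strictly below it are fixation samples;
#'   at or above it, saccade samples.
#' @param velocity_window_ms Length of the symmetric velocity window (ms).
#' @param gap_fill_max_ms Longest run of invalid samples that is linearly
#'   interpolated (ms).
#' @param min_fixation_ms Candidate fixations shorter than this are
#'   discarded (ms).
#' @param merge_max_gap_ms,merge_max_angle_deg Adjacent fixation candidates
#'   closer than this in time and visual angle are merged.
#'
#' @return An `ivt_config` list.
#' @export
ivt_config <- function(velocity_threshold_deg_s = 30,
                       velocity_window_ms = 20,
                       gap_fill_max_ms = 75,
                       min_fixation_ms = 60,
                       merge_max_gap_ms = 75,
                       merge_max_angle_deg = 0.5) {
  vals <- c(velocity_threshold_deg_s, velocity_window_ms, gap_fill_max_ms,
            min_fixation_ms, merge_max_gap_ms, merge_max_angle_deg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ivt_config parameters must be strictly positive", call. = FALSE)
  }
  structure(
    list(
      velocity_threshold_deg_s = velocity_threshold_deg_s,
      velocity_window_ms = velocity_window_ms,
      gap_fill_max_ms = gap_fill_max_ms,
      min_fixation_ms = min_fixation_ms,
      merge_max_gap_ms = merge_max_gap_ms,
      merge_max_angle_deg = merge_max_angle_deg
    ),
    class = "ivt_config"
  )
}

#' Average the two eyes into a cyclopean gaze stream
#'
#' Each timestamp yields one `(x, y, valid)` triple: the mean of the two
#' eyes when both are valid, the single valid eye when only one is, and
#' an invalid sample otherwise. The original both-eyes-valid flag is kept
#' in `both_valid` because quality control is defined on raw binocular
#' pupil detection, never on averaged or interpolated data.
#'
#' @param samples A gaze-sample data frame with columns `t`, `clip_id`,
#'   `xL`, `yL`, `xR`, `yR`, `validL`, `validR` (see [read_gaze_table()]).
#'
#' @return A tibble with columns `clip_id`, `t`, `x`, `y`, `valid`,
#'   `both_valid`, `interpolated` (all `FALSE` here).
#' @export
combine_eyes <- function(samples) {
  vL <- samples$validL & is.finite(samples$xL) & is.finite(samples$yL)
  vR <- samples$validR & is.finite(samples$xR) & is.finite(samples$yR)
  x <- ifelse(vL & vR, (samples$xL + samples$xR) / 2,
              ifelse(vL, samples$xL, ifelse(vR, samples$xR, NA_real_)))
  y <- ifelse(vL & vR, (samples$yL + samples$yR) / 2,
              ifelse(vL, samples$yL, ifelse(vR, samples$yR, NA_real_)))
  tibble::tibble(
    clip_id = samples$clip_id,
    t = samples$t,
    x = x, y = y,
    valid = vL | vR,
    both_valid = samples$validL & samples$validR,
    interpolated = FALSE
  )
}

#' Linearly interpolate short tracking gaps
#'
#' Runs of invalid samples whose total duration is at most
#' `gap_fill_max_ms` and that are bounded by valid samples on both sides
#' are filled by straight-line interpolation in x and y and flagged
#' `interpolated = TRUE`. Longer gaps and gaps touching a clip edge are
#' left untouched. `both_valid` (the raw QC flag) is never altered, and
#' the operation is idempotent.
#'
#' @param stream A cyclopean stream from [combine_eyes()].
#' @param gap_fill_max_ms Maximum gap duration to fill (ms).
#'
#' @return The stream with fillable gaps interpolated.
#' @export
fill_gaps <- function(stream, gap_fill_max_ms = 75) {
  out <- dplyr::group_by(stream, .data$clip_id)
  out <- dplyr::group_modify(out, function(df, key) fill_gaps_clip(df, gap_fill_max_ms))
  dplyr::ungroup(out)
}

fill_gaps_clip <- function(df, gap_fill_max_ms) {
  n <- nrow(df)
  if (n == 0 || all(df$valid)) return(df)
  r <- rle(!df$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == n) next                       # edge gap
    # duration spanned by the invalid run, bounded by its valid neighbours
    if (df$t[i1 + 1] - df$t[i0 - 1] > gap_fill_max_ms) next
    idx <- i0:i1
    frac <- (df$t[idx] - df$t[i0 - 1]) / (df$t[i1 + 1] - df$t[i0 - 1])
    df$x[idx] <- df$x[i0 - 1] + frac * (df$x[i1 + 1] - df$x[i0 - 1])
    df$y[idx] <- df$y[i0 - 1] + frac * (df$y[i1 + 1] - df$y[i0 - 1])
    df$valid[idx] <- TRUE
    df$interpolated[idx] <- TRUE
  }
  df
}

#' Per-sample angular gaze velocity
#'
#' The velocity at sample i is the visual angle between the gaze
#' positions at the two edges of a symmetric window of length
#' `window_ms` centred on t_i, divided by the elapsed time between the
#' samples actually used. Window edges snap to the nearest recorded
#' sample; the velocity is undefined (`NA`) where either edge sample is
#' invalid or the window extends beyond the clip.
#'
#' @param stream A gap-filled cyclopean stream.
#' @param window_ms Velocity window length in ms.
#' @param geometry A [viewing_geometry()] object.
#'
#' @return The stream with a `velocity_deg_s` column (`NA` = undefined).
#' @export
angular_velocity <- function(stream, window_ms, geometry) {
  assert_geometry(geometry)
  out <- dplyr::group_by(stream, .data$clip_id)
  out <- dplyr::group_modify(out, function(df, key) {
    df$velocity_deg_s <- velocity_clip(df, window_ms, geometry)
    df
  })
  dplyr::ungroup(out)
}

velocity_clip <- function(df, window_ms, geometry) {
  n <- nrow(df)
  v <- rep(NA_real_, n)
  if (n < 2) return(v)
  h <- window_ms / 2
  # nearest sample index to each window edge
  lo <- nearest_index(df$t, df$t - h)
  hi <- nearest_index(df$t, df$t + h)
  ok <- df$t - h >= df$t[1] - 1e-9 & df$t + h <= df$t[n] + 1e-9 &
    lo < hi & df$valid & df$valid[lo] & df$valid[hi]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    ang <- visual_angle(cbind(df$x[lo[ok]], df$y[lo[ok]]),
                        cbind(df$x[hi[ok]], df$y[hi[ok]]), geometry)
    dt <- (df$t[hi[ok]] - df$t[lo[ok]]) / 1000
    v[ok] <- ang / dt
  }
  v
}

# nearest index in sorted vector t for each query q (ties -> lower)
nearest_index <- function(t, q) {
  i <- findInterval(q, t, all.inside = TRUE)
  use_hi <- (t[pmin(i + 1, length(t))] - q) < (q - t[i])
  ifelse(use_hi, pmin(i + 1, length(t)), i)
}

#' Classify samples as fixation or saccade by velocity threshold
#'
#' A sample is a fixation sample iff its velocity is defined and strictly
#' below the threshold; a saccade sample iff defined and at or above it;
#' undefined otherwise. The boundary velocity (exactly 30 deg/s at the
#' default) is a saccade.
#'
#' @param velocities Numeric vector of velocities (deg/s), `NA` = undefined.
#' @param threshold Velocity threshold in deg/s.
#'
#' @return Character vector of `"fixation"`, `"saccade"`, `"undefined"`.
#' @export
classify_ivt <- function(velocities, threshold = 30) {
  ifelse(is.na(velocities), "undefined",
         ifelse(velocities < threshold, "fixation", "saccade"))
}

#' Aggregate fixation-labelled samples into fixations
#'
#' Maximal runs of fixation-labelled samples become candidate fixations
#' with centroid at the mean member position. Adjacent candidates within
#' `merge_max_gap_ms` and `merge_max_angle_deg` of each other are merged,
#' then candidates shorter than `min_fixation_ms` are discarded.
#' Off-screen centroids are flagged but retained.
#'
#' @param stream A cyclopean stream with a `label` column (or pass
#'   `labels` separately).
#' @param labels Optional per-sample labels from [classify_ivt()].
#' @param config An [ivt_config()].
#' @param geometry A [viewing_geometry()] object (for the merge angle and
#'   the off-screen flag).
#'
#' @return A tibble of fixations: `clip_id`, `t_start_ms`, `t_end_ms`,
#'   `x`, `y`, `duration_ms`, `n_samples`, `off_screen`; sorted by onset
#'   within clip, pairwise disjoint intervals.
#' @export
aggregate_fixations <- function(stream, labels = stream$label,
                                config = ivt_config(), geometry = viewing_geometry()) {
  assert_geometry(geometry)
  stream$..label <- labels
  out <- dplyr::group_by(stream, .data$clip_id)
  out <- dplyr::group_modify(out, function(df, key) {
    aggregate_fixations_clip(df, config, geometry)
  })
  out <- dplyr::ungroup(out)
  dplyr::arrange(out, .data$clip_id, .data$t_start_ms)
}

aggregate_fixations_clip <- function(df, config, geometry) {
  empty <- tibble::tibble(
    t_start_ms = numeric(), t_end_ms = numeric(), x = numeric(), y = numeric(),
    duration_ms = numeric(), n_samples = integer(), off_screen = logical()
  )
  is_fix <- df$..label == "fixation"
  if (!any(is_fix)) return(empty)
  r <- rle(is_fix)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cand <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    list(t0 = df$t[starts[k]], t1 = df$t[ends[k]],
         sx = sum(df$x[idx]), sy = sum(df$y[idx]), n = length(idx))
  })
  # merge pass: adjacent candidates close in time and angle
  merged <- list(cand[[1]])
  if (length(cand) > 1) {
    for (k in 2:length(cand)) {
      last <- merged[[length(merged)]]
      cur <- cand[[k]]
      gap <- cur$t0 - last$t1
      ang <- visual_angle(c(last$sx / last$n, last$sy / last$n),
                          c(cur$sx / cur$n, cur$sy / cur$n), geometry)
      if (gap <= config$merge_max_gap_ms && ang <= config$merge_max_angle_deg) {
        merged[[length(merged)]] <- list(
          t0 = last$t0, t1 = cur$t1,
          sx = last$sx + cur$sx, sy = last$sy + cur$sy, n = last$n + cur$n
        )
      } else {
        merged[[length(merged) + 1]] <- cur
      }
    }
  }
  fx <- dplyr::bind_rows(lapply(merged, function(m) {
    tibble::tibble(
      t_start_ms = m$t0, t_end_ms = m$t1,
      x = m$sx / m$n, y = m$sy / m$n,
      duration_ms = m$t1 - m$t0, n_samples = as.integer(m$n)
    )
  }))
  fx <- fx[fx$duration_ms >= config$min_fixation_ms, , drop = FALSE]
  if (nrow(fx) == 0) return(empty)
  fx$off_screen <- fx$x < 0 | fx$x > geometry$screen_w_px |
    fx$y < 0 | fx$y > geometry$screen_h_px
  fx
}

#' Run the full I-VT pipeline on a gaze recording
#'
#' Convenience wrapper: binocular averaging, gap filling, angular
#' velocity, threshold classification and fixation aggregation.
#'
#' @param samples A gaze-sample data frame (see [read_gaze_table()]).
#' @param config An [ivt_config()].
#' @param geometry A [viewing_geometry()] object.
#'
#' @return A tibble of fixations (see [aggregate_fixations()]).
#' @export
detect_fixations <- function(samples, config = ivt_config(),
                             geometry = viewing_geometry()) {
  stream <- combine_eyes(samples)
  stream <- fill_gaps(stream, config$gap_fill_max_ms)
  stream <- angular_velocity(stream, config$velocity_window_ms, geometry)
  stream$label <- classify_ivt(stream$velocity_deg_s, config$velocity_threshold_deg_s)
  aggregate_fixations(stream, stream$label, config, geometry)
}
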