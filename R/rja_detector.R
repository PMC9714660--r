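#' Detector configuration
#'
#' Tunable parameters of the RJA event detector.
#'
#' @param radius_multiplier Dimensionless factor applied to the face and
#'   target AOI radii when testing whether a fixation starts at the face
#'   or ends at the target; default 1.2.
#' @param max_angle_deg Maximum intersection angle (strict) between each
#'   fixation-to-fixation vector and the face-to-target benchmark
#'   vector; default 90.
#' @param window_policy How fixations are assigned to the actor's action
#'   window: `"onset"` (fixation onset inside the closed window; default)
#'   or `"overlap"` (any temporal overlap).
#' @param termination `"earliest"` closes an event at the first fixation
#'   reaching the target criterion (default); `"maximal"` keeps
#'   extending while all criteria continue to hold and closes at the
#'   last fixation that still satisfies the target criterion.
#'
#' @return A `detector_config` list.
#' @export
detector_config <- function(radius_multiplier = 1.2, max_angle_deg = 90,
                            window_policy = c("onset", "overlap"),
                            termination = c("earliest", "maximal")) {
  if (!is.finite(radius_multiplier) || radius_multiplier <= 0) {
    stop("radius_multiplier must be > 0", call. = FALSE)
  }
  if (!is.finite(max_angle_deg) || max_angle_deg <= 0 || max_angle_deg > 180) {
    stop("max_angle_deg must be in (0, 180]", call. = FALSE)
  }
  structure(
    list(radius_multiplier = radius_multiplier,
         max_angle_deg = max_angle_deg,
         window_policy = match.arg(window_policy),
         termination = match.arg(termination)),
    class = "detector_config"
  )
}

#' Fixations inside a clip's action window
#'
#' Restricts a clip's fixation list to the actor's cueing interval.
#' Under the default onset policy a fixation belongs to the window iff
#' its onset lies in the closed interval
#' `[action_start_ms, action_end_ms]`; under the overlap policy, iff it
#' overlaps the window at all.
#'
#' @param fixations Fixation tibble for one clip (from
#'   [detect_fixations()]).
#' @param clip One row of a clip-spec tibble (or a list with
#'   `action_start_ms`, `action_end_ms`).
#' @param policy `"onset"` or `"overlap"`.
#' @return The windowed subset, order preserved.
#' @export
fixations_in_window <- function(fixations, clip, policy = c("onset", "overlap")) {
  policy <- match.arg(policy)
  if (policy == "onset") {
    keep <- fixations$t_start_ms >= clip$action_start_ms &
      fixations$t_start_ms <= clip$action_end_ms
  } else {
    keep <- fixations$t_end_ms >= clip$action_start_ms &
      fixations$t_start_ms <= clip$action_end_ms
  }
  fixations[keep, , drop = FALSE]
}

dist_to <- function(fx, point) {
  sqrt((fx$x - point[1])^2 + (fx$y - point[2])^2)
}

#' Test whether a fixation subsequence is an RJA event
#'
#' A contiguous sequence of two or more windowed fixations is an RJA
#' event iff all four criteria hold (all comparisons strict):
#' (1) the first fixation lies within `m * R_F` of the face centre F;
#' (2) the last fixation lies within `m * R_T` of the target centre T;
#' (3) every fixation except the first is closer to the target centre T
#' than to the non-target centre N;
#' (4) every consecutive-fixation vector makes an angle below
#' `max_angle_deg` with the F -> T benchmark vector.
#'
#' @param fix_subseq Tibble of >= 2 consecutive fixations (columns `x`,
#'   `y`).
#' @param aoi_geom An [aoi_geometry()] object.
#' @param config A [detector_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_rja_sequence <- function(fix_subseq, aoi_geom, config = detector_config()) {
  n <- nrow(fix_subseq)
  if (n < 2) stop("an RJA sequence needs at least 2 fixations", call. = FALSE)
  m <- config$radius_multiplier
  if (!(dist_to(fix_subseq[1, ], aoi_geom$F) < m * aoi_geom$R_F)) return(FALSE)
  if (!(dist_to(fix_subseq[n, ], aoi_geom$T) < m * aoi_geom$R_T)) return(FALSE)
  rest <- fix_subseq[-1, , drop = FALSE]
  if (!all(dist_to(rest, aoi_geom$T) < dist_to(rest, aoi_geom$N))) return(FALSE)
  vx <- diff(fix_subseq$x)
  vy <- diff(fix_subseq$y)
  all(vector_angle(cbind(vx, vy), aoi_geom$benchmark) < config$max_angle_deg)
}

#' Detect RJA events in one clip's windowed fixations
#'
#' Deterministic left-to-right scan. A candidate opens at each fixation
#' satisfying the face criterion; it is extended fixation by fixation
#' while the target-closer-than-non-target and forward-angle criteria
#' hold for each addition, and closes as an event at the first extension
#' that also satisfies the target criterion (earliest termination). On
#' emission the scan resumes after the event, so events never share
#' fixations; on any criterion failure the candidate is abandoned and
#' the scan resumes at the next fixation. The result equals brute-force
#' enumeration of all contiguous subsequences passing
#' [is_rja_sequence()], reduced by the same earliest-start /
#' earliest-end / non-overlap rule.
#'
#' @param fixations Windowed fixations for one clip, in temporal order.
#' @param clip The clip-spec row (for `clip_id`; windowing is applied if
#'   the fixations are not pre-windowed — pass `window = FALSE` to skip).
#' @param aoi_geom An [aoi_geometry()] object.
#' @param config A [detector_config()].
#' @param participant_id Carried into the result.
#' @param window Apply [fixations_in_window()] first (default `TRUE`).
#' @return A tibble of events: `participant_id`, `clip_id`,
#'   `fixation_index_start`, `fixation_index_end` (1-based, inclusive,
#'   into the windowed fixation list), `t_start_ms`, `t_end_ms`,
#'   `n_fixations`.
#' @export
detect_rja_events <- function(fixations, clip, aoi_geom,
                              config = detector_config(),
                              participant_id = NA_character_,
                              window = TRUE) {
  if (window) {
    fixations <- fixations_in_window(fixations, clip, config$window_policy)
  }
  empty <- tibble::tibble(
    participant_id = character(), clip_id = character(),
    fixation_index_start = integer(), fixation_index_end = integer(),
    t_start_ms = numeric(), t_end_ms = numeric(), n_fixations = integer()
  )
  n <- nrow(fixations)
  if (n < 2) return(empty)
  m <- config$radius_multiplier
  d_F <- dist_to(fixations, aoi_geom$F)
  d_T <- dist_to(fixations, aoi_geom$T)
  d_N <- dist_to(fixations, aoi_geom$N)
  ang <- c(NA_real_,
           vector_angle(cbind(diff(fixations$x), diff(fixations$y)),
                        aoi_geom$benchmark))
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i < n) {
    if (d_F[i] < m * aoi_geom$R_F) {
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        # extension criteria for fixation j: closer to T than N, forward vector
        if (!(d_T[j] < d_N[j] && ang[j] < config$max_angle_deg)) break
        if (d_T[j] < m * aoi_geom$R_T) {
          if (config$termination == "earliest") {
            starts <- c(starts, i); ends <- c(ends, j)
            closed <- TRUE
            break
          }
          # maximal: remember the latest valid close, keep extending
          closed <- TRUE
          last_close <- j
        }
        j <- j + 1L
      }
      if (closed && config$termination == "maximal") {
        starts <- c(starts, i); ends <- c(ends, last_close)
        i <- last_close + 1L
        next
      }
      if (closed) {
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(starts) == 0) return(empty)
  tibble::tibble(
    participant_id = participant_id,
    clip_id = if (is.null(clip$clip_id)) NA_character_ else clip$clip_id,
    fixation_index_start = starts,
    fixation_index_end = ends,
    t_start_ms = fixations$t_start_ms[starts],
    t_end_ms = fixations$t_end_ms[ends],
    n_fixations = ends - starts + 1L
  )
}

#' Detect RJA events across all clips of a session
#'
#' Runs windowing and detection per clip and row-binds the events.
#'
#' @param fixations Fixation tibble with a `clip_id` column.
#' @param clips Clip-spec tibble.
#' @param aoi_map Named list of [aoi_geometry()] objects (or AOI sets,
#'   converted on the fly) keyed by `clip_id`.
#' @param config A [detector_config()].
#' @param participant_id Carried into the result.
#' @return Event tibble (see [detect_rja_events()]).
#' @export
detect_session_events <- function(fixations, clips, aoi_map,
                                  config = detector_config(),
                                  participant_id = NA_character_) {
  per_clip <- lapply(seq_len(nrow(clips)), function(k) {
    clip <- clips[k, ]
    geom <- aoi_map[[clip$clip_id]]
    if (is.null(geom)) stop("no AOI set for clip ", clip$clip_id, call. = FALSE)
    if (!inherits(geom, "aoi_geometry")) geom <- aoi_geometry(geom)
    fx <- fixations[fixations$clip_id == clip$clip_id, , drop = FALSE]
    detect_rja_events(fx, clip, geom, config, participant_id)
  })
  dplyr::bind_rows(per_clip)
}

#' Summarize a participant's detected events
#'
#' Collapses a participant's events into the feature vector used
#' downstream: average valid sampling rate, event counts split by
#' stimulus type, and a per-clip any-event flag. Multiple events in one
#' clip are each counted in the totals.
#'
#' @param events Event tibble for one participant.
#' @param clips Clip-spec tibble (provides stimulus types; an event in a
#'   clip absent from `clips` is an error).
#' @param qc A QC result row for the participant (from
#'   [qc_participant()]), or `NULL` to omit the rate.
#' @param participant_id,group Metadata (taken from `events`/`qc` when
#'   available).
#' @return A one-row tibble: `participant_id`, `group`,
#'   `avg_valid_sampling_rate`, `n_events_total`, `n_events_looking`,
#'   `n_events_pointing`, plus a list-column `has_event_by_clip` (named
#'   logical over all clips).
#' @export
summarize_participant <- function(events, clips, qc = NULL,
                                  participant_id = NULL, group = NA_character_) {
  if (is.null(participant_id)) {
    participant_id <- if (nrow(events) > 0) events$participant_id[1] else
      if (!is.null(qc)) qc$participant_id[1] else NA_character_
  }
  unknown <- setdiff(unique(events$clip_id), clips$clip_id)
  if (length(unknown) > 0) {
    stop("event references unknown clip(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  type_of <- stats::setNames(clips$stimulus_type, clips$clip_id)
  ev_types <- type_of[events$clip_id]
  flags <- stats::setNames(clips$clip_id %in% events$clip_id, clips$clip_id)
  tibble::tibble(
    participant_id = participant_id,
    group = group,
    avg_valid_sampling_rate = if (!is.null(qc)) qc$avg_rate[1] else NA_real_,
    n_events_total = nrow(events),
    n_events_looking = sum(ev_types == "looking"),
    n_events_pointing = sum(ev_types == "pointing"),
    has_event_by_clip = list(flags)
  )
}
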