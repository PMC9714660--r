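#' Column dialect of a gaze-sample export
#'
#' Gaze exports differ in header naming and validity coding across
#' acquisition software versions. A dialect maps the logical fields the
#' package needs onto the file's column names and states which integer
#' codes mean "pupil detected". Defaults follow the Tobii-Studio-style
#' table export.
#'
#' @param col_t,col_clip,col_xL,col_yL,col_xR,col_yR,col_validL,col_validR
#'   Column names in the file.
#' @param valid_codes Integer codes counted as a validly detected pupil.
#'
#' @return A `gaze_dialect` list.
#' @export
gaze_dialect <- function(col_t = "RecordingTimestamp",
                         col_clip = "MediaName",
                         col_xL = "GazePointLeftX",
                         col_yL = "GazePointLeftY",
                         col_xR = "GazePointRightX",
                         col_yR = "GazePointRightY",
                         col_validL = "ValidityLeft",
                         col_validR = "ValidityRight",
                         valid_codes = 0L) {
  structure(
    list(col_t = col_t, col_clip = col_clip,
         col_xL = col_xL, col_yL = col_yL, col_xR = col_xR, col_yR = col_yR,
         col_validL = col_validL, col_validR = col_validR,
         valid_codes = as.integer(valid_codes)),
    class = "gaze_dialect"
  )
}

#' Read a gaze-sample table
#'
#' Reads a tab-separated gaze export into a tidy sample table. Samples
#' are ordered by time within each clip; unparseable or blank coordinate
#' cells make the corresponding eye invalid rather than failing the read.
#' Timestamps that are not strictly increasing within a clip are a data
#' error.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect A [gaze_dialect()] naming the columns.
#' @param participant_id,group Metadata attached as columns.
#'
#' @return A tibble with columns `participant_id`, `group`, `clip_id`,
#'   `t` (ms), `xL`, `yL`, `xR`, `yR`, `validL`, `validR`,
#'   `interpolated` (always `FALSE` on read). The number of coordinate
#'   cells coerced to invalid is recorded in attribute `n_coerced`.
#' @export
read_gaze_table <- function(path, dialect = gaze_dialect(),
                            participant_id = NA_character_,
                            group = NA_character_) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  need <- c(dialect$col_t, dialect$col_clip, dialect$col_xL, dialect$col_yL,
            dialect$col_xR, dialect$col_yR, dialect$col_validL, dialect$col_validR)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("gaze table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  t <- num(dialect$col_t)
  if (any(is.na(t)) || any(t < 0)) {
    stop("unparseable or negative timestamps in ", path, call. = FALSE)
  }
  xL <- num(dialect$col_xL); yL <- num(dialect$col_yL)
  xR <- num(dialect$col_xR); yR <- num(dialect$col_yR)
  vL <- suppressWarnings(as.integer(raw[[dialect$col_validL]])) %in% dialect$valid_codes
  vR <- suppressWarnings(as.integer(raw[[dialect$col_validR]])) %in% dialect$valid_codes
  # an eye whose coordinates did not parse carries no usable gaze point
  coercedL <- vL & (is.na(xL) | is.na(yL))
  coercedR <- vR & (is.na(xR) | is.na(yR))
  vL[coercedL] <- FALSE
  vR[coercedR] <- FALSE
  out <- tibble::tibble(
    participant_id = participant_id, group = group,
    clip_id = raw[[dialect$col_clip]], t = t,
    xL = xL, yL = yL, xR = xR, yR = yR,
    validL = vL, validR = vR, interpolated = FALSE
  )
  # monotonicity is judged in file order within each clip, so interleaved
  # clip blocks are fine as long as each clip's own timeline moves forward
  bad <- dplyr::summarise(
    dplyr::group_by(out, .data$clip_id),
    ok = dplyr::n() < 2 || all(diff(.data$t) > 0)
  )
  if (any(!bad$ok)) {
    stop("non-monotone timestamps within clip(s): ",
         paste(bad$clip_id[!bad$ok], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::arrange(out, match(.data$clip_id, unique(out$clip_id)), .data$t)
  attr(out, "n_coerced") <- sum(coercedL) + sum(coercedR)
  out
}

#' Write a gaze-sample table
#'
#' Inverse of [read_gaze_table()] under the same dialect; used by the
#' synthetic generator to emit sessions in the dialect the reader parses.
#'
#' @param samples A gaze-sample tibble.
#' @param path Output TSV path.
#' @param dialect A [gaze_dialect()].
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(samples, path, dialect = gaze_dialect()) {
  valid_code <- dialect$valid_codes[1]
  invalid_code <- if (valid_code == 4L) 0L else 4L
  out <- data.frame(
    t = samples$t, clip = samples$clip_id,
    xL = samples$xL, yL = samples$yL, xR = samples$xR, yR = samples$yR,
    vL = ifelse(samples$validL, valid_code, invalid_code),
    vR = ifelse(samples$validR, valid_code, invalid_code)
  )
  names(out) <- c(dialect$col_t, dialect$col_clip, dialect$col_xL, dialect$col_yL,
                  dialect$col_xR, dialect$col_yR, dialect$col_validL,
                  dialect$col_validR)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read clip specifications
#'
#' Loads the stimulus protocol: one entry per clip with its stimulus
#' type (`looking` or `pointing`), the actor's cueing interval
#' (`action_start_ms`, `action_end_ms`) and the clip duration.
#'
#' @param path JSON file with top-level key `clips`: a list of objects
#'   with fields `clip_id`, `stimulus_type`, `action_start_ms`,
#'   `action_end_ms`, `duration_ms`.
#' @return A tibble of clip specs, validated.
#' @export
read_clip_specs <- function(path) {
  if (!file.exists(path)) stop("clip spec file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  clips <- tibble::as_tibble(spec$clips)
  validate_clip_specs(clips)
}

validate_clip_specs <- function(clips) {
  need <- c("clip_id", "stimulus_type", "action_start_ms", "action_end_ms",
            "duration_ms")
  missing_cols <- setdiff(need, names(clips))
  if (length(missing_cols) > 0) {
    stop("clip spec missing field(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(clips$stimulus_type %in% c("looking", "pointing"))) {
    stop("stimulus_type must be 'looking' or 'pointing'", call. = FALSE)
  }
  bad <- clips$action_start_ms < 0 |
    clips$action_end_ms <= clips$action_start_ms |
    clips$duration_ms < clips$action_end_ms
  if (any(bad)) {
    stop("invalid action window for clip(s): ",
         paste(clips$clip_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(clips$clip_id)) stop("duplicate clip_id", call. = FALSE)
  tibble::as_tibble(clips)
}

#' Write clip specifications
#' @param clips A clip-spec tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_clip_specs <- function(clips, path) {
  jsonlite::write_json(list(clips = clips), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read AOI specifications
#'
#' Loads, for each clip, the face / target / non-target polygons as
#' vertex lists in screen pixels. The three regions must be non-empty
#' and pairwise disjoint (checked on bounding boxes, then on rasterized
#' pixel sets where boxes overlap).
#'
#' @param path JSON file with top-level key `aois`: a list of objects
#'   with `clip_id` and `face` / `target` / `nontarget` vertex arrays
#'   `[[x, y], ...]`.
#' @return A named list (by `clip_id`) of AOI sets, each with vertex
#'   matrices `face`, `target`, `nontarget`.
#' @export
read_aoi_specs <- function(path) {
  if (!file.exists(path)) stop("AOI spec file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  sets <- lapply(spec$aois, function(a) {
    out <- list(
      clip_id = a$clip_id,
      face = as_vertex_matrix(a$face),
      target = as_vertex_matrix(a$target),
      nontarget = as_vertex_matrix(a$nontarget)
    )
    validate_aoi_set(out)
  })
  stats::setNames(sets, vapply(sets, function(a) a$clip_id, character(1)))
}

validate_aoi_set <- function(aoi_set) {
  regions <- list(face = aoi_set$face, target = aoi_set$target,
                  nontarget = aoi_set$nontarget)
  pairs <- utils::combn(names(regions), 2, simplify = FALSE)
  for (p in pairs) {
    if (regions_overlap(regions[[p[1]]], regions[[p[2]]])) {
      stop("AOI regions overlap in clip ", aoi_set$clip_id, ": ",
           p[1], " and ", p[2], call. = FALSE)
    }
  }
  structure(aoi_set, class = "aoi_set")
}

regions_overlap <- function(a, b) {
  # bounding-box prefilter, exact rasterized check only when boxes meet
  if (max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2])) {
    return(FALSE)
  }
  pa <- rasterize_polygon(a)
  pb <- rasterize_polygon(b)
  any(paste(pa[, 1], pa[, 2]) %in% paste(pb[, 1], pb[, 2]))
}

#' Write AOI specifications
#' @param aoi_map Named list of AOI sets (as from [read_aoi_specs()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_aoi_specs <- function(aoi_map, path) {
  aois <- lapply(unname(aoi_map), function(a) {
    list(clip_id = a$clip_id,
         face = unname(apply(a$face, 1, c, simplify = FALSE)),
         target = unname(apply(a$target, 1, c, simplify = FALSE)),
         nontarget = unname(apply(a$nontarget, 1, c, simplify = FALSE)))
  })
  jsonlite::write_json(list(aois = aois), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write detected events and participant summaries
#'
#' Emits two TSVs: one row per detected event (participant, clip, start
#' and end times, number of fixations) and one row per participant
#' summary (average valid sampling rate and event counts for all,
#' looking and pointing clips). Floats round-trip to 6 decimals.
#'
#' @param events Event tibble from [detect_rja_events()].
#' @param summaries Summary tibble from [summarize_participant()].
#' @param events_path,summaries_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_event_table <- function(events, summaries, events_path, summaries_path) {
  ev <- events[, c("participant_id", "clip_id", "fixation_index_start",
                   "fixation_index_end", "t_start_ms", "t_end_ms",
                   "n_fixations")]
  su <- summaries[, c("participant_id", "group", "avg_valid_sampling_rate",
                      "n_events_total", "n_events_looking", "n_events_pointing")]
  for (p in c(events_path, summaries_path)) {
    if (!dir.exists(dirname(p))) stop("unwritable path: ", p, call. = FALSE)
  }
  utils::write.table(ev, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(su, summaries_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(events = events_path, summaries = summaries_path))
}

#' Read back event and summary tables written by [write_event_table()]
#' @param events_path,summaries_path TSV paths.
#' @return A list with tibbles `events` and `summaries`.
#' @export
read_event_table <- function(events_path, summaries_path) {
  list(
    events = tibble::as_tibble(utils::read.delim(events_path, sep = "\t")),
    summaries = tibble::as_tibble(utils::read.delim(summaries_path, sep = "\t"))
  )
}
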