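# Shared fixtures and independent oracles, all built in code.

# A minimal AOI geometry without polygons, for detector unit tests.
toy_geom <- function(F = c(300, 540), T = c(1620, 220), N = c(1620, 860),
                     R_F = 150, R_T = 120, R_N = 120) {
  structure(
    list(clip_id = "toy", F = F, T = T, N = N,
         R_F = R_F, R_T = R_T, R_N = R_N, benchmark = T - F),
    class = "aoi_geometry"
  )
}

toy_clip <- function(action_start_ms = 2000, action_end_ms = 4000,
                     duration_ms = 6000, stimulus_type = "looking",
                     clip_id = "toy") {
  tibble::tibble(clip_id = clip_id, stimulus_type = stimulus_type,
                 action_start_ms = action_start_ms,
                 action_end_ms = action_end_ms, duration_ms = duration_ms)
}

# Fixation table from a point matrix, onsets inside the toy window.
fix_tbl <- function(pts, t0 = 2100, dur = 200, gap = 50) {
  pts <- rbind(pts)
  n <- nrow(pts)
  starts <- t0 + (seq_len(n) - 1) * (dur + gap)
  tibble::tibble(
    clip_id = "toy", t_start_ms = starts, t_end_ms = starts + dur,
    x = pts[, 1], y = pts[, 2],
    duration_ms = dur, n_samples = 60L, off_screen = FALSE
  )
}

# Independent brute-force detector oracle: enumerate every contiguous
# subsequence passing is_rja_sequence, then apply the documented
# earliest-start / earliest-end / non-overlap selection.
oracle_detect <- function(fixations, aoi_geom, config = detector_config()) {
  n <- nrow(fixations)
  cand <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (is_rja_sequence(fixations[i:j, , drop = FALSE], aoi_geom, config)) {
          cand[[length(cand) + 1]] <- c(i, j)
        }
      }
    }
  }
  sel <- list()
  while (length(cand) > 0) {
    ij <- do.call(rbind, cand)
    best <- order(ij[, 1], ij[, 2])[1]
    pick <- cand[[best]]
    sel[[length(sel) + 1]] <- pick
    cand <- Filter(function(c) c[1] > pick[2], cand)
  }
  if (length(sel) == 0) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  out <- do.call(rbind, sel)
  colnames(out) <- c("i", "j")
  out
}

# Random fixation layout biased to sometimes produce events.
random_layout <- function(geom, n_max = 12) {
  n <- sample(2:n_max, 1)
  anchors <- rbind(geom$F, geom$T, geom$N,
                   c(stats::runif(1, 0, 1920), stats::runif(1, 0, 1080)))
  pts <- t(vapply(seq_len(n), function(i) {
    a <- anchors[sample(4, 1), ]
    a + stats::rnorm(2, 0, 180)
  }, numeric(2)))
  data.frame(clip_id = "toy",
             t_start_ms = 2050 + (seq_len(n) - 1) * 150,
             t_end_ms = 2050 + (seq_len(n) - 1) * 150 + 100,
             x = pts[, 1], y = pts[, 2],
             duration_ms = 100, n_samples = 30L, off_screen = FALSE)
}

# Piecewise-constant stream with linear transitions: planted fixation
# points held for `hold_ms` each, transitions lasting `trans_ms`.
# Independent of the generator in R/synthetic_gaze.R.
segment_stream <- function(points, hold_ms = 300, trans_ms = 20,
                           rate_hz = 300, clip_id = "seg") {
  points <- rbind(points)
  dt <- 1000 / rate_hz
  t <- c(); x <- c(); y <- c()
  cur <- 0
  for (i in seq_len(nrow(points))) {
    th <- seq(cur, cur + hold_ms - dt / 2, by = dt)
    t <- c(t, th)
    x <- c(x, rep(points[i, 1], length(th)))
    y <- c(y, rep(points[i, 2], length(th)))
    cur <- cur + hold_ms
    if (i < nrow(points)) {
      tt <- seq(cur, cur + trans_ms - dt / 2, by = dt)
      frac <- (tt - cur) / trans_ms
      t <- c(t, tt)
      x <- c(x, points[i, 1] + frac * (points[i + 1, 1] - points[i, 1]))
      y <- c(y, points[i, 2] + frac * (points[i + 1, 2] - points[i, 2]))
      cur <- cur + trans_ms
    }
  }
  tibble::tibble(clip_id = clip_id, t = t, x = x, y = y,
                 valid = TRUE, both_valid = TRUE, interpolated = FALSE)
}

# Raw binocular sample tibble from a cyclopean stream.
as_binocular <- function(stream, participant_id = "P1", group = "TDC") {
  tibble::tibble(
    participant_id = participant_id, group = group,
    clip_id = stream$clip_id, t = stream$t,
    xL = stream$x, yL = stream$y, xR = stream$x, yR = stream$y,
    validL = stream$valid, validR = stream$valid, interpolated = FALSE
  )
}

write_tiny_gaze_tsv <- function(path, rows) {
  header <- paste(c("RecordingTimestamp", "MediaName",
                    "GazePointLeftX", "GazePointLeftY",
                    "GazePointRightX", "GazePointRightY",
                    "ValidityLeft", "ValidityRight"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}
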