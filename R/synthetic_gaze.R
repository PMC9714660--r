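#' Behavioural parameters of the synthetic gaze generator
#'
#' Controls the simulated participant: how often an RJA scanpath is
#' produced per clip type, the shape of the scanpath, fixation
#' durations, saccade kinematics, fixation jitter and track loss.
#'
#' @param p_rja_looking,p_rja_pointing Per-clip probability of producing
#'   an RJA scanpath for looking / pointing clips.
#' @param n_intermediate_fixations Number of forward fixations between
#'   the face and the target (0-3); `NA` draws 0-3 uniformly per clip.
#' @param fixation_dur_meanlog,fixation_dur_sdlog Lognormal parameters
#'   of fixation duration in ms (default: median 250 ms).
#' @param saccade_peak_deg_s Minimum peak saccade velocity; rendered
#'   saccades are shortened until their minimum-jerk peak reaches it.
#'   Must be at least twice the 30 deg/s I-VT threshold.
#' @param jitter_deg Marginal SD of fixational jitter in degrees
#'   (rendered as a temporally correlated AR(1) wobble).
#' @param track_loss_rate Long-run fraction of samples lost (both-eye
#'   validity dropped), generated in bursts.
#' @param track_loss_burst_ms Mean burst length of a loss episode (ms).
#'
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(p_rja_looking = 0.6, p_rja_pointing = 0.8,
                            n_intermediate_fixations = NA,
                            fixation_dur_meanlog = log(250),
                            fixation_dur_sdlog = 0.25,
                            saccade_peak_deg_s = 300,
                            jitter_deg = 0.15,
                            track_loss_rate = 0.05,
                            track_loss_burst_ms = 50) {
  if (p_rja_looking < 0 || p_rja_looking > 1 ||
      p_rja_pointing < 0 || p_rja_pointing > 1) {
    stop("RJA probabilities must be in [0, 1]", call. = FALSE)
  }
  if (saccade_peak_deg_s < 60) {
    stop("saccade_peak_deg_s must be at least 60 (twice the I-VT threshold)",
         call. = FALSE)
  }
  if (track_loss_rate < 0 || track_loss_rate >= 1) {
    stop("track_loss_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(p_rja_looking = p_rja_looking, p_rja_pointing = p_rja_pointing,
         n_intermediate_fixations = n_intermediate_fixations,
         fixation_dur_meanlog = fixation_dur_meanlog,
         fixation_dur_sdlog = fixation_dur_sdlog,
         saccade_peak_deg_s = saccade_peak_deg_s,
         jitter_deg = jitter_deg,
         track_loss_rate = track_loss_rate,
         track_loss_burst_ms = track_loss_burst_ms),
    class = "behavior_params"
  )
}

#' Default 12-clip stimulus protocol
#'
#' Six looking and six pointing clips of 6 s each. The actor holds
#' still for the first 2 s, cues between 2 and 4 s (the detection
#' window), and returns to rest for the final 2 s.
#'
#' @return A clip-spec tibble (see [read_clip_specs()]).
#' @export
default_protocol <- function() {
  tibble::tibble(
    clip_id = sprintf("clip%02d", 1:12),
    stimulus_type = rep(c("looking", "pointing"), 6),
    action_start_ms = 2000,
    action_end_ms = 4000,
    duration_ms = 6000
  )
}

#' Default AOI layout for the 12-clip protocol
#'
#' Square face and object AOIs on a 1920 x 1080 screen. The actor's
#' face sits on one side (or bottom-centre) and the target and
#' non-target objects occupy the opposite corners; which corner holds
#' the target alternates across clips so sides are counterbalanced.
#'
#' @param clips A clip-spec tibble (default [default_protocol()]).
#' @return Named list of AOI sets keyed by `clip_id`.
#' @export
default_aois <- function(clips = default_protocol()) {
  sq <- function(cx, cy, half) {
    rbind(c(cx - half, cy - half), c(cx + half, cy - half),
          c(cx + half, cy + half), c(cx - half, cy + half))
  }
  sets <- lapply(seq_len(nrow(clips)), function(k) {
    side <- c("right", "left", "top")[(k - 1) %% 3 + 1]
    swap <- (k - 1) %/% 3 %% 2 == 1    # alternate which corner is the target
    if (side == "right") {
      face <- sq(300, 540, 130)
      o1 <- sq(1620, 220, 100); o2 <- sq(1620, 860, 100)
    } else if (side == "left") {
      face <- sq(1620, 540, 130)
      o1 <- sq(300, 220, 100); o2 <- sq(300, 860, 100)
    } else {
      face <- sq(960, 820, 130)
      o1 <- sq(260, 200, 100); o2 <- sq(1660, 200, 100)
    }
    validate_aoi_set(list(
      clip_id = clips$clip_id[k],
      face = face,
      target = if (swap) o2 else o1,
      nontarget = if (swap) o1 else o2
    ))
  })
  stats::setNames(sets, clips$clip_id)
}

# lognormal fixation duration clamped to a physiological range
draw_fix_dur <- function(n, behavior) {
  pmin(pmax(stats::rlnorm(n, behavior$fixation_dur_meanlog,
                          behavior$fixation_dur_sdlog), 120), 600)
}

rand_disc <- function(center, radius) {
  a <- stats::runif(1, 0, 2 * pi)
  r <- radius * sqrt(stats::runif(1))
  center + r * c(cos(a), sin(a))
}

#' Plan one clip's fixation scanpath
#'
#' With probability `p_rja(stimulus_type)` the plan is an RJA event: a
#' fixation inside the face circle, 0-3 forward intermediate fixations
#' (each closer to the target than the non-target, moving at less than
#' 70 degrees to the benchmark vector) and a final fixation inside the
#' target circle, all with onsets inside the action window. Otherwise
#' the plan is a distractor scanpath that keeps clear of the face
#' circle, so no subsequence can satisfy the face-start criterion. Both
#' branches are verified against [is_rja_sequence()] at generation time
#' and redrawn on failure.
#'
#' @param clip One clip-spec row.
#' @param aoi_geom The clip's [aoi_geometry()].
#' @param behavior A [behavior_params()].
#' @param config The [detector_config()] the plan must (not) satisfy.
#' @return List: `plan` (tibble `t_start_ms`, `t_end_ms`, `x`, `y`),
#'   `rja_planted` (logical).
#' @export
simulate_scanpath <- function(clip, aoi_geom, behavior = behavior_params(),
                              config = detector_config()) {
  margin <- 0.5  # planted endpoints stay well inside the (1.2 R) circles
  if (sqrt(sum(aoi_geom$benchmark^2)) <
      config$radius_multiplier * (aoi_geom$R_F + aoi_geom$R_T)) {
    stop("AOIs too close together for clean planted margins", call. = FALSE)
  }
  p_rja <- if (clip$stimulus_type == "looking") behavior$p_rja_looking else
    behavior$p_rja_pointing
  want_rja <- stats::runif(1) < p_rja
  for (attempt in 1:50) {
    pts <- if (want_rja) {
      plan_rja_points(aoi_geom, behavior, margin)
    } else {
      plan_distractor_points(aoi_geom, config)
    }
    if (is.null(pts)) next
    fx <- tibble::tibble(x = pts[, 1], y = pts[, 2])
    ok <- if (want_rja) {
      is_rja_sequence(fx, aoi_geom, config)
    } else {
      !any_rja_subsequence(fx, aoi_geom, config)
    }
    if (ok) break
    pts <- NULL
  }
  if (is.null(pts)) stop("could not generate a feasible scanpath", call. = FALSE)
  # schedule: centre fixation before the window, planned points inside it;
  # durations are compressed (floored well above the 60 ms minimum) so the
  # whole plan's onsets fit inside the action window
  n <- nrow(pts)
  durs <- draw_fix_dur(n, behavior)
  sac <- stats::runif(n, 25, 45)
  onset <- clip$action_start_ms + stats::runif(1, 60, 150)
  avail <- clip$action_end_ms - 60 - onset
  need <- sum(durs) + sum(sac[-1])
  if (need > avail) {
    durs <- pmax(durs * (avail - sum(sac[-1])) / sum(durs), 130)
  }
  t0 <- numeric(n); t1 <- numeric(n)
  for (i in seq_len(n)) {
    t0[i] <- if (i == 1) onset else t1[i - 1] + sac[i]
    t1[i] <- t0[i] + durs[i]
  }
  center <- c(960, 540)
  pre <- tibble::tibble(t_start_ms = 100, t_end_ms = clip$action_start_ms - 60,
                        x = center[1], y = center[2])
  post_t0 <- max(t1[n] + 60, clip$action_end_ms + 60)
  post_t0 <- min(post_t0, clip$duration_ms - 200)
  post <- tibble::tibble(t_start_ms = post_t0,
                         t_end_ms = clip$duration_ms - 20,
                         x = center[1], y = center[2])
  plan <- dplyr::bind_rows(
    pre,
    tibble::tibble(t_start_ms = t0, t_end_ms = t1, x = pts[, 1], y = pts[, 2]),
    post
  )
  list(plan = plan, rja_planted = want_rja)
}

plan_rja_points <- function(aoi_geom, behavior, margin) {
  k <- behavior$n_intermediate_fixations
  if (is.na(k)) k <- sample(0:3, 1)
  p_first <- rand_disc(aoi_geom$F, margin * aoi_geom$R_F)
  p_last <- rand_disc(aoi_geom$T, margin * aoi_geom$R_T)
  if (k == 0) return(rbind(p_first, p_last))
  fr <- sort(stats::runif(k, 0.35, 0.8))
  if (k > 1 && min(diff(fr)) < 0.12) return(NULL)   # keep steps well apart
  b <- aoi_geom$benchmark
  perp <- c(-b[2], b[1]) / sqrt(sum(b^2))
  mid <- t(vapply(fr, function(s) {
    aoi_geom$F + s * b + perp * stats::rnorm(1, 0, 0.04 * sqrt(sum(b^2)))
  }, numeric(2)))
  pts <- rbind(p_first, mid, p_last)
  # clean margins: every step long enough and well inside the 90-degree
  # angle criterion, so centroid jitter cannot flip a vector past it
  v <- cbind(diff(pts[, 1]), diff(pts[, 2]))
  if (any(sqrt(rowSums(v^2)) < 80)) return(NULL)
  if (any(vector_angle(v, b) >= 70)) return(NULL)
  pts
}

plan_distractor_points <- function(aoi_geom, config) {
  n <- sample(3:6, 1)
  keep_out <- 1.1 * config$radius_multiplier * aoi_geom$R_F
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      p <- c(stats::runif(1, 60, 1860), stats::runif(1, 60, 1020))
      if (sqrt(sum((p - aoi_geom$F)^2)) > keep_out) break
    }
    pts[i, ] <- p
  }
  pts
}

# brute-force: does any contiguous subsequence satisfy the four criteria?
any_rja_subsequence <- function(fx, aoi_geom, config) {
  n <- nrow(fx)
  if (n < 2) return(FALSE)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (is_rja_sequence(fx[i:j, , drop = FALSE], aoi_geom, config)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Render a full synthetic session as 300 Hz binocular samples
#'
#' Draws a scanpath plan per clip and renders it: fixations become
#' stationary segments with temporally correlated jitter, transitions
#' become minimum-jerk saccades whose peak velocity is forced above
#' `saccade_peak_deg_s`, and bursty two-state track loss removes
#' both-eye validity at the configured long-run rate. The two eyes are
#' the cyclopean trace offset horizontally by half an interocular
#' spread, so their average recovers the plan. Deterministic for a
#' fixed seed.
#'
#' @param participant_id,group Metadata columns.
#' @param clips Clip-spec tibble (default [default_protocol()]).
#' @param aoi_map Named list of AOI sets or [aoi_geometry()] objects
#'   (default [default_aois()]).
#' @param behavior A [behavior_params()].
#' @param geometry A [viewing_geometry()].
#' @param config The [detector_config()] the plans are verified against.
#' @param rate_hz Sampling rate (default 300).
#' @param seed Integer seed.
#' @return List: `samples` (gaze-sample tibble in the [read_gaze_table()]
#'   schema), `truth` (tibble per clip: `clip_id`, `rja_planted`,
#'   `n_plan_fixations`, list-column `plan`).
#' @export
simulate_session <- function(participant_id, group = "TDC",
                             clips = default_protocol(),
                             aoi_map = default_aois(clips),
                             behavior = behavior_params(),
                             geometry = viewing_geometry(),
                             config = detector_config(),
                             rate_hz = 300, seed = 1) {
  set.seed(seed)
  geoms <- lapply(aoi_map, function(a) {
    if (inherits(a, "aoi_geometry")) a else aoi_geometry(a)
  })
  per_clip <- lapply(seq_len(nrow(clips)), function(k) {
    clip <- clips[k, ]
    sp <- simulate_scanpath(clip, geoms[[clip$clip_id]], behavior, config)
    smp <- render_clip(sp$plan, clip, behavior, geometry, rate_hz)
    smp$clip_id <- clip$clip_id
    list(samples = smp,
         truth = tibble::tibble(clip_id = clip$clip_id,
                                rja_planted = sp$rja_planted,
                                n_plan_fixations = nrow(sp$plan),
                                plan = list(sp$plan)))
  })
  samples <- dplyr::bind_rows(lapply(per_clip, `[[`, "samples"))
  samples <- tibble::tibble(participant_id = participant_id, group = group,
                            samples)
  samples <- samples[, c("participant_id", "group", "clip_id", "t",
                         "xL", "yL", "xR", "yR", "validL", "validR",
                         "interpolated")]
  list(samples = samples, truth = dplyr::bind_rows(lapply(per_clip, `[[`, "truth")))
}

render_clip <- function(plan, clip, behavior, geometry, rate_hz) {
  dt <- 1000 / rate_hz
  t <- seq(0, clip$duration_ms - dt / 2, by = dt)
  n <- length(t)
  x <- numeric(n); y <- numeric(n)
  peak <- behavior$saccade_peak_deg_s
  # piecewise: hold during fixations, minimum-jerk jumps between them
  for (i in seq_len(nrow(plan))) {
    infix <- t >= plan$t_start_ms[i] & t <= plan$t_end_ms[i]
    x[infix] <- plan$x[i]; y[infix] <- plan$y[i]
    if (i < nrow(plan)) {
      gap <- t > plan$t_end_ms[i] & t < plan$t_start_ms[i + 1]
      if (any(gap)) {
        p0 <- c(plan$x[i], plan$y[i]); p1 <- c(plan$x[i + 1], plan$y[i + 1])
        amp_deg <- visual_angle(p0, p1, geometry)
        gap_len <- plan$t_start_ms[i + 1] - plan$t_end_ms[i]
        # shorten the movement so its minimum-jerk peak (1.875 A / T)
        # clears the requested peak velocity; the movement ends exactly at
        # the next fixation's onset so recovered onsets never run early
        T_sac <- max(2 * dt, min(gap_len, 1000 * 1.875 * amp_deg / peak))
        sac_start <- plan$t_start_ms[i + 1] - T_sac
        tau <- pmin(pmax((t[gap] - sac_start) / T_sac, 0), 1)
        s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
        x[gap] <- p0[1] + s * (p1[1] - p0[1])
        y[gap] <- p0[2] + s * (p1[2] - p0[2])
      }
    }
  }
  before <- t < plan$t_start_ms[1]
  x[before] <- plan$x[1]; y[before] <- plan$y[1]
  after <- t > plan$t_end_ms[nrow(plan)]
  x[after] <- plan$x[nrow(plan)]; y[after] <- plan$y[nrow(plan)]
  # AR(1) fixational wobble with the requested marginal SD
  sd_px <- deg_to_px(behavior$jitter_deg, geometry)
  phi <- 0.95
  innov_sd <- sd_px * sqrt(1 - phi^2)
  jx <- stats::filter(stats::rnorm(n, 0, innov_sd), phi, "recursive")
  jy <- stats::filter(stats::rnorm(n, 0, innov_sd), phi, "recursive")
  x <- x + as.numeric(jx); y <- y + as.numeric(jy)
  valid <- !markov_loss(n, behavior$track_loss_rate,
                        behavior$track_loss_burst_ms / dt)
  ipd <- 4  # half interocular spread on screen, px
  tibble::tibble(
    t = t,
    xL = ifelse(valid, x - ipd, NA_real_), yL = ifelse(valid, y, NA_real_),
    xR = ifelse(valid, x + ipd, NA_real_), yR = ifelse(valid, y, NA_real_),
    validL = valid, validR = valid, interpolated = FALSE
  )
}

# two-state Markov burst loss with given long-run rate and mean burst length
markov_loss <- function(n, rate, mean_burst_samples) {
  if (rate <= 0) return(rep(FALSE, n))
  p_exit <- 1 / max(mean_burst_samples, 1)
  p_enter <- p_exit * rate / (1 - rate)
  lost <- logical(n)
  state <- stats::runif(1) < rate
  for (i in seq_len(n)) {
    lost[i] <- state
    state <- if (state) stats::runif(1) >= p_exit else stats::runif(1) < p_enter
  }
  lost
}

#' Simulate a feature-level cohort
#'
#' Draws per-participant feature rows (average valid sampling rate and
#' total RJA event count) from group-specific distributions, for
#' statistical power and classifier tests without rendering full
#' sessions. Alternatively, with `logistic_coef` given, labels are
#' drawn from a planted logistic model on the two features, for
#' parameter-recovery tests.
#'
#' @param group_specs Tibble with columns `group`, `rate_mean`,
#'   `rate_sd`, `events_mean`, `events_size` (negative-binomial
#'   dispersion); see [default_group_specs()].
#' @param n_per_group Participants per group (recycled).
#' @param seed Integer seed.
#' @param logistic_coef Optional `c(b0, b1, b2)`; if given, two groups
#'   `ASD`/`TDC` are labelled by the planted model
#'   `logit P(ASD) = b0 + b1 * rate + b2 * events` with features drawn
#'   from the first group spec.
#' @return A tibble: `participant_id`, `group` (label),
#'   `avg_valid_sampling_rate`, `n_events_total`, `label`, `age_years`,
#'   `sex`.
#' @export
simulate_cohort <- function(group_specs = default_group_specs(),
                            n_per_group = 100, seed = 1,
                            logistic_coef = NULL) {
  set.seed(seed)
  n_per_group <- rep_len(n_per_group, nrow(group_specs))
  if (!is.null(logistic_coef)) {
    n <- sum(n_per_group)
    g <- group_specs[1, ]
    rate <- pmin(pmax(stats::rnorm(n, g$rate_mean, g$rate_sd), 0.01), 1)
    events <- stats::rnbinom(n, mu = g$events_mean, size = g$events_size)
    eta <- logistic_coef[1] + logistic_coef[2] * rate + logistic_coef[3] * events
    lab <- ifelse(stats::runif(n) < stats::plogis(eta), "ASD", "TDC")
    return(tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      group = lab, avg_valid_sampling_rate = rate,
      n_events_total = events, label = lab,
      age_years = stats::runif(n, 4, 7),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2))
    ))
  }
  rows <- lapply(seq_len(nrow(group_specs)), function(k) {
    g <- group_specs[k, ]
    n <- n_per_group[k]
    adult <- g$group == "TDA"
    tibble::tibble(
      group = g$group,
      avg_valid_sampling_rate =
        pmin(pmax(stats::rnorm(n, g$rate_mean, g$rate_sd), 0.01), 1),
      n_events_total = stats::rnbinom(n, mu = g$events_mean, size = g$events_size),
      label = g$group,
      age_years = if (adult) stats::runif(n, 19, 32) else stats::runif(n, 4, 7),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(participant_id = sprintf("P%04d", seq_len(nrow(out))), out)
  out
}

#' Default group feature distributions
#'
#' Group-level feature distributions used by [simulate_cohort()]:
#' ASD children lower than TDC on both the valid sampling rate and the
#' event count, and TD adults highest — the effect directions reported
#' for this paradigm. Event counts are negative-binomial with matched
#' dispersion; rates are truncated normal.
#'
#' @return A tibble of group specs.
#' @export
default_group_specs <- function() {
  tibble::tibble(
    group = c("ASD", "TDC", "TDA"),
    rate_mean = c(0.75, 0.85, 0.93),
    rate_sd = c(0.12, 0.10, 0.05),
    events_mean = c(5, 9, 11),
    events_size = c(8, 8, 8)
  )
}
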