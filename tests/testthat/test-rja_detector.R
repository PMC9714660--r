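g <- toy_geom()
clip <- toy_clip()

test_that("window membership follows the onset policy with closed bounds", {
  fx <- fix_tbl(rbind(c(100, 100), c(200, 200), c(300, 300)))
  fx$t_start_ms <- c(1500, 2000, 4000)   # before, exactly at start, exactly at end
  fx$t_end_ms <- fx$t_start_ms + 200
  w <- fixations_in_window(fx, clip, "onset")
  expect_equal(w$t_start_ms, c(2000, 4000))

  straddler <- fx[1, ]
  straddler$t_start_ms <- 1900; straddler$t_end_ms <- 2100
  expect_equal(nrow(fixations_in_window(straddler, clip, "onset")), 0)
  expect_equal(nrow(fixations_in_window(straddler, clip, "overlap")), 1)
})

test_that("the four criteria behave on canonical and boundary layouts", {
  cfg <- detector_config()
  # canonical two-fixation event: face then target
  ev2 <- fix_tbl(rbind(g$F, g$T))
  expect_true(is_rja_sequence(ev2, g, cfg))

  # intermediate closer to the non-target fails criterion 3
  bad3 <- fix_tbl(rbind(g$F, g$N + c(-50, -50), g$T))
  expect_false(is_rja_sequence(bad3, g, cfg))

  # a return-toward-face vector fails the angle criterion
  back <- fix_tbl(rbind(g$F, g$T, g$T - 0.4 * g$benchmark, g$T))
  expect_false(is_rja_sequence(back, g, cfg))

  # first fixation at exactly 1.2 R_F fails (strict <); axis-aligned so
  # the boundary distance is exact in floating point
  u <- g$benchmark / sqrt(sum(g$benchmark^2))
  at_edge <- fix_tbl(rbind(g$F + c(1.2 * g$R_F, 0), g$T))
  expect_false(is_rja_sequence(at_edge, g, cfg))
  just_in <- fix_tbl(rbind(g$F + c(1.2 * g$R_F - 1, 0), g$T))
  expect_true(is_rja_sequence(just_in, g, cfg))

  # angle exactly 90 degrees fails: final step perpendicular to the benchmark
  perp <- c(-u[2], u[1])
  v <- rbind(g$F, g$T, g$T + perp * 50)
  expect_false(is_rja_sequence(fix_tbl(v), g, cfg))

  expect_error(is_rja_sequence(fix_tbl(rbind(g$F)), g, cfg), "at least 2")
})

test_that("scan detection matches the worked scanpath shapes", {
  cfg <- detector_config()
  # face -> two forward intermediates -> target: one event, four fixations
  mids <- rbind(g$F + 0.4 * g$benchmark + c(0, -30),
                g$F + 0.7 * g$benchmark + c(0, 20))
  fx <- fix_tbl(rbind(g$F, mids, g$T))
  ev <- detect_rja_events(fx, clip, g, cfg, window = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_fixations, 4L)
  expect_equal(ev$fixation_index_start, 1L)
  expect_equal(ev$fixation_index_end, 4L)

  # face -> target -> face -> target: two disjoint events
  fx2 <- fix_tbl(rbind(g$F, g$T, g$F, g$T))
  ev2 <- detect_rja_events(fx2, clip, g, cfg, window = FALSE)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$fixation_index_start, c(1L, 3L))
  expect_equal(ev2$fixation_index_end, c(2L, 4L))

  # nothing near the face: no events
  fx3 <- fix_tbl(rbind(g$N, g$T, g$N))
  expect_equal(nrow(detect_rja_events(fx3, clip, g, cfg, window = FALSE)), 0)
})

test_that("earliest termination closes at the first target fixation; maximal extends", {
  fx <- fix_tbl(rbind(g$F, g$T - 40 * g$benchmark / sqrt(sum(g$benchmark^2)),
                      g$T))
  # both the 2nd and 3rd fixations are inside 1.2 R_T
  ev_e <- detect_rja_events(fx, clip, g, detector_config(), window = FALSE)
  expect_equal(ev_e$fixation_index_end, 2L)
  ev_m <- detect_rja_events(fx, clip, g,
                            detector_config(termination = "maximal"),
                            window = FALSE)
  expect_equal(ev_m$fixation_index_end, 3L)
})

test_that("scan output equals the brute-force oracle over random layouts", {
  set.seed(101)
  n_trials <- 600
  mismatches <- 0
  for (k in seq_len(n_trials)) {
    fx <- random_layout(g)
    ev <- detect_rja_events(fx, clip, g, detector_config(), window = FALSE)
    orc <- oracle_detect(fx, g, detector_config())
    same <- nrow(ev) == nrow(orc) &&
      all(ev$fixation_index_start == orc[, "i"]) &&
      all(ev$fixation_index_end == orc[, "j"])
    if (!same) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("event counts are monotone in the detector thresholds", {
  set.seed(202)
  for (k in 1:60) {
    fx <- random_layout(g)
    n_def <- nrow(detect_rja_events(fx, clip, g, detector_config(), window = FALSE))
    n_small_m <- nrow(detect_rja_events(
      fx, clip, g, detector_config(radius_multiplier = 0.8), window = FALSE))
    n_small_a <- nrow(detect_rja_events(
      fx, clip, g, detector_config(max_angle_deg = 45), window = FALSE))
    n_big_a <- nrow(detect_rja_events(
      fx, clip, g, detector_config(max_angle_deg = 135), window = FALSE))
    expect_lte(n_small_m, n_def)
    expect_lte(n_small_a, n_def)
    expect_gte(n_big_a, n_def)
  }
})

test_that("events are invariant under rigid motion of fixations and AOIs together", {
  set.seed(303)
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(123, -45)
  xf <- function(p) as.numeric(R %*% p + shift)
  g2 <- toy_geom(F = xf(g$F), T = xf(g$T), N = xf(g$N),
                 R_F = g$R_F, R_T = g$R_T, R_N = g$R_N)
  for (k in 1:40) {
    fx <- random_layout(g)
    pts2 <- t(apply(cbind(fx$x, fx$y), 1, xf))
    fx2 <- fx; fx2$x <- pts2[, 1]; fx2$y <- pts2[, 2]
    ev1 <- detect_rja_events(fx, clip, g, detector_config(), window = FALSE)
    ev2 <- detect_rja_events(fx2, clip, g2, detector_config(), window = FALSE)
    expect_equal(ev1$fixation_index_start, ev2$fixation_index_start)
    expect_equal(ev1$fixation_index_end, ev2$fixation_index_end)
  }
})

test_that("participant summaries split counts by stimulus type and flag clips", {
  clips <- default_protocol()
  ev <- tibble::tibble(
    participant_id = "P1",
    clip_id = c("clip01", "clip02", "clip02"),   # looking, pointing x2
    fixation_index_start = 1L, fixation_index_end = 2L,
    t_start_ms = 2100, t_end_ms = 2500, n_fixations = 2L
  )
  qc <- tibble::tibble(participant_id = "P1", avg_rate = 0.8, included = TRUE)
  s <- summarize_participant(ev, clips, qc, group = "ASD")
  expect_equal(s$n_events_total, 3)
  expect_equal(s$n_events_looking, 1)
  expect_equal(s$n_events_pointing, 2)
  expect_equal(s$n_events_total, s$n_events_looking + s$n_events_pointing)
  flags <- s$has_event_by_clip[[1]]
  expect_true(flags[["clip01"]] && flags[["clip02"]])
  expect_equal(sum(flags), 2)
  expect_equal(s$avg_valid_sampling_rate, 0.8)

  s0 <- summarize_participant(ev[0, ], clips, qc, participant_id = "P1")
  expect_equal(s0$n_events_total, 0)
  expect_false(any(s0$has_event_by_clip[[1]]))

  bad <- ev; bad$clip_id[1] <- "nope"
  expect_error(summarize_participant(bad, clips, qc), "unknown clip")
})
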