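geom <- viewing_geometry()

test_that("binocular averaging takes the midpoint, single eye, or invalid", {
  s <- tibble::tibble(
    participant_id = "P", group = "TDC", clip_id = "c",
    t = c(0, 3.33, 6.67),
    xL = c(100, 50, NA), yL = c(100, 60, NA),
    xR = c(110, NA, NA), yR = c(100, NA, NA),
    validL = c(TRUE, TRUE, FALSE), validR = c(TRUE, FALSE, FALSE),
    interpolated = FALSE
  )
  cy <- combine_eyes(s)
  expect_equal(cy$x, c(105, 50, NA_real_))
  expect_equal(cy$y, c(100, 60, NA_real_))
  expect_equal(cy$valid, c(TRUE, TRUE, FALSE))
  expect_equal(cy$both_valid, c(TRUE, FALSE, FALSE))
})

test_that("short interior gaps are linearly interpolated; long and edge gaps are not", {
  dt <- 1000 / 300
  t <- seq(0, by = dt, length.out = 100)
  stream <- tibble::tibble(
    clip_id = "c", t = t, x = t, y = 2 * t,
    valid = TRUE, both_valid = TRUE, interpolated = FALSE
  )
  gap <- 11:18                      # ~27 ms interior gap
  stream$x[gap] <- NA; stream$y[gap] <- NA; stream$valid[gap] <- FALSE
  filled <- fill_gaps(stream, 75)
  expect_true(all(filled$valid[gap]))
  expect_true(all(filled$interpolated[gap]))
  # straight line in t: x == t and y == 2t restored exactly
  expect_equal(filled$x[gap], t[gap], tolerance = 1e-9)
  expect_equal(filled$y[gap], 2 * t[gap], tolerance = 1e-9)
  # original validity elsewhere untouched, idempotent
  expect_identical(fill_gaps(filled, 75)$x, filled$x)

  long <- stream
  long$valid[20:85] <- FALSE        # ~217 ms
  expect_false(any(fill_gaps(long, 75)$valid[20:85]))

  edge <- stream
  edge$valid[1:5] <- FALSE
  expect_false(any(fill_gaps(edge, 75)$valid[1:5]))
})

test_that("visual angle matches the closed form and the small-angle limit", {
  expect_equal(visual_angle(c(500, 300), c(500, 300), geom), 0)
  # full screen width, symmetric about centre, 65 cm away
  a <- visual_angle(c(0, 540), c(1920, 540), geom)
  expect_equal(a, 2 * atan(254.9 / 650) * 180 / pi, tolerance = 1e-6)
  # symmetry
  expect_equal(visual_angle(c(100, 100), c(700, 900), geom),
               visual_angle(c(700, 900), c(100, 100), geom))
  # small-angle oracle within 1% for separations under 2 degrees
  for (d_px in c(5, 20, 60, 120)) {
    approx <- d_px * geom$mm_per_px_x / geom$distance_mm * 180 / pi
    exact <- visual_angle(c(960 - d_px / 2, 540), c(960 + d_px / 2, 540), geom)
    expect_lt(abs(exact - approx) / approx, 0.01)
  }
})

test_that("angular velocity is zero when still, matches a constructed ramp, and is undefined at gaps", {
  dt <- 1000 / 300
  t <- seq(0, by = dt, length.out = 200)
  still <- tibble::tibble(clip_id = "c", t = t, x = 960, y = 540,
                          valid = TRUE, both_valid = TRUE, interpolated = FALSE)
  v <- angular_velocity(still, 20, geom)$velocity_deg_s
  expect_true(all(v[!is.na(v)] == 0))
  expect_true(is.na(v[1]) && is.na(v[200]))   # window leaves the clip

  # drift of 1 degree per 100 ms through the screen centre
  px_per_deg <- deg_to_px(1, geom)
  ramp <- tibble::tibble(
    clip_id = "c", t = t, x = 960 - px_per_deg + t / 100 * px_per_deg, y = 540,
    valid = TRUE, both_valid = TRUE, interpolated = FALSE
  )
  vr <- angular_velocity(ramp, 20, geom)$velocity_deg_s
  mid <- vr[50:150]
  expect_true(all(abs(mid - 10) / 10 < 0.05, na.rm = TRUE))

  gappy <- still
  gappy$valid[100] <- FALSE
  vg <- angular_velocity(gappy, 20, geom)$velocity_deg_s
  expect_true(is.na(vg[100]))      # edge sample invalid
})

test_that("the 30 deg/s boundary is a saccade and undefined stays undefined", {
  expect_equal(classify_ivt(c(29.9, 30, 0, NA), 30),
               c("fixation", "saccade", "fixation", "undefined"))
})

test_that("fixation aggregation merges close candidates and drops short ones", {
  dt <- 1000 / 300
  mk <- function(spans, pts, labels) {
    # spans: list of c(t0, t1); constant position per span, with one
    # saccade-labelled sample in each temporal gap so runs are distinct
    rows <- purrr::map2(spans, seq_along(spans), function(sp, i) {
      t <- seq(sp[1], sp[2] - dt / 2, by = dt)
      out <- tibble::tibble(clip_id = "c", t = t, x = pts[i, 1], y = pts[i, 2],
                            valid = TRUE, both_valid = TRUE,
                            interpolated = FALSE, label = labels[i])
      if (i < length(spans)) {
        mid <- (sp[2] + spans[[i + 1]][1]) / 2
        out <- dplyr::bind_rows(out, tibble::tibble(
          clip_id = "c", t = mid,
          x = (pts[i, 1] + pts[i + 1, 1]) / 2,
          y = (pts[i, 2] + pts[i + 1, 2]) / 2,
          valid = TRUE, both_valid = TRUE, interpolated = FALSE,
          label = "saccade"
        ))
      }
      out
    })
    dplyr::bind_rows(rows)
  }
  # single 200 ms stationary run
  s1 <- mk(list(c(0, 200)), rbind(c(500, 500)), "fixation")
  f1 <- aggregate_fixations(s1, s1$label, ivt_config(), geom)
  expect_equal(nrow(f1), 1)
  expect_equal(c(f1$x, f1$y), c(500, 500))

  # two 100 ms runs 10 ms apart, ~0.1 degree apart -> merged
  d01 <- deg_to_px(0.1, geom)
  s2 <- mk(list(c(0, 100), c(110, 210)),
           rbind(c(500, 500), c(500 + d01, 500)),
           c("fixation", "fixation"))
  f2 <- aggregate_fixations(s2, s2$label, ivt_config(), geom)
  expect_equal(nrow(f2), 1)

  # same runs 3 degrees apart -> not merged
  d3 <- deg_to_px(3, geom)
  s3 <- mk(list(c(0, 100), c(110, 210)),
           rbind(c(500, 500), c(500 + d3, 500)),
           c("fixation", "fixation"))
  expect_equal(nrow(aggregate_fixations(s3, s3$label, ivt_config(), geom)), 2)

  # 40 ms run is discarded under the 60 ms minimum
  s4 <- mk(list(c(0, 40)), rbind(c(500, 500)), "fixation")
  expect_equal(nrow(aggregate_fixations(s4, s4$label, ivt_config(), geom)), 0)
})

test_that("planted fixation/saccade segments are recovered with correct count and centroids", {
  set.seed(11)
  pts <- rbind(c(400, 400), c(1200, 400), c(800, 800), c(1500, 900))
  stream <- segment_stream(pts, hold_ms = 300, trans_ms = 20)
  samples <- as_binocular(stream)
  fx <- detect_fixations(samples, ivt_config(), geom)
  expect_equal(nrow(fx), nrow(pts))
  for (i in seq_len(nrow(pts))) {
    err <- visual_angle(c(fx$x[i], fx$y[i]), pts[i, ], geom)
    expect_lt(err, 0.2)
  }
  # fixation intervals disjoint, ordered, all above the minimum duration
  expect_true(all(diff(fx$t_start_ms) > 0))
  expect_true(all(utils::head(fx$t_end_ms, -1) < utils::tail(fx$t_start_ms, -1)))
  expect_true(all(fx$duration_ms >= 60))
})

test_that("gap filling does not change QC validity and recovery survives jitter", {
  set.seed(21)
  pts <- rbind(c(400, 500), c(1300, 500))
  stream <- segment_stream(pts, hold_ms = 400, trans_ms = 20)
  # add 0.1 degree i.i.d. jitter within fixations
  sd_px <- deg_to_px(0.1, geom) / 2
  stream$x <- stream$x + rnorm(nrow(stream), 0, sd_px)
  stream$y <- stream$y + rnorm(nrow(stream), 0, sd_px)
  samples <- as_binocular(stream)
  # knock out a short burst inside the first fixation
  burst <- 40:47
  samples$validL[burst] <- FALSE
  samples$validR[burst] <- FALSE
  fx <- detect_fixations(samples, ivt_config(), geom)
  expect_equal(nrow(fx), 2)
  expect_lt(visual_angle(c(fx$x[1], fx$y[1]), pts[1, ], geom), 0.2)
  # QC computed on raw validity is unaffected by interpolation
  expect_equal(clip_valid_sampling_rate(samples, "seg"),
               1 - length(burst) / nrow(samples))
})
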