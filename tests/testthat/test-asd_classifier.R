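feature_rows <- function(n, b = c(8.35, -8.2855, -0.2151), seed = 1) {
  set.seed(seed)
  rate <- pmin(pmax(rnorm(n, 0.8, 0.12), 0.05), 1)
  events <- rnbinom(n, mu = 8, size = 4)
  eta <- b[1] + b[2] * rate + b[3] * events
  tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    avg_valid_sampling_rate = rate,
    n_events_total = events,
    label = ifelse(runif(n) < plogis(eta), "ASD", "TDC")
  )
}

test_that("the IRLS fit matches glm and recovers a planted null", {
  rows <- feature_rows(800, seed = 5)
  fit <- fit_logistic(rows)
  expect_true(fit$converged)
  ref <- glm(I(label == "ASD") ~ avg_valid_sampling_rate + n_events_total,
             data = rows, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-3)

  # label independent of features: both slopes within 2 SE of zero
  set.seed(6)
  null_rows <- feature_rows(600, b = c(0, 0, 0), seed = 6)
  nf <- fit_logistic(null_rows)
  expect_lt(abs(nf$coefficients["rate"]), 2 * nf$se["rate"])
  expect_lt(abs(nf$coefficients["events"]), 2 * nf$se["events"])

  expect_error(fit_logistic(dplyr::mutate(rows, label = "ASD")), "both classes")
})

test_that("complete separation is reported as a status, not huge coefficients", {
  rows <- tibble::tibble(
    participant_id = as.character(1:20),
    avg_valid_sampling_rate = c(seq(0.1, 0.4, length.out = 10),
                                seq(0.6, 0.9, length.out = 10)),
    n_events_total = rep(c(3, 5, 7, 9), 5),
    label = rep(c("ASD", "TDC"), each = 10)
  )
  fit <- fit_logistic(rows)
  expect_equal(fit$status, "separated")
  expect_false(fit$converged)
})

test_that("planted coefficients are recovered within 10% at n = 5000", {
  b <- c(8.35, -log(2.29) / 0.1, -log(1.24))
  ok <- 0
  for (s in 1:5) {
    rows <- feature_rows(5000, b = b, seed = 100 + s)
    fit <- fit_logistic(rows)
    rel <- abs((fit$coefficients - b) / b)
    if (all(rel < 0.10)) ok <- ok + 1
  }
  expect_gte(ok, 4)
  # and the odds-ratio interpretations come back out
  rows <- feature_rows(5000, b = b, seed = 123)
  fit <- fit_logistic(rows)
  expect_equal(odds_ratio_per_delta(fit, "rate", -0.1), 2.29, tolerance = 0.1)
  expect_equal(1 / odds_ratio_per_delta(fit, "events", 1), 1.24,
               tolerance = 0.05)
})

test_that("the stratified split preserves class counts and is seed-deterministic", {
  rows <- tibble::tibble(
    participant_id = as.character(1:256),
    avg_valid_sampling_rate = runif(256),
    n_events_total = rpois(256, 6),
    label = c(rep("ASD", 143), rep("TDC", 113))
  )
  sp <- split_train_test(rows, 0.20, seed = 42)
  expect_equal(sum(sp$test$label == "ASD"), 29)
  expect_equal(sum(sp$test$label == "TDC"), 23)
  expect_equal(sum(sp$train$label == "ASD"), 114)
  expect_equal(sum(sp$train$label == "TDC"), 90)
  sp2 <- split_train_test(rows, 0.20, seed = 42)
  expect_identical(sp$test$participant_id, sp2$test$participant_id)
  expect_error(split_train_test(rows, 0), "test_frac")
})

test_that("cross-validation is stratified, sized k, and calibrated to chance on shuffled labels", {
  rows <- feature_rows(400, seed = 11)
  cv <- kfold_cv(rows, k = 10, seed = 2)
  expect_equal(nrow(cv$per_fold), 10)
  expect_equal(sum(cv$per_fold$n_test), nrow(rows))

  # perfectly predictable data
  sep_rows <- tibble::tibble(
    participant_id = as.character(1:200),
    avg_valid_sampling_rate = c(runif(100, 0.05, 0.35), runif(100, 0.65, 0.95)),
    n_events_total = c(rpois(100, 2), rpois(100, 14)),
    label = rep(c("ASD", "TDC"), each = 100)
  )
  cvs <- kfold_cv(sep_rows, k = 10, seed = 3)
  expect_equal(cvs$mean_acc, 1)
  expect_equal(cvs$sd_acc, 0)

  # label-shuffled, balanced: accuracy near 0.5
  set.seed(12)
  shuf <- feature_rows(400, seed = 12)
  shuf$label <- sample(rep(c("ASD", "TDC"), 200))
  cvn <- kfold_cv(shuf, k = 10, seed = 4)
  expect_lt(abs(cvn$mean_acc - 0.5), 0.1)

  expect_error(kfold_cv(rows[1:12, ], k = 10), "smallest class")
})

test_that("ROC/AUC follows the trapezoid rule, its symmetry, and pROC agrees", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels)$auc, 1)
  expect_equal(roc_auc(-scores, labels)$auc, 0)

  set.seed(13)
  s <- runif(300); l <- runif(300) < 0.5
  r1 <- roc_auc(s, l)
  expect_equal(r1$auc + roc_auc(-s, l)$auc, 1, tolerance = 1e-9)
  expect_lt(abs(r1$auc - 0.5), 0.08)
  # independent implementation
  ref <- suppressMessages(pROC::auc(pROC::roc(
    l, s, quiet = TRUE, levels = c(FALSE, TRUE), direction = "<")))
  expect_equal(r1$auc, as.numeric(ref), tolerance = 1e-9)
  expect_error(roc_auc(s, rep(TRUE, 300)), "both classes")
})

test_that("odds ratios are the closed-form exp(coef * delta) with symmetry", {
  rows <- feature_rows(500, seed = 14)
  fit <- fit_logistic(rows)
  b <- fit$coefficients
  expect_equal(odds_ratio_per_delta(fit, "rate", -0.1), exp(-0.1 * b[["rate"]]))
  expect_equal(odds_ratio_per_delta(fit, "events", 1) *
                 odds_ratio_per_delta(fit, "events", -1), 1)
  fit0 <- fit
  fit0$coefficients["rate"] <- 0
  expect_equal(odds_ratio_per_delta(fit0, "rate", -0.5), 1)
  expect_error(odds_ratio_per_delta(fit, "nope", 1), "unknown feature")
})

test_that("diagnostics match glm-based references and flag planted pathologies", {
  rows <- feature_rows(500, seed = 15)
  fit <- fit_logistic(rows)
  d <- logit_diagnostics(fit)
  ref <- glm(I(label == "ASD") ~ avg_valid_sampling_rate + n_events_total,
             data = rows, family = binomial())
  expect_equal(d$per_obs$cooks_distance, unname(cooks.distance(ref)),
               tolerance = 1e-4)
  expect_equal(d$per_obs$std_residual,
               unname(residuals(ref, "pearson") / sqrt(1 - hatvalues(ref))),
               tolerance = 1e-4)
  # two-feature closed form: VIF = 1 / (1 - cor^2)
  r2 <- cor(rows$avg_valid_sampling_rate, rows$n_events_total)^2
  expect_equal(unname(d$vif), rep(1 / (1 - r2), 2), tolerance = 1e-9)
  expect_true(all(d$vif >= 1))

  # two independent features: VIF close to 1
  expect_lt(max(d$vif), 1.1)

  # a gross x-outlier owns the largest Cook's distance
  out_rows <- rows
  out_rows$n_events_total[7] <- 400
  fo <- fit_logistic(out_rows)
  do <- logit_diagnostics(fo)
  expect_equal(which.max(do$per_obs$cooks_distance), 7L)

  # exact collinearity is reported as infinite VIF
  col_rows <- rows
  col_rows$n_events_total <- 100 * col_rows$avg_valid_sampling_rate
  suppressWarnings({
    fc <- fit_logistic(col_rows)
    dc <- logit_diagnostics(fc)
  })
  expect_true(is.infinite(max(dc$vif)))
})

test_that("evaluate_classifier ties the protocol together with tidy output", {
  rows <- feature_rows(300, seed = 16)
  ev <- evaluate_classifier(rows, seed = 3)
  expect_s3_class(ev, "rja_eval")
  expect_true(ev$auc > 0.5)                  # planted ASD-lower separation
  expect_true(all(coef(ev$fit)[c("rate", "events")] < 0))
  expect_equal(nrow(ev$odds_ratios), 2)
  expect_true(all(predict(ev$fit) > 0 & predict(ev$fit) < 1))
  g <- glance(ev)
  expect_true(g$test_accuracy >= 0 && g$test_accuracy <= 1)
  td <- tidy(ev$fit)
  expect_equal(td$term, c("(Intercept)", "rate", "events"))
  expect_s3_class(autoplot(structure(list(auc = ev$auc,
                                          roc = ev$roc),
                                     class = "rja_roc")), "ggplot")
})
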