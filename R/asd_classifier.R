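#' Fit the two-feature logistic classifier
#'
#' Maximum-likelihood logistic regression of diagnostic group on the
#' average valid sampling rate and the total RJA event count, fitted by
#' iteratively reweighted least squares (IRLS). Convergence is declared
#' when the largest coefficient change falls below `tol` (default 1e-8)
#' or after `max_iter` iterations. Complete separation is detected
#' (diverging coefficients with vanishing deviance) and reported as a
#' distinct status rather than returned as silently huge coefficients.
#'
#' @param rows A feature tibble with columns `avg_valid_sampling_rate`,
#'   `n_events_total` and `label` (factor/character; the positive class
#'   is `positive`).
#' @param positive Label modelled as the outcome 1 (default `"ASD"`).
#' @param tol,max_iter IRLS convergence controls.
#' @return An object of class `rja_logit`: coefficients (intercept,
#'   rate, events), standard errors, fitted probabilities, IRLS weights,
#'   the model matrix, deviance, convergence status.
#' @export
fit_logistic <- function(rows, positive = "ASD", tol = 1e-8, max_iter = 100) {
  y <- as.integer(rows$label == positive)
  if (length(unique(y)) < 2) {
    stop("both classes must be present to fit the classifier", call. = FALSE)
  }
  if (nrow(rows) < 10) stop("need at least 10 rows", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             rate = rows$avg_valid_sampling_rate,
             events = rows$n_events_total)
  if (any(!is.finite(X))) stop("missing or non-finite features", call. = FALSE)
  b <- rep(0, ncol(X))
  loglik <- -Inf
  status <- "max-iterations"
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    b_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                      error = function(e) NULL)
    if (is.null(b_new)) { status <- "singular"; break }
    delta <- max(abs(b_new - b))
    b <- b_new
    loglik <- sum(y * stats::plogis(drop(X %*% b), log.p = TRUE) +
                    (1 - y) * stats::plogis(-drop(X %*% b), log.p = TRUE))
    if (max(abs(b)) > 1e3 || max(abs(drop(X %*% b))) > 30) {
      # fitted log-odds diverging: data are (quasi-)separated
      status <- "separated"
      break
    }
    if (delta < tol) { status <- "converged"; break }
  }
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov_b <- tryCatch(solve(t(X * w) %*% X), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(cov_b), 0))
  names(b) <- names(se) <- colnames(X)
  structure(
    list(
      coefficients = b, se = se, cov = cov_b,
      fitted = mu, weights = w, X = X, y = y,
      deviance = -2 * sum(y * log(pmax(mu, 1e-300)) +
                            (1 - y) * log(pmax(1 - mu, 1e-300))),
      n = length(y), n_iterations = it, status = status,
      converged = status == "converged", positive = positive
    ),
    class = "rja_logit"
  )
}

#' @export
print.rja_logit <- function(x, ...) {
  cat(sprintf("<rja_logit> n=%d status=%s iters=%d\n", x$n, x$status,
              x$n_iterations))
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.rja_logit <- function(object, ...) object$coefficients

#' Predicted class-1 probabilities from a fitted classifier
#' @param object An `rja_logit` fit.
#' @param newdata Feature tibble (same columns as in [fit_logistic()]);
#'   the training data if omitted.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.rja_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, newdata$avg_valid_sampling_rate, newdata$n_events_total)
  stats::plogis(drop(X %*% object$coefficients))
}

#' Stratified train/test split
#'
#' Randomly assigns `test_frac` of each class to the test set, so class
#' ratios are preserved (a cohort of 143 + 113 at 20% yields a 29 + 23
#' test set). Deterministic for a fixed seed.
#'
#' @param rows Feature tibble with a `label` column.
#' @param test_frac Fraction held out (0 < test_frac < 1).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(rows, test_frac = 0.20, seed = 1) {
  if (!is.finite(test_frac) || test_frac <= 0 || test_frac >= 1) {
    stop("test_frac must be in (0, 1)", call. = FALSE)
  }
  counts <- table(rows$label)
  if (any(counts < 2)) stop("every class needs at least 2 members", call. = FALSE)
  set.seed(seed)
  test_idx <- unlist(lapply(names(counts), function(lv) {
    idx <- which(rows$label == lv)
    sample(idx, round(length(idx) * test_frac))
  }))
  list(train = rows[-test_idx, , drop = FALSE],
       test = rows[test_idx, , drop = FALSE])
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits the training rows into k stratified folds, refits the model
#' on each complement and scores held-out accuracy at the 0.5
#' probability threshold.
#'
#' @param train Feature tibble.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param positive Positive-class label.
#' @return List: `mean_acc`, `sd_acc`, `per_fold` (tibble with `fold`,
#'   `n_test`, `accuracy`).
#' @export
kfold_cv <- function(train, k = 10, seed = 1, positive = "ASD") {
  counts <- table(train$label)
  if (k > min(counts)) {
    stop("k exceeds the size of the smallest class", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(train))
  for (lv in names(counts)) {
    idx <- sample(which(train$label == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  per_fold <- lapply(seq_len(k), function(f) {
    fit <- fit_logistic(train[fold != f, , drop = FALSE], positive = positive)
    held <- train[fold == f, , drop = FALSE]
    pred <- predict(fit, held) >= 0.5
    tibble::tibble(fold = f, n_test = nrow(held),
                   accuracy = mean(pred == (held$label == positive)))
  })
  per_fold <- dplyr::bind_rows(per_fold)
  list(mean_acc = mean(per_fold$accuracy),
       sd_acc = stats::sd(per_fold$accuracy),
       per_fold = per_fold)
}

#' ROC curve and AUC
#'
#' Full threshold sweep over the scores; the AUC is computed by the
#' trapezoidal rule and equals the rank-based (Mann-Whitney) probability
#' that a random positive scores above a random negative.
#'
#' @param scores Predicted probabilities or any monotone scores.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return List: `auc`, `roc` (tibble `threshold`, `fpr`, `tpr`),
#'   class `rja_roc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ROC", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  # one ROC point per distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  roc <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, tp[keep] / sum(l)),
    fpr = c(0, fp[keep] / sum(!l))
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(auc = auc, roc = roc), class = "rja_roc")
}

#' Odds ratio per feature change
#'
#' The multiplicative change in the odds of the positive class for a
#' change of `delta` in one feature: `exp(coef * delta)`. With the
#' fitted signs negative on both features, a 0.1 drop in sampling rate
#' or one fewer event raises the odds of ASD.
#'
#' @param fit An `rja_logit` fit.
#' @param feature `"rate"` or `"events"`.
#' @param delta Change in the feature's own units.
#' @return The odds ratio.
#' @export
odds_ratio_per_delta <- function(fit, feature, delta) {
  if (!feature %in% names(fit$coefficients)[-1]) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  exp(unname(fit$coefficients[feature]) * delta)
}

#' Regression diagnostics for the fitted classifier
#'
#' Per-observation influence and collinearity checks computed from the
#' IRLS weights: standardized Pearson residuals, Cook's distances, the
#' variance-inflation factor of each feature (from regressing it on the
#' others), and a logit-linearity check comparing the deviance of the
#' linear model with a quartile-binned version of each feature.
#'
#' @param fit An `rja_logit` fit.
#' @return List: `per_obs` (tibble `pearson_residual`,
#'   `std_residual`, `cooks_distance`, `leverage`), `max_cooks`,
#'   `max_abs_std_residual`, `vif` (named; `Inf` flags exact
#'   collinearity), `linearity` (tibble per feature: deviance drop and
#'   chi-square p of the binned model against the linear one).
#' @export
logit_diagnostics <- function(fit) {
  X <- fit$X; w <- fit$weights; y <- fit$y; mu <- fit$fitted
  p <- ncol(X)
  if (fit$n < p + 2) stop("too few rows for diagnostics", call. = FALSE)
  XtWX_inv <- fit$cov
  # hat diagonal of the weighted least-squares smoother
  h <- rowSums((X %*% XtWX_inv) * X) * w
  h <- pmin(h, 1 - 1e-10)
  pr <- (y - mu) / sqrt(w)
  std <- pr / sqrt(1 - h)
  cooks <- pr^2 * h / (p * (1 - h)^2)
  feats <- X[, -1, drop = FALSE]
  vif <- vapply(seq_len(ncol(feats)), function(j) {
    r2 <- summary(stats::lm(feats[, j] ~ feats[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(feats)
  linearity <- dplyr::bind_rows(lapply(colnames(feats), function(nm) {
    xj <- feats[, nm]
    br <- unique(stats::quantile(xj, probs = seq(0, 1, 0.25)))
    if (length(br) < 3) {
      return(tibble::tibble(feature = nm, deviance_drop = NA_real_,
                            df = NA_real_, p = NA_real_))
    }
    binned <- cut(xj, breaks = br, include.lowest = TRUE)
    others <- feats[, setdiff(colnames(feats), nm), drop = FALSE]
    d_lin <- stats::glm(y ~ xj + others, family = stats::binomial())$deviance
    d_bin <- stats::glm(y ~ binned + others, family = stats::binomial())$deviance
    df <- length(levels(binned)) - 2
    drop_dev <- d_lin - d_bin
    tibble::tibble(feature = nm, deviance_drop = drop_dev, df = df,
                   p = stats::pchisq(max(drop_dev, 0), df, lower.tail = FALSE))
  }))
  list(
    per_obs = tibble::tibble(pearson_residual = pr, std_residual = std,
                             cooks_distance = cooks, leverage = h),
    max_cooks = max(cooks),
    max_abs_std_residual = max(abs(std)),
    vif = vif,
    linearity = linearity
  )
}

#' Evaluate the classifier end to end
#'
#' Convenience wrapper reproducing the full evaluation protocol:
#' stratified 80/20 split, fit on the training set, accuracy on both
#' sets at threshold 0.5, stratified 10-fold cross-validation on the
#' training set, ROC/AUC on the test set, decile calibration bins of
#' the predicted probabilities, and regression diagnostics.
#'
#' @param rows Feature tibble (`avg_valid_sampling_rate`,
#'   `n_events_total`, `label`).
#' @param test_frac,k,seed,positive Protocol parameters.
#' @return An `rja_eval` list with the fitted model, accuracies, CV
#'   summary, ROC, calibration bins and diagnostics; `seed` is recorded.
#' @export
evaluate_classifier <- function(rows, test_frac = 0.20, k = 10, seed = 1,
                                positive = "ASD") {
  sp <- split_train_test(rows, test_frac, seed)
  fit <- fit_logistic(sp$train, positive = positive)
  acc <- function(d) mean((predict(fit, d) >= 0.5) == (d$label == positive))
  cv <- kfold_cv(sp$train, k = k, seed = seed, positive = positive)
  test_scores <- predict(fit, sp$test)
  roc <- roc_auc(test_scores, sp$test$label == positive)
  all_scores <- predict(fit, rows)
  bins <- cut(all_scores, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  calibration <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bins,
                                   asd = rows$label == positive,
                                   score = all_scores), .data$bin),
    n = dplyr::n(), mean_predicted = mean(.data$score),
    observed_fraction = mean(.data$asd), .groups = "drop"
  )
  structure(
    list(fit = fit, train_accuracy = acc(sp$train), test_accuracy = acc(sp$test),
         cv_mean = cv$mean_acc, cv_sd = cv$sd_acc, cv_per_fold = cv$per_fold,
         auc = roc$auc, roc = roc$roc, calibration = calibration,
         diagnostics = logit_diagnostics(fit),
         odds_ratios = tibble::tibble(
           effect = c("per -0.1 sampling rate", "per +1 event"),
           odds_ratio = c(odds_ratio_per_delta(fit, "rate", -0.1),
                          odds_ratio_per_delta(fit, "events", 1))
         ),
         n_train = nrow(sp$train), n_test = nrow(sp$test), seed = seed),
    class = "rja_eval"
  )
}

#' @export
print.rja_eval <- function(x, ...) {
  cat(sprintf(
    "<rja_eval> train acc %.3f | test acc %.3f | CV %.3f +/- %.3f | AUC %.3f (seed %d)\n",
    x$train_accuracy, x$test_accuracy, x$cv_mean, x$cv_sd, x$auc, x$seed))
  invisible(x)
}
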