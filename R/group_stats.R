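#' Percent agreement between two raters
#'
#' @param ratings_a,ratings_b Equal-length vectors of categorical
#'   judgments (e.g. event present/absent per clip).
#' @return Fraction of items on which the raters agree.
#' @export
percent_agreement <- function(ratings_a, ratings_b) {
  check_ratings(ratings_a, ratings_b)
  mean(ratings_a == ratings_b)
}

check_ratings <- function(a, b) {
  if (length(a) != length(b)) stop("rating vectors differ in length", call. = FALSE)
  if (length(a) == 0) stop("empty rating vectors", call. = FALSE)
  invisible(NULL)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' the expected agreement `p_e` from the product of the raters' marginal
#' category frequencies. When both raters are constant and identical
#' (`p_e = 1` with perfect agreement) kappa is reported as 1; a
#' degenerate `p_e = 1` without perfect agreement is `NA`.
#'
#' @param ratings_a,ratings_b Equal-length categorical vectors.
#' @return A one-row tibble: `n_items`, `n_agree`, `percent_agreement`,
#'   `kappa`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  check_ratings(ratings_a, ratings_b)
  n <- length(ratings_a)
  p_o <- mean(ratings_a == ratings_b)
  lev <- union(unique(ratings_a), unique(ratings_b))
  pa <- table(factor(ratings_a, levels = lev)) / n
  pb <- table(factor(ratings_b, levels = lev)) / n
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  kappa <- if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) 1 else NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  tibble::tibble(n_items = n, n_agree = as.integer(round(p_o * n)),
                 percent_agreement = p_o, kappa = kappa)
}

#' Mann-Whitney U test with effect-size r
#'
#' Two-sided rank-sum test between two independent samples. The U
#' statistic is the count of pairs where x precedes y (ties counted
#' half). The z statistic uses the normal approximation with tie
#' correction and an optional continuity correction; the effect size is
#' `r = |z| / sqrt(n1 + n2)`. For small samples (both n <= 20) without
#' ties the p-value is exact (from the Wilcoxon distribution); otherwise
#' the normal approximation is used.
#'
#' @param x,y Numeric samples.
#' @param continuity Apply the 0.5 continuity correction to z (default
#'   `TRUE`).
#' @return A one-row tibble: `n1`, `n2`, `U`, `z`, `p`, `r`, `method`.
#' @export
mann_whitney_r <- function(x, y, continuity = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  mu <- n1 * n2 / 2
  cc <- if (continuity) sign(U - mu) * 0.5 else 0
  z <- if (sigma == 0) 0 else (U - mu - cc) / sigma
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 20 && n2 <= 20) {
    p <- if (U > mu) {
      min(1, 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    } else {
      min(1, 2 * stats::pwilcox(U, n1, n2))
    }
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approx"
  }
  tibble::tibble(n1 = n1, n2 = n2, U = U, z = z, p = p,
                 r = abs(z) / sqrt(N), method = method)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more
#' likely than the observed one — the convention of mainstream
#' statistical environments.
#'
#' @param table A 2x2 non-negative integer matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Spearman correlations with Benjamini-Hochberg correction
#'
#' Runs a batch of Spearman correlations (midranks for ties) and
#' adjusts the p-values by the Benjamini-Hochberg step-up procedure
#' across the batch.
#'
#' @param batches A list of lists/tibbles, each with `label`, `x`, `y`;
#'   or a tibble with columns `label`, `x`, `y` grouped by `label`.
#' @return A tibble: `label`, `n`, `rho`, `p`, `q`.
#' @export
spearman_bh <- function(batches) {
  if (is.data.frame(batches)) {
    batches <- lapply(split(batches, batches$label), function(d) {
      list(label = d$label[1], x = d$x, y = d$y)
    })
  }
  rows <- lapply(batches, function(b) {
    ok <- is.finite(b$x) & is.finite(b$y)
    x <- b$x[ok]; y <- b$y[ok]
    if (length(x) < 3) stop("fewer than 3 complete pairs for '", b$label, "'",
                            call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    tibble::tibble(label = b$label, n = length(x),
                   rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Linear age trend of event counts
#'
#' Ordinary least squares of event counts on age, with the two-sided
#' t-test on the slope. Used to describe how joint-attention performance
#' progresses across developmental age within a group.
#'
#' @param ages Ages in years.
#' @param counts Event counts (or any numeric outcome).
#' @return A one-row tibble: `slope` (events/year), `intercept`,
#'   `p_slope`, `r_squared`, `n`.
#' @export
linear_age_trend <- function(ages, counts) {
  ok <- is.finite(ages) & is.finite(counts)
  ages <- ages[ok]; counts <- counts[ok]
  if (length(ages) < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(ages) == 0) stop("no variance in age", call. = FALSE)
  fit <- stats::lm(counts ~ ages)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_slope = sm$coefficients[2, 4],
    r_squared = sm$r.squared,
    n = length(ages)
  )
}
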