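#' Ratings table for agreement statistics
#'
#' @param counts numeric `n x k` matrix: `n` specimens (rows) rated by `k`
#'   raters or repeats (columns); no missing cells, counts >= 0.
#' @return Validated numeric matrix of class `ratings_table` with dimnames
#'   filled in.
#' @export
ratings_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    validation_error("a ratings table needs >= 2 specimens and >= 2 raters")
  if (anyNA(counts)) validation_error("ratings table has missing cells")
  if (any(counts < 0)) validation_error("counts must be >= 0")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("specimen", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("rater", seq_len(ncol(counts)))
  structure(counts, class = c("ratings_table", class(counts)))
}

#' Two-way random-effects intraclass correlation (absolute agreement,
#' single measures)
#'
#' The ICC(2,1) of Shrout & Fleiss, the usual SPSS choice for method
#' comparison. From the two-way ANOVA mean squares (rows = specimens,
#' columns = raters):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' The p-value tests ICC = 0 via `F = MS_R / MS_E` on
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param table a [ratings_table()] (or coercible matrix).
#' @return List of class `icc_result`: `icc`, `p_value`, `model`
#'   (descriptor string), `ms` (named mean squares `MS_R`, `MS_C`,
#'   `MS_E`), `n`, `k`.
#' @examples
#' tab <- ratings_table(cbind(a = c(1, 5, 9), b = c(1, 5, 9)))
#' icc_two_way(tab)$icc # 1: identical raters
#' @export
icc_two_way <- function(table) {
  x <- unclass(ratings_table(table))
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  if (ss_total == 0)
    validation_error("ratings table is constant; ICC undefined")
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- max(ss_err, 0) / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) /
    (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  f <- if (ms_e == 0) Inf else ms_r / ms_e
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, p_value = p,
                 model = "two-way random effects, absolute agreement, single measures (ICC(2,1))",
                 ms = c(MS_R = ms_r, MS_C = ms_c, MS_E = ms_e),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f (p = %.4g)\n  %s\n  n = %d specimens, k = %d raters\n",
              x$icc, x$p_value, x$model, x$n, x$k))
  invisible(x)
}

#' Coefficient of variation between two counts, in percent
#'
#' `100 * SD / mean` of the pair, with the sample SD (n-1 denominator);
#' equivalently `100 * sqrt(2) * |a - b| / (a + b)`.
#'
#' @param count_a,count_b the two repeat counts; their sum must be > 0.
#' @return CV in percent.
#' @examples
#' cv_percent(5, 15) # 70.71068
#' @export
cv_percent <- function(count_a, count_b) {
  if (count_a + count_b <= 0)
    validation_error("CV undefined: both counts are zero")
  100 * stats::sd(c(count_a, count_b)) / mean(c(count_a, count_b))
}

#' Bland-Altman agreement analysis
#'
#' Per-specimen differences `a - b` against means `(a + b) / 2`, with 95%
#' limits of agreement `mean difference +/- 1.96 * SD(differences)`.
#'
#' @param pairs two-column matrix/data.frame of paired measurements
#'   (method a, method b), >= 2 pairs.
#' @return List of class `bland_altman_result`: `mean_difference`,
#'   `sd_difference`, `upper_limit`, `lower_limit`, and `points`
#'   (data.frame `mean`, `difference`).
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L || ncol(pairs) != 2L || anyNA(pairs))
    validation_error("`pairs` must be a complete n x 2 matrix with n >= 2")
  d <- pairs[, 1] - pairs[, 2]
  m <- (pairs[, 1] + pairs[, 2]) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_difference = md, sd_difference = sdd,
                 upper_limit = md + 1.96 * sdd,
                 lower_limit = md - 1.96 * sdd,
                 points = data.frame(mean = m, difference = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, 95%% limits [%.4g, %.4g] (n = %d)\n",
              x$mean_difference, x$lower_limit, x$upper_limit,
              nrow(x$points)))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided test on the differences `a - b`. Zero differences are dropped
#' (Wilcoxon's rule), tied absolute differences receive midranks, and the
#' statistic is the sum of ranks of the positive differences. For up to
#' `exact_max` informative pairs the p-value is exact, from the full null
#' distribution over all sign assignments (computed by dynamic programming,
#' valid under ties); above that a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param pairs two-column matrix/data.frame of paired measurements.
#' @param exact_max enumeration threshold (default 25 informative pairs).
#' @return List of class `wilcoxon_result`: `statistic` (V, sum of
#'   positive ranks), `p_value`, `n_informative`, `method` (`"exact"` or
#'   `"normal"`).
#' @export
wilcoxon_signed_rank <- function(pairs, exact_max = 25L) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L || ncol(pairs) != 2L || anyNA(pairs))
    validation_error("`pairs` must be a complete n x 2 matrix with n >= 2")
  d <- pairs[, 1] - pairs[, 2]
  d <- d[d != 0]
  if (length(d) == 0L)
    validation_error("all paired differences are zero; test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= exact_max) {
    # null distribution of 2V by DP over doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    prob <- numeric(tot + 1L) # index s+1 holds P(2V = s) * 2^n
    prob[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), prob[seq_len(tot + 1L - ri)])
      prob <- prob + shifted
    }
    prob <- prob / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(prob[seq_len(v2 + 1L)])
    p_ge <- sum(prob[(v2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(statistic = v, p_value = p, n_informative = n,
                 method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: V = %g, p = %.4g (%s, n = %d)\n",
              x$statistic, x$p_value, x$method, x$n_informative))
  invisible(x)
}

#' Generate a synthetic ratings table with known variance components
#'
#' `count_ij = round(max(0, mean + b_i + e_ij))` with specimen effects
#' `b_i ~ N(0, sigma_between^2)` and noise `e_ij ~ N(0, sigma_within^2)`.
#' The population single-measure ICC of this model is
#' `sigma_between^2 / (sigma_between^2 + sigma_within^2)`.
#'
#' @param n_specimens,k_raters table dimensions (>= 2 each).
#' @param sigma_between,sigma_within standard deviations (>= 0).
#' @param mean grand mean count.
#' @param seed integer seed.
#' @return A [ratings_table()].
#' @export
generate_ratings <- function(n_specimens, k_raters, sigma_between,
                             sigma_within, mean = 50, seed = 1L) {
  if (n_specimens < 2L || k_raters < 2L)
    validation_error("need n_specimens >= 2 and k_raters >= 2")
  if (sigma_between < 0 || sigma_within < 0)
    validation_error("sigmas must be >= 0")
  with_seed(seed, {
    b <- stats::rnorm(n_specimens, 0, sigma_between)
    e <- matrix(stats::rnorm(n_specimens * k_raters, 0, sigma_within),
                n_specimens, k_raters)
    counts <- round(pmax(mean + b + e, 0)) # first arg keeps the dim
    ratings_table(counts)
  })
}
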