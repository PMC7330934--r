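test_that("ratings_table validates shape and content", {
  expect_error(ratings_table(matrix(1:2, 1, 2)),
               class = "ihcquant_validation_error")
  expect_error(ratings_table(matrix(c(1, NA, 3, 4), 2, 2)),
               class = "ihcquant_validation_error")
  expect_error(ratings_table(matrix(c(-1, 2, 3, 4), 2, 2)),
               class = "ihcquant_validation_error")
  tab <- ratings_table(matrix(c(1, 5, 9, 1, 5, 9), 3, 2))
  expect_equal(dim(tab), c(3L, 2L))
})

test_that("ICC(2,1): perfect agreement gives 1, constant table errors", {
  tab <- ratings_table(cbind(c(1, 5, 9), c(1, 5, 9)))
  r <- icc_two_way(tab)
  expect_equal(r$icc, 1)
  expect_equal(r$p_value, 0)
  expect_equal(unname(r$ms["MS_E"]), 0)
  expect_error(icc_two_way(matrix(5, 3, 2)),
               class = "ihcquant_validation_error")
})

test_that("ICC matches the ANOVA decomposition on a hand-checked table", {
  x <- cbind(a = c(9, 6, 8, 7, 10, 6), b = c(2, 1, 4, 1, 5, 2))
  n <- 6; k <- 2
  # independent recomputation via aov()
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(1:n, k)),
                   rater = factor(rep(1:k, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expected <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  r <- icc_two_way(ratings_table(x))
  expect_equal(r$icc, expected)
  expect_equal(unname(r$ms), c(msr, msc, mse))
  expect_equal(r$p_value,
               stats::pf(msr / mse, n - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE))
})

test_that("ICC is invariant under permutation, shift and positive scaling", {
  set.seed(5)
  for (i in 1:5) {
    x <- matrix(rpois(8 * 3, 40), 8, 3)
    base <- icc_two_way(ratings_table(x))$icc
    expect_equal(icc_two_way(ratings_table(x[, c(3, 1, 2)]))$icc, base)
    expect_equal(icc_two_way(ratings_table(x[sample(8), ]))$icc, base)
    expect_equal(icc_two_way(ratings_table(x + 7))$icc, base)
    expect_equal(icc_two_way(ratings_table(x * 2.5))$icc, base)
  }
})

test_that("ICC recovers known variance components in simulation", {
  # population ICC = 100 / (100 + 25) = 0.8
  iccs <- vapply(1:200, function(s)
    icc_two_way(generate_ratings(50, 2, 10, 5, mean = 50, seed = s))$icc,
    numeric(1))
  expect_lt(abs(mean(iccs) - 0.8), 0.03)

  # independent columns: ICC centred on 0
  iccs0 <- vapply(1:200, function(s)
    icc_two_way(generate_ratings(50, 2, 0, 10, mean = 50, seed = 1000 + s))$icc,
    numeric(1))
  expect_lt(abs(mean(iccs0)), 0.05)
})

test_that("cv_percent matches the closed form and the SD/mean oracle", {
  expect_equal(cv_percent(10, 10), 0)
  expect_equal(cv_percent(5, 15), 100 * sqrt(2) * 10 / 20)
  expect_equal(round(cv_percent(5, 15), 2), 70.71)
  set.seed(2)
  for (i in 1:20) {
    ab <- runif(2, 0, 100)
    expect_equal(cv_percent(ab[1], ab[2]),
                 100 * stats::sd(ab) / base::mean(ab))
  }
  expect_error(cv_percent(0, 0), class = "ihcquant_validation_error")
})

test_that("Bland-Altman limits equal mean +/- 1.96 SD of differences", {
  same <- cbind(c(3, 7, 9), c(3, 7, 9))
  r <- bland_altman(same)
  expect_equal(r$mean_difference, 0)
  expect_equal(r$upper_limit, 0)
  expect_equal(r$lower_limit, 0)

  off <- cbind(c(3, 7, 9), c(3, 7, 9) - 4) # constant offset 4
  r2 <- bland_altman(off)
  expect_equal(r2$mean_difference, 4)
  expect_equal(r2$sd_difference, 0)
  expect_equal(r2$upper_limit, 4)
  expect_equal(r2$lower_limit, 4)

  set.seed(8)
  pairs <- matrix(rpois(24, 30), 12, 2)
  r3 <- bland_altman(pairs)
  d <- pairs[, 1] - pairs[, 2]
  expect_equal(r3$upper_limit, mean(d) + 1.96 * sqrt(sum((d - mean(d))^2) / 11))
  expect_equal(r3$lower_limit, mean(d) - 1.96 * sqrt(sum((d - mean(d))^2) / 11))
  expect_equal(r3$points$mean, rowMeans(pairs))

  expect_error(bland_altman(cbind(1, 2)), class = "ihcquant_validation_error")
})

test_that("Wilcoxon signed-rank: exact small-sample behaviour", {
  # all 6 differences positive: p = 2 / 2^6
  r <- wilcoxon_signed_rank(cbind(11:16, 1:6))
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, 2 * (1 / 2^6))
  expect_equal(r$method, "exact")

  # symmetric swapped values: statistic at the null centre, p = 1
  sym <- rbind(c(10, 14), c(14, 10), c(20, 27), c(27, 20))
  rs <- wilcoxon_signed_rank(sym)
  expect_equal(rs$p_value, 1)

  expect_error(wilcoxon_signed_rank(cbind(c(1, 2), c(1, 2))),
               class = "ihcquant_validation_error")
})

test_that("Wilcoxon agrees with the full 2^n enumeration oracle", {
  set.seed(17)
  for (i in 1:10) {
    pairs <- matrix(sample(0:30, 16, replace = TRUE), 8, 2)
    if (all(pairs[, 1] == pairs[, 2])) next
    mine <- wilcoxon_signed_rank(pairs)
    oracle <- wilcoxon_oracle(pairs)
    expect_equal(mine$statistic, oracle$statistic)
    expect_equal(mine$p_value, oracle$p_value)
  }
})

test_that("normal approximation is close to the exact p beyond the cutoff", {
  set.seed(23)
  pairs <- matrix(rpois(60, 20) + rep(c(0, 2), each = 30), 30, 2)
  ex <- wilcoxon_signed_rank(pairs, exact_max = 40L)
  ap <- wilcoxon_signed_rank(pairs, exact_max = 25L)
  expect_equal(ap$method, "normal")
  expect_equal(ap$p_value, ex$p_value, tolerance = 0.05)
})

test_that("generate_ratings hits its stated variance-component world", {
  t1 <- generate_ratings(6, 2, 10, 0, mean = 50, seed = 3)
  expect_equal(unname(t1[, 1]), unname(t1[, 2])) # sigma_within = 0
  expect_equal(icc_two_way(t1)$icc, 1)
  expect_identical(generate_ratings(6, 2, 10, 5, seed = 9),
                   generate_ratings(6, 2, 10, 5, seed = 9))
  expect_error(generate_ratings(1, 2, 1, 1),
               class = "ihcquant_validation_error")
  expect_error(generate_ratings(5, 2, -1, 1),
               class = "ihcquant_validation_error")
})
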