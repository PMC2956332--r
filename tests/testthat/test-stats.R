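test_that("the published two-proportion contrasts are reproduced exactly", {
  cmp <- proportion_difference(64, 1062, 79, 1037)
  expect_equal(round(cmp$diff_pct, 1), -1.6)
  expect_equal(round(cmp$ci_low_pct, 2), -3.75)
  expect_equal(round(cmp$ci_high_pct, 2), 0.57)
  expect_equal(cmp$chi2, 2.0940, tolerance = 1e-4)
  expect_equal(round(cmp$p_value, 2), 0.15)

  cmp <- proportion_difference(29, 1062, 42, 1037)
  expect_equal(round(c(cmp$ci_low_pct, cmp$ci_high_pct), 2), c(-2.87, 0.23))

  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$diff_pct, cmp$diff_pct)
  expect_equal(glance(cmp)$p.value, cmp$p_value)
})

test_that("identical groups give a null, symmetric contrast", {
  cmp <- proportion_difference(15, 80, 15, 80)
  expect_equal(cmp$diff_pct, 0)
  expect_equal(cmp$ci_low_pct, -cmp$ci_high_pct)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("swapping the groups negates the difference and reflects the CI", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n1 <- sample(5:400, 1); n2 <- sample(5:400, 1)
      x1 <- rbinom(1, n1, runif(1)); x2 <- rbinom(1, n2, runif(1))
      a <- proportion_difference(x1, n1, x2, n2)
      b <- proportion_difference(x2, n2, x1, n1)
      expect_equal(b$diff_pct, -a$diff_pct)
      expect_equal(b$ci_low_pct, -a$ci_high_pct)
      expect_equal(b$ci_high_pct, -a$ci_low_pct)
      expect_equal(b$chi2, a$chi2)
      expect_equal(b$p_value, a$p_value)
    }
  })
})

test_that("the Pearson statistic matches chisq.test and the squared pooled z", {
  withr::with_seed(7, {
    for (i in 1:40) {
      n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
      x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
      x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
      ours <- pearson_chi_square(x1, n1, x2, n2)
      if (ours$degenerate) next
      ref <- suppressWarnings(
        chisq.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE),
                   correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      # chi-square equals the square of the pooled-variance z statistic
      p1 <- x1 / n1; p2 <- x2 / n2; pb <- (x1 + x2) / (n1 + n2)
      z <- (p1 - p2) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
      expect_equal(ours$statistic, z^2, tolerance = 1e-10)
    }
  })
})

test_that("degenerate tables are flagged instead of dividing by zero", {
  res <- pearson_chi_square(0, 50, 0, 60)
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  cmp <- proportion_difference(0, 50, 0, 60)
  expect_true(cmp$degenerate)
  expect_equal(cmp$ci_low_pct, cmp$ci_high_pct)
  expect_error(proportion_difference(5, 0, 1, 10), "positive")
  expect_error(proportion_difference(11, 10, 1, 10), "0 <= x <= n")
})

test_that("chi-square p agrees with a label-permutation oracle on small tables", {
  # The permutation null is discrete; the asymptotic chi-square p estimates
  # its mid-p (half the atom at the observed table), so that is the
  # comparable quantity. Tolerance: 3 MC standard errors plus a small
  # allowance for the chi-square approximation itself at these sizes.
  perm_mid_p <- function(x1, n1, x2, n2, B, seed) {
    obs <- pearson_chi_square(x1, n1, x2, n2)$statistic
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    events <- c(rep(TRUE, x1), rep(FALSE, n1 - x1),
                rep(TRUE, x2), rep(FALSE, n2 - x2))
    withr::with_seed(seed, {
      stats <- vapply(seq_len(B), function(i) {
        lab <- sample(labels)
        pearson_chi_square(sum(events & lab), n1, sum(events & !lab), n2)$statistic
      }, numeric(1))
    })
    mean(stats > obs + 1e-12) + 0.5 * mean(abs(stats - obs) <= 1e-12)
  }
  cases <- list(c(12, 30, 19, 30), c(10, 40, 18, 45), c(20, 60, 30, 55))
  B <- 4000
  for (cs in cases) {
    p_perm <- perm_mid_p(cs[1], cs[2], cs[3], cs[4], B = B, seed = sum(cs))
    p_chi <- pearson_chi_square(cs[1], cs[2], cs[3], cs[4])$p_value
    mc_se <- sqrt(p_perm * (1 - p_perm) / B)
    expect_lt(abs(p_chi - p_perm), 3 * mc_se + 0.02)
  }
})

test_that("Welch contrasts match t.test and behave under translation", {
  x <- c(5.1, 5.9, 6.3, 4.8, 5.5, 6.0)
  same <- mean_difference_raw(x, x)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  y <- x + 0.7
  shifted <- mean_difference_raw(x, y)
  expect_equal(shifted$diff, -0.7)

  withr::with_seed(11, {
    a <- rnorm(40, 5.5, 1.2)
    b <- rnorm(55, 5.2, 1.6)
  })
  ours <- mean_difference_raw(a, b)
  ref <- t.test(a, b)
  expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int))
  expect_equal(ours$p_value, ref$p.value)
  # missing values are dropped, never imputed
  expect_equal(tidy(mean_difference_raw(c(a, NA), b)), tidy(ours))
  expect_error(mean_difference_raw(c(1, NA), b), "at least 2")
})

test_that("summary-statistic Welch intervals agree with raw-data t tests", {
  # construct raw samples with exactly the requested summaries
  make_sample <- function(n, m, s) {
    z <- scale(rnorm(n))
    as.numeric(m + s * z)
  }
  withr::with_seed(3, {
    a <- make_sample(937, 77.0, 17.2)
    b <- make_sample(926, 77.0, 16.74)
  })
  summ <- mean_difference_summary(77.0, 17.2, 937, 77.0, 16.74, 926)
  raw <- mean_difference_raw(a, b)
  expect_equal(summ$diff, raw$diff, tolerance = 1e-8)
  expect_equal(summ$ci_low, raw$ci_low, tolerance = 1e-6)
  expect_equal(summ$ci_high, raw$ci_high, tolerance = 1e-6)
  # frozen closed-form value for this configuration
  expect_equal(summ$diff, 0)
  expect_equal(summ$ci_high, 1.5422, tolerance = 1e-3)
})

test_that("two-proportion power matches its planning scenario and the null", {
  expect_gte(two_proportion_power(0.075, 0.05, n1 = 1969), 0.90)
  expect_equal(two_proportion_power(0.075, 0.05, n1 = 1969), 0.9001,
               tolerance = 1e-3)
  # null case: power collapses to the type-I error rate
  expect_equal(two_proportion_power(0.1, 0.1, n1 = 500), 0.05, tolerance = 0.005)
  # monotone in n and in effect size
  expect_gt(two_proportion_power(0.075, 0.05, n1 = 3000),
            two_proportion_power(0.075, 0.05, n1 = 1000))
  expect_gt(two_proportion_power(0.10, 0.05, n1 = 1000),
            two_proportion_power(0.075, 0.05, n1 = 1000))
})

test_that("analytic power agrees with simulated rejection rates", {
  sim_power <- function(p1, p2, n, B, seed) {
    withr::with_seed(seed, {
      x1 <- rbinom(B, n, p1)
      x2 <- rbinom(B, n, p2)
    })
    rej <- vapply(seq_len(B), function(i)
      pearson_chi_square(x1[i], n, x2[i], n)$p_value <= 0.05, logical(1))
    mean(rej)
  }
  for (cs in list(c(0.20, 0.10, 200), c(0.50, 0.40, 300))) {
    B <- 3000
    emp <- sim_power(cs[1], cs[2], cs[3], B = B, seed = 1234)
    ana <- two_proportion_power(cs[1], cs[2], n1 = cs[3])
    expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / B) + 0.01)
  }
  # the observed-trial scenario: both routes put power near 0.88, not at it
  emp <- sim_power(0.116, 0.076, 1050, B = 3000, seed = 99)
  ana <- two_proportion_power(0.116, 0.076, n1 = 1062, n2 = 1037)
  expect_equal(ana, 0.876, tolerance = 0.005)
  expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / 3000) + 0.01)
})

test_that("required sample size inverts the power function", {
  n <- required_n_per_group(0.05, 0.025)
  expect_equal(n, 1969)
  expect_gte(two_proportion_power(0.075, 0.05, n1 = n), 0.90)
  expect_lt(two_proportion_power(0.075, 0.05, n1 = n - 1), 0.90)
  # round trip across a parameter grid
  grid <- expand.grid(p = c(0.05, 0.2, 0.5), d = c(0.02, 0.05, 0.1),
                      pw = c(0.8, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    n <- required_n_per_group(g$p, g$d, power = g$pw)
    expect_gte(two_proportion_power(g$p + g$d, g$p, n1 = n), g$pw)
    if (n > 2) expect_lt(two_proportion_power(g$p + g$d, g$p, n1 = n - 1), g$pw)
  }
  expect_gt(required_n_per_group(0.05, 0.025),
            required_n_per_group(0.05, 0.05))    # doubling delta shrinks n
  expect_lte(required_n_per_group(0.05, 0.025, power = 0.049), 2)
  expect_error(required_n_per_group(0.05, 0), "nonzero")
})
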