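test_that("cronbach_alpha matches hand-computed and limiting cases", {
  # 8 identical columns: perfect consistency
  x <- matrix(rep(c(1, 3, 4, 5, 2), 8), ncol = 8)
  expect_equal(cronbach_alpha(x), 1)
  # items differing by a constant: alpha = 1 by the formula
  x <- cbind(1:4, 2:5)
  expect_equal(cronbach_alpha(x), 1)
  # independent uniform columns: population alpha 0 (simulation oracle)
  set.seed(1)
  x <- matrix(sample(1:5, 2000 * 8, replace = TRUE), 2000, 8)
  expect_lt(abs(cronbach_alpha(x)), 0.05)
  # degenerate: zero total variance
  expect_error(cronbach_alpha(matrix(3, 4, 8)), "variance")
})

test_that("alpha is invariant under adding a constant to an item", {
  for (seed in 1:5) {
    x <- random_ratings(30, seed = seed)
    y <- x
    y[, 3] <- y[, 3] + 7  # shift one item
    expect_equal(cronbach_alpha(y), cronbach_alpha(x))
  }
})

test_that("content validity indices are direct proportions", {
  x <- matrix(5, 4, 3)
  cv <- content_validity(x)
  expect_equal(unname(cv$i_cvi), rep(1, 3))
  expect_equal(cv$s_cvi, 1)

  one <- matrix(c(4, 4, 4, 4, 4, 2), ncol = 1)
  expect_equal(unname(content_validity(one)$i_cvi), 5 / 6)

  two <- cbind(c(4, 4, 4, 4, 2), c(4, 4, 4, 4, 4))
  cv <- content_validity(two)
  expect_equal(cv$s_cvi, mean(c(0.8, 1.0)))
  expect_equal(cv$s_cvi, 0.9)

  # reproducible by direct counting at any threshold
  set.seed(3)
  m <- random_ratings(40, seed = 3)
  for (floor_ in 2:5) {
    direct <- apply(m, 2, function(v) sum(v >= floor_) / length(v))
    expect_equal(unname(content_validity(m, floor_)$i_cvi),
                 unname(direct))
  }
  expect_error(content_validity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("ICC(2,1) agrees with the ANOVA mean-squares oracle", {
  # frozen hand computation for the 4-subject fixture
  res <- icc_test_retest(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(res$icc, 4.333333333 / 4.583333333, tolerance = 1e-9)
  expect_equal(unname(res$ms), c(4.458333333, 0.125, 0.125),
               tolerance = 1e-9)
  expect_true(res$lower < res$icc && res$icc < res$upper)

  # independent oracle: mean squares from stats::aov on random fixtures
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- sample(1:5, 12, replace = TRUE)
    t2 <- pmin(pmax(t1 + sample(-1:1, 12, replace = TRUE), 1), 5)
    d <- data.frame(y = c(t1, t2),
                    subj = factor(rep(1:12, 2)),
                    occ = factor(rep(1:2, each = 12)))
    ms <- summary(stats::aov(y ~ subj + occ, data = d))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_aov <- (msr - mse) /
      (msr + (2 - 1) * mse + 2 / 12 * (msc - mse))
    expect_equal(icc_test_retest(t1, t2)$icc, icc_aov, tolerance = 1e-10)
  }
})

test_that("ICC limiting behaviour: identity and independence", {
  v <- c(1, 2, 3, 4, 5, 2, 3)
  expect_equal(icc_test_retest(v, v)$icc, 1)
  set.seed(1)
  t1 <- sample(1:5, 1000, replace = TRUE)
  t2 <- sample(1:5, 1000, replace = TRUE)
  expect_lt(abs(icc_test_retest(t1, t2)$icc), 0.06)
  expect_error(icc_test_retest(1:4, 1:5), "identical shapes")
  expect_error(icc_test_retest(1, 1), "2 subjects")
})

test_that("descriptives match a brute-force moment oracle", {
  d <- panel_descriptives(cbind(a = c(1, 1, 1, 5), b = c(1, 2, 3, 4)))
  v <- c(1, 1, 1, 5)
  n <- 4
  m2 <- mean((v - mean(v))^2)
  g1 <- mean((v - mean(v))^3) / m2^1.5
  expect_equal(d$mean[1], 2)
  expect_equal(d$sd[1], sd(v))
  expect_equal(d$skewness[1], g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(d$kurtosis[1], mean((v - mean(v))^4) / m2^2)

  # symmetric ratings: zero skewness
  d <- panel_descriptives(cbind(x = 1:5, y = c(2, 3, 3, 3, 4)))
  expect_equal(d$skewness, c(0, 0))

  # constant column: degenerate flag, moments reported as 0
  d <- panel_descriptives(cbind(const = rep(3, 6), var = c(1:5, 5)))
  expect_true(d$degenerate[1])
  expect_equal(d$sd[1], 0)
  expect_equal(d$skewness[1], 0)
  expect_false(d$degenerate[2])
})

test_that("qc_report assembles stages and warns on threshold violations", {
  p <- simulate_panel(default_sim_config(seed = 4))
  # low-agreement panel: CVI warnings expected, never an error
  w <- capture_warnings(rep_ <- qc_report(p))
  expect_match(w, "QC threshold", all = FALSE)
  expect_s3_class(rep_, "qc_report")
  expect_equal(rep_$cronbach_alpha, cronbach_alpha(p))
  expect_equal(nrow(rep_$per_factor), 8)
  # with a retest occasion the ICC is populated
  p2 <- as.matrix(p)
  suppressWarnings(rep2 <- qc_report(p, retest = p2))
  expect_equal(rep2$icc$icc, 1)
})
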