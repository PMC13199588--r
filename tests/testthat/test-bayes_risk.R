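test_that("ratings map onto the stated correlation anchors", {
  expect_identical(map_correlation_level(c(1, 2, 3, 4, 5)),
                   c("low", "low", "medium", "high", "high"))
  expect_error(map_correlation_level(6), "1:5")
  # anchors are configurable but ordered
  a <- correlation_anchors(low_max = 1, medium_value = 2, high_min = 3)
  expect_identical(map_correlation_level(2, a), "medium")
  expect_error(correlation_anchors(3, 3, 4))
})

test_that("count_levels tallies factors, groups and pools", {
  h <- pl_hierarchy()
  p <- as_panel(matrix(5L, 2, 8, dimnames = list(NULL, h$factors)))
  lc <- count_levels(p)
  expect_true(all(lc$counts[, "high"] == 2))
  expect_true(all(lc$counts[, c("low", "medium")] == 0))

  m <- matrix(3L, 3, 8, dimnames = list(NULL, h$factors))
  m[, "X3"] <- c(1L, 3L, 4L)
  lc <- count_levels(as_panel(m))
  expect_equal(unname(lc$counts["X3", ]), c(1, 1, 1))

  # per-factor counts always sum to n; pools are column sums
  for (seed in 1:10) {
    lc <- count_levels(as_panel(random_ratings(10, seed)))
    expect_true(all(rowSums(lc$counts) == 10))
    expect_equal(unname(lc$all_counts), unname(colSums(lc$counts)))
    expect_equal(lc$secondary_cells, 60)
    expect_equal(unname(lc$stage_cells), c(40, 40))
  }
})

test_that("posterior_probability implements the stated update", {
  r <- posterior_probability(0.5, 0.8)
  expect_equal(r$inverse, 0.2)
  expect_equal(r$marginal, 0.5)
  expect_equal(r$posterior, 0.8)
  # prior mass 1: posterior 1 for any positive likelihood
  r <- posterior_probability(1, c(0.3, 0.9))
  expect_equal(r$posterior, c(1, 1))
  # symmetric likelihood cancels: posterior = prior
  r <- posterior_probability(c(0.2, 0.7), 0.5)
  expect_equal(r$posterior, c(0.2, 0.7))
  # marginal 0 flagged, not NaN
  r <- posterior_probability(0, 1)
  expect_true(r$undefined)
  expect_true(is.na(r$posterior))
  expect_error(posterior_probability(1.2, 0.5), "\\[0, 1\\]")
})

test_that("posterior stays in [0,1] and is monotone in likelihood", {
  grid <- seq(0, 1, by = 0.05)
  for (prior in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    post <- posterior_probability(prior, grid)$posterior
    ok <- !is.na(post)
    expect_true(all(post[ok] >= 0 & post[ok] <= 1))
    expect_true(all(diff(post[ok]) >= -1e-12))
  }
})

test_that("degenerate panels give certainty posteriors", {
  h <- pl_hierarchy()
  p5 <- as_panel(matrix(5L, 4, 8, dimnames = list(NULL, h$factors)))
  r <- assess_risk(p5)
  high <- r[r$level == "high", ]
  expect_equal(high$posterior, rep(1, 9))
  expect_true(all(high$band == "high"))
  expect_true(all(high$risky))

  p1 <- as_panel(matrix(1L, 4, 8, dimnames = list(NULL, h$factors)))
  r <- assess_risk(p1)
  high <- r[r$level == "high", ]
  expect_equal(high$posterior, rep(0, 9))
  expect_true(all(high$band == "low"))
  expect_false(any(high$risky))
})

test_that("assess_risk equals the spreadsheet-style counting oracle", {
  for (seed in 1:25) {
    m <- random_ratings(12, seed = seed)
    r <- assess_risk(as_panel(m))
    got <- setNames(r$posterior, paste0(r$factor, ".", r$level))
    want <- risk_oracle(m)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    expect_true(all(r$posterior >= 0 & r$posterior <= 1, na.rm = TRUE))
  }
})

test_that("canonical marginal option normalizes over levels", {
  m <- random_ratings(15, seed = 7)
  r <- assess_risk(as_panel(m), method = "canonical")
  for (f in unique(r$factor)) {
    sub <- r[r$factor == f, ]
    # full-mixture marginal is shared across levels and posteriors sum to 1
    expect_equal(length(unique(sub$marginal)), 1L)
    expect_equal(sum(sub$posterior), 1)
  }
})

test_that("risk bands partition [0,1] and match the published calls", {
  expect_identical(classify_band(c(0.9838, 0.4803, 0.4652, 0.3243, 0.0545)),
                   c("high", "medium", "medium", "low", "low"))
  # the [0.80, 0.81) sliver is closed upward into the high band
  expect_identical(classify_band(0.805), "high")
  expect_identical(classify_band(0.8), "high")
  expect_identical(classify_band(0.4), "low")
  # no unlabeled probability anywhere on a fine grid
  g <- seq(0, 1, by = 0.001)
  expect_true(all(classify_band(g) %in% c("low", "medium", "high")))
  expect_identical(is_risky(c(0.4, 0.41)), c(FALSE, TRUE))
})
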