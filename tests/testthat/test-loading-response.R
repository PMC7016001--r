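make_map <- function(values, converged = NULL) {
  t <- values
  conv <- if (is.null(converged)) !is.na(t) else converged
  structure(list(relaxation_time = t, amplitude = t * 0 + 1,
                 converged = conv, residual_norm = t * 0,
                 contrast = "T2", bounds = c(1, 500)),
            class = "parameter_map")
}

test_that("ROI summaries use only unflagged pixels and the frozen quartile rule", {
  mask <- matrix(TRUE, 3, 3)
  part <- partition_thirds(mask, "left")

  uni <- make_map(matrix(50, 3, 3))
  s <- summarize_roi(uni, part, "entire")
  expect_equal(s$median, 50)
  expect_equal(s$iqr, 0)
  expect_equal(s$pixel_count, 9L)

  # values 1..9: median 5; quartile rule must equal a sort-based oracle
  m <- make_map(matrix(1:9, 3, 3))
  s <- summarize_roi(m, part, "entire")
  expect_equal(s$median, 5)
  v <- sort(1:9)
  oracle_q <- function(p) {           # type-6 interpolation, by hand
    h <- (length(v) + 1) * p
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  expect_equal(s$q1, oracle_q(0.25))
  expect_equal(s$q3, oracle_q(0.75))

  # flagged pixels are excluded; empty ROI yields missing values
  conv <- matrix(TRUE, 3, 3); conv[, 1] <- FALSE
  mf <- make_map(matrix(1:9, 3, 3), conv)
  expect_message(s1 <- summarize_roi(mf, part, "I"), "empty")
  expect_true(is.na(s1$median))
  expect_equal(s1$pixel_count, 0L)
  expect_equal(summarize_roi(mf, part, "entire")$pixel_count, 6L)
})

test_that("entire-ROI pixel count equals the sum of the zonal counts", {
  set.seed(5)
  m <- random_blob_mask()
  part <- partition_thirds(m, "left")
  vals <- matrix(NA_real_, nrow(m), ncol(m)); vals[m] <- runif(sum(m), 10, 60)
  map <- make_map(vals)
  counts <- vapply(c("I", "II", "III"),
                   function(z) summarize_roi(map, part, z)$pixel_count,
                   integer(1))
  expect_equal(summarize_roi(map, part, "entire")$pixel_count, sum(counts))
})

test_that("relative change follows the Delta formula and its invariances", {
  expect_equal(relative_change(50, 40), 25)
  expect_equal(relative_change(42.3, 42.3), 0)
  expect_equal(relative_change(554, 696), -20.40229885, tolerance = 1e-8)
  # scale invariance
  for (k in c(0.5, 2, 17)) {
    expect_equal(relative_change(50 * k, 40 * k), relative_change(50, 40))
  }
  expect_true(is.na(relative_change(50, 0)))
  expect_true(is.na(relative_change(50, NA)))
})

test_that("contact pressure reproduces the worked footprint arithmetic", {
  expect_equal(pressure_from_force(38, 15, 8.4), 0.30)
  expect_equal(pressure_from_force(69, 15, 8.4), 0.55)
  expect_equal(pressure_from_force(0, 15, 8.4), 0)
  expect_equal(15 * 8.4, 126)
  expect_error(pressure_from_force(38, 0, 8.4), "positive")
})

test_that("pixel counts track compression factors and flag monotone collapse", {
  masks <- lapply(c(1, 0.9, 0.75), function(f)
    generate_wedge_mask(8.4, 14.9, 0.25, f))
  pc <- pixel_count_series(masks)
  expect_true(pc$monotone_decreasing)
  ratios <- pc$counts / pc$counts[1]
  expect_lt(max(abs(ratios - c(1, 0.9, 0.75))), 0.01)
  same <- pixel_count_series(list(masks[[1]], masks[[1]]))
  expect_equal(unname(diff(same$counts)), 0L)
  expect_true(same$monotone_decreasing)
})
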