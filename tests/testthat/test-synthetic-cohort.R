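small_spec <- function(...) {
  phantom_spec(n = 6, image_shape = c(32, 32), pixel_size = 0.5,
               grade_fractions = c(2, 2, 2) / 6,
               contrasts = "T2", seed = 7, ...)
}

test_that("identical seeds yield bit-identical cohorts", {
  c1 <- generate_cohort(small_spec())
  c2 <- generate_cohort(small_spec())
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(small_spec(noise_sigma = 3))
  expect_false(identical(c1$samples[[1]]$loads$delta0$stacks,
                         c3$samples[[1]]$loads$delta0$stacks))
})

test_that("grade fractions reproduce the cohort trichotomy sizes", {
  spec <- phantom_spec(n = 45, image_shape = c(32, 32), pixel_size = 0.5,
                       contrasts = "T2", seed = 3)
  coh <- generate_cohort(spec)
  groups <- vapply(coh$samples, `[[`, character(1), "group")
  expect_equal(unname(table(factor(groups, c("I", "II", ">=III")))),
               c(14L, 16L, 15L), ignore_attr = TRUE)
  # drawn Pauli grades are consistent with the assigned subgroup
  for (s in coh$samples) {
    expect_equal(as.character(s$pauli$group), s$group)
  }
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(phantom_spec(grade_fractions = c(0.5, 0.2, 0.2)),
               "grade_fractions")
  expect_error(phantom_spec(compression_factors = c(1, 0.9, 0.95)),
               "compression_factors")
  expect_error(phantom_spec(wedge_width = -1), "wedge")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
})

test_that("wedge masks are connected, shrink with compression, and honour geometry", {
  m1 <- generate_wedge_mask(8.4, 11.9, 0.25)
  m1b <- generate_wedge_mask(8.4, 11.9, 0.25)
  expect_identical(m1, m1b)
  # mediolateral extent matches the requested width
  cols <- which(colSums(m1) > 0)
  expect_equal(length(cols), 34, tolerance = 1)   # 8.4 mm / 0.25 mm
  m05 <- generate_wedge_mask(8.4, 11.9, 0.25, 0.5)
  expect_lt(abs(sum(m05) / (sum(m1) * 0.5) - 1), 0.05)
  # width preserved under compression, height reduced
  expect_equal(range(which(colSums(m05) > 0)), range(cols))
  expect_lt(max(table(col(m05)[m05])), max(table(col(m1)[m1])))
  expect_error(generate_wedge_mask(8.4, 11.9, 0.25, 0.01), "3 pixels")
  expect_error(generate_wedge_mask(8.4, 11.9, 0.25, 1.5), "compression_factor")
})

test_that("per-load mask areas follow the compression factors", {
  spec <- small_spec(compression_factors = c(1, 0.9, 0.75))
  coh <- generate_cohort(spec)
  s <- coh$samples[[1]]
  counts <- vapply(s$loads, function(l) sum(l$mask), integer(1))
  expect_true(all(diff(counts) < 0))
  expect_lt(max(abs(counts / counts[1] - c(1, 0.9, 0.75))), 0.03)
})

test_that("Rician noise recovers the noiseless signal at high SNR", {
  set.seed(12)
  draws <- rician_noise(rep(100, 2e4), 2)
  expect_lt(abs(mean(draws) / 100 - 1), 0.01)
  # zero noise is the identity
  expect_identical(rician_noise(c(1, 2, 3), 0), c(1, 2, 3))
  # zero signal follows a Rayleigh background with mean sigma*sqrt(pi/2)
  bg <- rician_noise(rep(0, 2e4), 3)
  expect_lt(abs(mean(bg) / (3 * sqrt(pi / 2)) - 1), 0.03)
})

test_that("stress-strain curves obey the exponential model closed forms", {
  cur <- generate_stress_strain(5, 1, seq(0, 1, 0.1))
  expect_equal(cur$stress[1], 0)
  expect_equal(cur$stress[cur$strain == 0.2], exp(1) - 1, tolerance = 1e-12)
  expect_error(generate_stress_strain(-1, 1), "positive")
  expect_error(generate_stress_strain(5, 1, c(0, 1.2)), "0, 1")
})

test_that("generated Pauli subscores stay inside their grade bins", {
  set.seed(21)
  for (g in c("I", "II", ">=III")) {
    for (i in 1:20) {
      sc <- generate_pauli_subscores(g)
      expect_equal(as.character(sc$group), g)
      rng <- switch(g, I = c(0, 4), II = c(5, 9), ">=III" = c(10, 16))
      expect_gte(sc$sum, rng[1]); expect_lte(sc$sum, rng[2])
    }
  }
})

test_that("cohort EM statistics and pixel ordering match the emulated study conditions", {
  coh <- generate_cohort(phantom_spec(seed = 5, contrasts = "T2",
                                     image_shape = c(48, 48),
                                     pixel_size = 0.35))
  em20 <- vapply(coh$samples, function(s) s$c * s$b * exp(0.2 * s$b),
                 numeric(1))
  em80 <- vapply(coh$samples, function(s) s$c * s$b * exp(0.8 * s$b),
                 numeric(1))
  expect_gt(mean(em20), 10); expect_lt(mean(em20), 25)
  expect_gt(mean(em80), 250); expect_lt(mean(em80), 470)
  # default compression factors reproduce the printed pixel-count ordering
  full <- generate_cohort(small_spec())
  counts <- vapply(full$samples[[1]]$loads, function(l) sum(l$mask),
                   integer(1))
  expect_true(all(diff(counts) < 0))
})
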