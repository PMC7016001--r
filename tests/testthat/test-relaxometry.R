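grids <- acquisition_grids()

uniform_stack <- function(contrast, truth, A = 100, sigma = 0,
                          shape = c(8, 8)) {
  tm <- matrix(truth, shape[1], shape[2])
  generate_signal_stack(tm, contrast, grids[[contrast]]$times, A, sigma)
}

test_that("noiseless stacks are recovered exactly for all three contrasts", {
  cases <- list(list(ct = "T2", fit = fit_t2_map, truth = 25),
                list(ct = "T2", fit = fit_t2_map, truth = 24.7),
                list(ct = "T1rho", fit = fit_t1rho_map, truth = 46.7),
                list(ct = "T1", fit = fit_t1_map, truth = 700),
                list(ct = "T1", fit = fit_t1_map, truth = 696))
  for (cs in cases) {
    map <- cs$fit(uniform_stack(cs$ct, cs$truth))
    err <- abs(map$relaxation_time - cs$truth)
    tol <- if (cs$ct == "T1") 0.1 else 1e-3
    expect_lt(max(err), tol)
    expect_true(all(map$converged))
    # amplitude recovered too (equilibrium term for T1)
    expect_true(all(abs(map$amplitude - 100) < 1e-2))
  }
})

test_that("relaxation estimates are scale-equivariant and robust to dropping the last point", {
  for (cs in list(list(ct = "T2", fit = fit_t2_map, truth = 31.2),
                  list(ct = "T1rho", fit = fit_t1rho_map, truth = 52.1),
                  list(ct = "T1", fit = fit_t1_map, truth = 850))) {
    st <- uniform_stack(cs$ct, cs$truth, shape = c(3, 3))
    base <- cs$fit(st)
    scaled <- signal_stack(st$data * 3.7, st$times, st$contrast)
    ms <- cs$fit(scaled)
    expect_equal(ms$relaxation_time, base$relaxation_time, tolerance = 1e-6)
    expect_equal(ms$amplitude, base$amplitude * 3.7, tolerance = 1e-6)
    n <- length(st$times)
    shorter <- signal_stack(st$data[, , -n, drop = FALSE], st$times[-n],
                            st$contrast)
    if (cs$ct == "T1" && n - 1 < 4) next
    mshort <- cs$fit(shorter)
    expect_lt(max(abs(mshort$relaxation_time / base$relaxation_time - 1)),
              1e-3)
  }
})

test_that("two-point spin-lock stacks reproduce the closed form", {
  s0 <- 80; t1rho <- 46.7
  s40 <- s0 * exp(-40 / t1rho)
  st <- signal_stack(array(c(s0, s40), c(1, 1, 2)), c(0, 40), "T1rho")
  map <- fit_t1rho_map(st)
  expect_equal(map$relaxation_time[1, 1], 40 / log(s0 / s40),
               tolerance = 1e-9)
})

test_that("degenerate pixels are flagged, not silently kept", {
  st <- uniform_stack("T2", 25, shape = c(2, 2))
  st$data[1, 1, ] <- 50                      # constant across echoes
  st$data[1, 2, ] <- 0                       # no signal at all
  map <- fit_t2_map(st)
  expect_false(map$converged[1, 1])
  expect_equal(map$relaxation_time[1, 1], relaxation_bounds()$T2[2])
  expect_false(map$converged[1, 2])
  expect_true(all(map$converged[2, ]))
})

test_that("noisy T2 fits match a dense grid-search oracle and are nearly unbiased", {
  set.seed(42)
  n <- 4000
  truth <- 24.7
  S <- t(sapply(grids$T2$times, function(te)
    rep(monoexp_signal(te, 100, truth), n)))
  S <- rician_noise(S, 1)
  fit <- meniscusqmri:::fit_monoexp_matrix(S, grids$T2$times, 1, 500)
  med <- median(fit$t[fit$converged])
  expect_lt(abs(med / truth - 1), 0.02)
  t_grid <- seq(15, 40, by = 0.02)
  for (j in sample(which(fit$converged), 25)) {
    oracle <- monoexp_grid_oracle(S[, j], grids$T2$times, t_grid)
    expect_lt(abs(fit$t[j] - oracle), 0.05)
  }
})

test_that("noisy T1rho median bias stays within the pipeline tolerance", {
  set.seed(43)
  n <- 4000
  truth <- 46.7
  S <- t(sapply(grids$T1rho$times, function(tsl)
    rep(monoexp_signal(tsl, 80, truth), n)))
  S <- rician_noise(S, 2)
  fit <- meniscusqmri:::fit_monoexp_matrix(S, grids$T1rho$times, 1, 500)
  med <- median(fit$t[fit$converged])
  expect_lt(abs(med / truth - 1), 0.05)
})

test_that("polarity-ambiguous IR pixels agree with the sign-enumeration oracle", {
  set.seed(44)
  truth <- 500 / log(2)          # signal null lands on the 500 ms TI
  n <- 40
  S <- t(sapply(grids$T1$times, function(ti)
    rep(ir_signal(ti, 100, truth), n)))
  S <- rician_noise(S, 1.5)
  fit <- meniscusqmri:::fit_ir_matrix(S, grids$T1$times, 50, 5000)
  t_grid <- exp(seq(log(400), log(1100), length.out = 3000))
  for (j in 1:n) {
    oracle <- ir_grid_oracle(S[, j], grids$T1$times, t_grid)
    expect_lt(abs(fit$t[j] / oracle - 1), 0.01)
  }
})

test_that("vectorized mono-exponential fits match per-pixel Levenberg-Marquardt", {
  set.seed(45)
  times <- grids$T2$times
  for (i in 1:8) {
    truth <- runif(1, 15, 60); A <- runif(1, 50, 150)
    y <- rician_noise(monoexp_signal(times, A, truth), 1)
    ours <- meniscusqmri:::fit_monoexp_matrix(cbind(y), times, 1, 500)
    ref <- minpack.lm::nlsLM(y ~ a * exp(-times / tt),
                             start = list(a = max(y), tt = 30))
    expect_equal(unname(ours$t[1]), unname(coef(ref)["tt"]), tolerance = 1e-4)
    expect_equal(unname(ours$amplitude[1]), unname(coef(ref)["a"]),
                 tolerance = 1e-4)
  }
})

test_that("stack validation enforces the acquisition contract", {
  arr <- array(1, c(4, 4, 6))
  expect_error(signal_stack(arr, c(1, 2, 3)), "match")
  expect_error(signal_stack(arr, c(6:2, 10)), "increasing")
  expect_error(signal_stack(-arr, 8.4 * (1:6)), "non-negative")
  st <- signal_stack(arr, 8.4 * (1:6), "T2")
  expect_error(fit_t1_map(st), "T1")
  tsl <- signal_stack(array(1, c(4, 4, 4)), c(10, 20, 30, 40), "T1rho")
  expect_error(fit_t1rho_map(tsl), "TSL")
})
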