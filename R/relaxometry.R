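#' Multi-contrast magnitude signal stack
#'
#' Container for a per-sample series of 2-D magnitude images indexed by an
#' acquisition variable: inversion time TI (T1 mapping), spin-lock
#' duration TSL (T1rho) or echo time TE (T2), all in ms.
#'
#' @param data numeric array `rows x cols x n_points`, all values >= 0
#' @param times acquisition variable values in ms, strictly increasing
#' @param contrast one of `"T1"`, `"T1rho"`, `"T2"`
#' @param tr repetition time in ms (metadata only)
#' @return object of class `signal_stack`
#' @export
signal_stack <- function(data, times, contrast = c("T1", "T1rho", "T2"),
                         tr = NA_real_) {
  contrast <- match.arg(contrast)
  if (length(dim(data)) != 3L)
    stop("data must be a rows x cols x n_points array")
  if (dim(data)[3] != length(times))
    stop("third array dimension must match length(times)")
  if (length(times) < 2L) stop("need at least 2 acquisition points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(data)) || any(data < 0))
    stop("signal values must be finite and non-negative")
  structure(list(data = data, times = as.numeric(times),
                 contrast = contrast, tr = tr),
            class = "signal_stack")
}

#' @export
print.signal_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s signal stack: %d x %d pixels, %d points (%s ms)\n",
              x$contrast, d[1], d[2], d[3],
              paste(signif(x$times, 4), collapse = ", ")))
  invisible(x)
}

#' Default relaxation-time fitting bounds (ms)
#'
#' @return named list of `c(lower, upper)` bounds per contrast
#' @export
relaxation_bounds <- function() {
  list(T1 = c(50, 5000), T1rho = c(1, 500), T2 = c(1, 500))
}

new_parameter_map <- function(t, amplitude, converged, residual, contrast,
                              bounds) {
  structure(list(relaxation_time = t, amplitude = amplitude,
                 converged = converged, residual_norm = residual,
                 contrast = contrast, bounds = bounds),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$relaxation_time[x$converged & !is.na(x$relaxation_time)]
  cat(sprintf("%s parameter map: %d fitted pixels, median %.1f ms, %d flagged\n",
              x$contrast, length(v), stats::median(v),
              sum(!x$converged, na.rm = TRUE)))
  invisible(x)
}

#' Fit a voxelwise T2 map
#'
#' Per-pixel nonlinear least-squares fit of the mono-exponential decay
#' `S(TE) = A * exp(-TE / T2)` over a multi-echo stack, initialized from a
#' signal-weighted log-linear regression and refined by damped
#' Gauss-Newton iterations run simultaneously over all pixels.
#' Pixels with non-positive signal throughout, fits pinned at the T2
#' bounds, or non-converged iterations are flagged (`converged = FALSE`)
#' and excluded from downstream ROI summaries.
#'
#' @param stack a [signal_stack] with `contrast = "T2"`
#' @param mask optional logical matrix restricting the fit
#' @param bounds T2 search interval in ms
#' @return a `parameter_map`
#' @export
fit_t2_map <- function(stack, mask = NULL, bounds = relaxation_bounds()$T2) {
  stopifnot(inherits(stack, "signal_stack"))
  if (stack$contrast != "T2") stop("stack contrast must be T2")
  fit_monoexp_map(stack, mask, bounds, "T2")
}

#' Fit a voxelwise T1rho map
#'
#' Identical model to [fit_t2_map] but along the spin-lock duration axis:
#' `S(TSL) = A * exp(-TSL / T1rho)`. The TSL = 0 point anchors the
#' amplitude and must be present in the acquisition grid.
#'
#' @inheritParams fit_t2_map
#' @export
fit_t1rho_map <- function(stack, mask = NULL,
                          bounds = relaxation_bounds()$T1rho) {
  stopifnot(inherits(stack, "signal_stack"))
  if (stack$contrast != "T1rho") stop("stack contrast must be T1rho")
  if (min(stack$times) != 0) stop("TSL grid must include 0")
  fit_monoexp_map(stack, mask, bounds, "T1rho")
}

#' Fit a voxelwise T1 map from magnitude inversion-recovery data
#'
#' Three-parameter magnitude-IR model `S(TI) = |a + b * exp(-TI / T1)|`.
#' Magnitude images lose the sign of the recovering longitudinal
#' magnetization, so polarity is restored by trying every "first k points
#' negative" sign pattern, solving the profiled linear parameters (a, b)
#' in closed form on a coarse logarithmic T1 grid, and refining the best
#' candidate per pixel with a vectorized golden-section search on log T1.
#'
#' @param stack a [signal_stack] with `contrast = "T1"` and >= 4 TIs
#' @param mask optional logical matrix restricting the fit
#' @param bounds T1 search interval in ms
#' @return a `parameter_map` (amplitude = fitted equilibrium term `a`)
#' @export
fit_t1_map <- function(stack, mask = NULL, bounds = relaxation_bounds()$T1) {
  stopifnot(inherits(stack, "signal_stack"))
  if (stack$contrast != "T1") stop("stack contrast must be T1")
  if (length(stack$times) < 4L) stop("T1 fitting requires >= 4 inversion times")
  dims <- dim(stack$data)[1:2]
  sel <- mask_selector(mask, dims)
  S <- stack_matrix(stack, sel)
  fit <- fit_ir_matrix(S, stack$times, bounds[1], bounds[2])
  assemble_map(fit, sel, dims, "T1", bounds)
}

fit_monoexp_map <- function(stack, mask, bounds, contrast) {
  dims <- dim(stack$data)[1:2]
  sel <- mask_selector(mask, dims)
  S <- stack_matrix(stack, sel)
  fit <- fit_monoexp_matrix(S, stack$times, bounds[1], bounds[2])
  assemble_map(fit, sel, dims, contrast, bounds)
}

mask_selector <- function(mask, dims) {
  if (is.null(mask)) return(rep(TRUE, prod(dims)))
  mask <- check_mask(mask)
  if (!all(dim(mask) == dims)) stop("mask and stack grids differ")
  as.vector(mask)
}

stack_matrix <- function(stack, sel) {
  d <- dim(stack$data)
  m <- matrix(stack$data, nrow = d[1] * d[2], ncol = d[3])
  t(m[sel, , drop = FALSE])   # n_points x n_pixels
}

assemble_map <- function(fit, sel, dims, contrast, bounds) {
  blank <- function(v, init = NA_real_) {
    out <- matrix(init, dims[1], dims[2]); out[sel] <- v; out
  }
  conv <- matrix(FALSE, dims[1], dims[2]); conv[sel] <- fit$converged
  new_parameter_map(blank(fit$t), blank(fit$amplitude), conv,
                    blank(fit$residual_norm), contrast, bounds)
}

# Damped Gauss-Newton for S = A * exp(-R * t), vectorized over pixels.
# Returns per-pixel relaxation time t = 1/R clamped to [t_lo, t_hi].
fit_monoexp_matrix <- function(S, times, t_lo, t_hi,
                               max_iter = 200, tol = 1e-8) {
  n_pix <- ncol(S); n_t <- nrow(S)
  r_lo <- 1 / t_hi; r_hi <- 1 / t_lo
  eps <- 1e-12

  valid <- colSums(S > 0) >= 2
  # signal-weighted log-linear init (weights ~ S^2 linearize the noise)
  Sc <- pmax(S, eps)
  w <- Sc^2
  ly <- log(Sc)
  sw <- colSums(w); swt <- colSums(w * times); swt2 <- colSums(w * times^2)
  swy <- colSums(w * ly); swty <- colSums(w * times * ly)
  den <- sw * swt2 - swt^2
  slope <- (sw * swty - swt * swy) / pmax(den, eps)
  inter <- (swy - slope * swt) / sw
  R <- pmin(pmax(-slope, r_lo), r_hi)
  A <- exp(pmin(inter, 700))
  A[!is.finite(A)] <- 1

  rss_of <- function(A, R, cols) {
    E <- exp(-outer(times, R))
    m <- sweep(E, 2, A, `*`)
    colSums((S[, cols, drop = FALSE] - m)^2)
  }
  rss <- rss_of(A, R, seq_len(n_pix))
  converged <- rep(FALSE, n_pix)
  active <- valid & !converged

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    Ra <- R[idx]; Aa <- A[idx]
    E <- exp(-outer(times, Ra))
    m <- sweep(E, 2, Aa, `*`)
    r <- S[, idx, drop = FALSE] - m
    J2 <- -sweep(E * times, 2, Aa, `*`)     # d m / d R
    a11 <- colSums(E * E); a12 <- colSums(E * J2); a22 <- colSums(J2 * J2)
    g1 <- colSums(E * r); g2 <- colSums(J2 * r)
    det <- a11 * a22 - a12^2
    det[abs(det) < eps] <- eps
    dA <- (a22 * g1 - a12 * g2) / det
    dR <- (a11 * g2 - a12 * g1) / det
    # step halving where the full step does not decrease the residual
    step <- rep(1, length(idx))
    newA <- Aa + dA; newR <- pmin(pmax(Ra + dR, r_lo), r_hi)
    new_rss <- rss_of(newA, newR, idx)
    for (h in 1:12) {
      worse <- new_rss > rss[idx] * (1 + 1e-15)
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      newA[worse] <- Aa[worse] + step[worse] * dA[worse]
      newR[worse] <- pmin(pmax(Ra[worse] + step[worse] * dR[worse], r_lo), r_hi)
      new_rss[worse] <- rss_of(newA[worse], newR[worse], idx[worse])
    }
    improved <- new_rss <= rss[idx]
    rel_change <- abs(rss[idx] - new_rss) / pmax(rss[idx], eps)
    A[idx[improved]] <- newA[improved]
    R[idx[improved]] <- newR[improved]
    rss[idx[improved]] <- new_rss[improved]
    done <- rel_change < tol | !improved
    converged[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }

  at_bound <- R <= r_lo * (1 + 1e-9) | R >= r_hi * (1 - 1e-9)
  ok <- valid & converged & !at_bound
  t_out <- 1 / R
  t_out[!valid] <- t_hi
  list(t = t_out, amplitude = A, converged = ok,
       residual_norm = sqrt(rss))
}

# Magnitude inversion recovery |a + b exp(-TI/T1)|: sign-pattern
# enumeration + profiled linear solve on a coarse log grid, then
# vectorized golden-section refinement of T1.
fit_ir_matrix <- function(S, TI, t1_lo, t1_hi, n_grid = 60, n_golden = 40) {
  n_t <- nrow(S); n_pix <- ncol(S)
  valid <- (colMeans(S^2) - colMeans(S)^2 > 1e-12) & colSums(S > 0) >= 2
  grid <- exp(seq(log(t1_lo), log(t1_hi), length.out = n_grid))
  patterns <- lapply(0:n_t, function(k) c(rep(-1, k), rep(1, n_t - k)))

  best_rss <- rep(Inf, n_pix)
  best_i <- rep(1L, n_pix)
  best_k <- rep(1L, n_pix)

  yty_by_k <- colSums(S^2)     # sign flips do not change y'y
  for (ki in seq_along(patterns)) {
    Y <- S * patterns[[ki]]
    Sy <- colSums(Y)
    for (i in seq_along(grid)) {
      x <- exp(-TI / grid[i])
      Sx <- sum(x); Sxx <- sum(x^2)
      Sxy <- colSums(x * Y)
      den <- n_t * Sxx - Sx^2
      b <- (n_t * Sxy - Sx * Sy) / den
      a <- (Sy - b * Sx) / n_t
      rss <- yty_by_k - a * Sy - b * Sxy
      upd <- rss < best_rss
      best_rss[upd] <- rss[upd]
      best_i[upd] <- i
      best_k[upd] <- ki
    }
  }

  # fix each pixel's sign pattern, refine T1 within the bracketing grid cells
  signs <- vapply(patterns, identity, numeric(n_t))[, best_k, drop = FALSE]
  Ysel <- S * signs
  Sy <- colSums(Ysel); yty <- colSums(Ysel^2)
  prof_rss <- function(t1) {            # per-pixel T1 vector
    X <- exp(-outer(TI, 1 / t1))
    Sx <- colSums(X); Sxx <- colSums(X^2)
    Sxy <- colSums(X * Ysel)
    den <- n_t * Sxx - Sx^2
    b <- (n_t * Sxy - Sx * Sy) / den
    a <- (Sy - b * Sx) / n_t
    yty - a * Sy - b * Sxy
  }
  lo <- log(grid[pmax(best_i - 1L, 1L)])
  hi <- log(grid[pmin(best_i + 1L, length(grid))])
  g <- (sqrt(5) - 1) / 2
  for (it in seq_len(n_golden)) {
    x1 <- hi - g * (hi - lo)
    x2 <- lo + g * (hi - lo)
    f1 <- prof_rss(exp(x1)); f2 <- prof_rss(exp(x2))
    take1 <- f1 < f2
    hi[take1] <- x2[take1]
    lo[!take1] <- x1[!take1]
  }
  t1 <- exp((lo + hi) / 2)

  X <- exp(-outer(TI, 1 / t1))
  Sx <- colSums(X); Sxx <- colSums(X^2); Sxy <- colSums(X * Ysel)
  den <- n_t * Sxx - Sx^2
  b <- (n_t * Sxy - Sx * Sy) / den
  a <- (Sy - b * Sx) / n_t
  rss <- pmax(yty - a * Sy - b * Sxy, 0)

  at_bound <- t1 <= t1_lo * 1.001 | t1 >= t1_hi * 0.999
  list(t = t1, amplitude = a, converged = valid & !at_bound,
       residual_norm = sqrt(rss))
}
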