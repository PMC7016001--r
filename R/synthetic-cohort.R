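#' Rasterize a wedge-shaped meniscus cross-section mask
#'
#' The meniscus body cross section is approximated as a right-triangular
#' wedge: a flat bottom resting on the lever device, a vertical base edge
#' on the peripheral side and a hypotenuse tapering to the apex tip.
#' Loading flattens the wedge; this is emulated geometrically by scaling
#' the height with the compression factor while preserving the width, so
#' the pixel area scales approximately with the factor.
#'
#' @param width_mm mediolateral width in mm
#' @param height_mm unloaded base height in mm
#' @param pixel_size pixel edge length in mm
#' @param compression_factor area-retention fraction in (0, 1]
#' @param image_shape output grid `c(rows, cols)`
#' @param apex_side `"left"` or `"right"`
#' @return logical matrix
#' @export
generate_wedge_mask <- function(width_mm, height_mm, pixel_size,
                                compression_factor = 1,
                                image_shape = c(64, 64),
                                apex_side = "left") {
  if (width_mm <= 0 || height_mm <= 0 || pixel_size <= 0)
    stop("wedge dimensions and pixel size must be positive")
  if (compression_factor <= 0 || compression_factor > 1)
    stop("compression_factor must be in (0, 1]")
  nr <- image_shape[1]; nc <- image_shape[2]
  w_px <- width_mm / pixel_size
  h_px <- height_mm * compression_factor / pixel_size
  if (h_px < 3) stop("compressed wedge would be fewer than 3 pixels tall")
  if (w_px > nc || h_px > nr) stop("wedge does not fit the image grid")
  x0 <- (nc - w_px) / 2
  bottom <- nr - 2                    # flat bottom row (lever side)
  xc <- (seq_len(nc) - 0.5) - x0      # column centres relative to the tip
  frac <- pmin(pmax(xc / w_px, 0), 1)
  if (apex_side == "right") frac <- rev(frac)
  local_h <- h_px * frac
  rows <- seq_len(nr) - 0.5
  # pixel (r, c) is tissue when its centre lies within the local height
  mask <- outer(rows, local_h, function(r, h) r > bottom - h & r <= bottom)
  inside <- matrix(rep(xc > 0 & xc < w_px, each = nr), nr, nc)
  if (apex_side == "right") inside <- inside[, rev(seq_len(nc))]
  mask & inside
}

#' Rician noise for magnitude MRI
#'
#' Magnitude reconstruction of a complex signal with independent Gaussian
#' noise on both channels: the noisy value is
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`. At zero signal
#' this reduces to a Rayleigh background; at high signal-to-noise ratio
#' the mean approaches the noiseless signal.
#'
#' @param signal numeric vector/array of noiseless magnitudes (>= 0)
#' @param sigma noise scale in signal units
#' @return noisy magnitudes, same shape as `signal`
#' @export
rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Noiseless signal models of the three mapping sequences
#'
#' `monoexp_signal` is the spin-lock / multi-echo decay
#' `A exp(-t / T)`; `ir_signal` is the ideal magnitude
#' inversion-recovery curve `|A (1 - 2 exp(-TI / T1))|`.
#'
#' @param t acquisition variable (TSL or TE) in ms
#' @param A amplitude in signal units
#' @param T_relax relaxation time in ms
#' @export
monoexp_signal <- function(t, A, T_relax) A * exp(-t / T_relax)

#' @rdname monoexp_signal
#' @param TI inversion time in ms
#' @param T1 longitudinal relaxation time in ms
#' @export
ir_signal <- function(TI, A, T1) abs(A * (1 - 2 * exp(-TI / T1)))

#' Simulate a magnitude signal stack from a truth map
#'
#' @param truth matrix of true relaxation times (ms); `NA` outside tissue
#' @param contrast `"T1"`, `"T1rho"` or `"T2"`
#' @param times acquisition grid in ms
#' @param amplitude signal amplitude
#' @param noise_sigma Rician noise scale
#' @param tr repetition time metadata
#' @return a [signal_stack]
#' @export
generate_signal_stack <- function(truth, contrast, times, amplitude,
                                  noise_sigma, tr = NA_real_) {
  nr <- nrow(truth); nc <- ncol(truth)
  arr <- array(0, c(nr, nc, length(times)))
  tv <- truth
  tv[is.na(tv)] <- Inf          # background: zero signal
  for (i in seq_along(times)) {
    plane <- if (contrast == "T1") ir_signal(times[i], amplitude, tv)
             else monoexp_signal(times[i], amplitude, tv)
    plane[!is.finite(truth)] <- 0
    plane[is.na(truth)] <- 0
    arr[, , i] <- plane
  }
  arr <- rician_noise(arr, noise_sigma)
  signal_stack(arr, times, contrast, tr)
}

#' Simulate an unconfined-compression stress-strain curve
#'
#' Noiseless stress follows the exponential model
#' `sigma(eps) = c (exp(b eps) - 1)`; measurement noise is additive
#' Gaussian on the stress.
#'
#' @param b nonlinearity exponent (> 0)
#' @param c stress scale in MPa (> 0)
#' @param strain_grid strain fractions in `[0, 1]`
#' @param noise_sd Gaussian stress noise sd in MPa
#' @return data.frame with columns `strain`, `stress`
#' @export
generate_stress_strain <- function(b, c, strain_grid = seq(0, 1, 0.01),
                                   noise_sd = 0) {
  if (b <= 0 || c <= 0) stop("b and c must be positive")
  if (any(strain_grid < 0 | strain_grid > 1))
    stop("strain_grid must lie in [0, 1]")
  sigma <- c * (exp(b * strain_grid) - 1)
  if (noise_sd > 0) sigma <- sigma + stats::rnorm(length(sigma), 0, noise_sd)
  data.frame(strain = strain_grid, stress = sigma)
}

#' Draw Pauli component scores for a degeneration subgroup
#'
#' A sum score is drawn from the subgroup's empirical distribution
#' (group I: mean 3.4, sd 0.9, clipped to 0-4; group II: 8.0 +/- 0.9 in
#' 5-9; group >=III: 12.3 +/- 1.5 in 10-16), then decomposed uniformly at
#' random into the four components under their caps (surface 0-9, others
#' 0-3 each).
#'
#' @param group `"I"`, `"II"` or `">=III"`
#' @return one-row data.frame as returned by [pauli_score]
#' @export
generate_pauli_subscores <- function(group = c("I", "II", ">=III")) {
  group <- match.arg(group)
  par <- switch(group,
                "I" = c(3.4, 0.9, 0, 4),
                "II" = c(8.0, 0.9, 5, 9),
                ">=III" = c(12.3, 1.5, 10, 16))
  s <- round(stats::rnorm(1, par[1], par[2]))
  s <- min(max(s, par[3]), par[4])
  caps <- c(surface = 9, cellularity = 3, collagen = 3, staining = 3)
  comp <- c(surface = 0, cellularity = 0, collagen = 0, staining = 0)
  for (unit in seq_len(s)) {
    open <- names(comp)[comp < caps]
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    comp[pick] <- comp[pick] + 1L
  }
  pauli_score(comp[["surface"]], comp[["cellularity"]],
              comp[["collagen"]], comp[["staining"]])
}

#' Generate a full synthetic cohort
#'
#' Produces, for every sample: the Pauli component scores and grade; the
#' per-load wedge mask; per-load, per-contrast ground-truth relaxation
#' maps (piecewise constant over the generator's own zonal partition of
#' the mask, scaled by the sample's latent factor and a small per-zone,
#' per-load log-normal jitter); the corresponding Rician-noised magnitude
#' signal stacks on the standard acquisition grids; and the
#' stress-strain curve of the biomechanical reference together with its
#' true `(b, c)`.
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec]
#' @return object of class `meniscus_cohort`: list with `spec` and
#'   `samples`; each sample holds `id`, `group`, `pauli`, `u`, `b`, `c`,
#'   `stress_strain` and a `loads` list (per loading state: `mask`,
#'   `truth` and `stacks` per contrast)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  grids <- acquisition_grids()
  loads <- paste0("delta", seq_along(spec$compression_factors) - 1L)

  counts <- diff(c(0L, round(cumsum(spec$grade_fractions) * spec$n)))
  groups <- rep(c("I", "II", ">=III"), counts)

  truth_arr <- truth_lookup(spec$zonal_truth)

  samples <- vector("list", spec$n)
  # largest wedge that still fits the grid after rasterization margins
  fov <- spec$image_shape * spec$pixel_size
  w_max <- fov[2] * 0.95
  h_max <- fov[1] * 0.92

  for (i in seq_len(spec$n)) {
    grp <- groups[i]
    pauli <- generate_pauli_subscores(grp)
    u <- stats::rnorm(1)
    w_i <- min(trunc_norm(spec$wedge_width, spec$wedge_width_sd), w_max)
    h_i <- min(trunc_norm(spec$wedge_height, spec$wedge_height_sd), h_max)
    scale_i <- exp(spec$sample_sigma * u)
    bm <- spec$biomech
    b_i <- max(bm$b_mean - bm$b_coupling * u + stats::rnorm(1, 0, bm$b_sd), 0.5)
    c_i <- bm$c_mean * exp(-bm$c_coupling * u + stats::rnorm(1, 0, bm$c_sd))

    load_list <- list()
    for (li in seq_along(loads)) {
      mask <- generate_wedge_mask(w_i, h_i, spec$pixel_size,
                                  spec$compression_factors[li],
                                  spec$image_shape, spec$apex_side)
      # truth zones follow the segmentation convention: thirds of the
      # boundary-excluded outline; the boundary ring inherits its
      # column's zone
      pe <- partition_thirds(exclude_boundary(mask), spec$apex_side)
      zone_of <- label_by_cuts(mask, pe$division_x, spec$apex_side)
      truth <- list(); stacks <- list()
      for (ct in spec$contrasts) {
        tm <- matrix(NA_real_, nrow(mask), ncol(mask))
        for (z in 1:3) {
          base_val <- truth_arr[grp, z, loads[li], ct]
          jit <- exp(stats::rnorm(1, 0, spec$jitter_sigma))
          tm[zone_of == z] <- base_val * scale_i * jit
        }
        truth[[ct]] <- tm
        stacks[[ct]] <- generate_signal_stack(
          tm, ct, grids[[ct]]$times, spec$amplitude, spec$noise_sigma,
          grids[[ct]]$tr)
      }
      load_list[[loads[li]]] <- list(mask = mask, truth = truth,
                                     stacks = stacks)
    }

    noise_sd <- bm$noise_frac * c_i * (exp(b_i * max(bm$strain_grid)) - 1)
    curve <- generate_stress_strain(b_i, c_i, bm$strain_grid, noise_sd)

    samples[[i]] <- list(id = sprintf("S%02d", i), group = grp,
                         pauli = pauli, u = u, b = b_i, c = c_i,
                         stress_strain = curve, loads = load_list)
  }
  structure(list(spec = spec, samples = samples), class = "meniscus_cohort")
}

# classify every mask pixel by existing mediolateral cut positions
label_by_cuts <- function(mask, division_x, apex_side) {
  centre <- col(mask) + 0.5
  third <- 1L + (centre > division_x[1]) + (centre > division_x[2])
  if (apex_side == "right") third <- 4L - third
  ifelse(mask, third, 0L)
}

# normal draw truncated at 2 sd (keeps sample geometry physiological)
trunc_norm <- function(mean, sd) {
  if (sd == 0) return(mean)
  min(max(stats::rnorm(1, mean, sd), mean - 2 * sd), mean + 2 * sd)
}

truth_lookup <- function(zonal_truth) {
  groups <- c("I", "II", ">=III"); zones <- c("I", "II", "III")
  loads <- c("delta0", "delta1", "delta2")
  contrasts <- c("T1", "T1rho", "T2")
  arr <- array(NA_real_, c(3, 3, 3, 3),
               dimnames = list(groups, zones, loads, contrasts))
  for (r in seq_len(nrow(zonal_truth))) {
    row <- zonal_truth[r, ]
    arr[row$group, row$zone, row$load, row$contrast] <- row$value
  }
  if (anyNA(arr[, , , unique(zonal_truth$contrast)]))
    stop("zonal_truth table is incomplete")
  arr
}

#' @export
print.meniscus_cohort <- function(x, ...) {
  grp <- table(vapply(x$samples, `[[`, character(1), "group"))
  cat(sprintf("synthetic meniscus cohort: n = %d (%s), seed %d\n",
              length(x$samples),
              paste(names(grp), grp, sep = "=", collapse = ", "),
              x$spec$seed))
  invisible(x)
}

#' Loading-state metadata
#'
#' Set pressures (bar) and calibrated compressive forces (N) of the three
#' loading positions of the pneumatic device.
#'
#' @return data.frame with `load`, `pressure_bar`, `force_N`
#' @export
loading_states <- function() {
  data.frame(load = c("delta0", "delta1", "delta2"),
             pressure_bar = c(0, 2, 4),
             force_N = c(0, 37.1, 69.1))
}
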