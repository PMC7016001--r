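#' Acquisition grids for the three mapping sequences
#'
#' The fitting problems are defined by the acquisition variables of the
#' three mapping sequences: inversion-recovery T1 (six inversion times),
#' spin-lock T1rho (five spin-lock durations including 0) and multi-spin
#' echo T2 (six echoes at multiples of 8.4 ms).
#'
#' @return named list per contrast with elements `times` (ms) and `tr` (ms)
#' @export
acquisition_grids <- function() {
  list(
    T1    = list(times = c(150, 300, 500, 800, 1000, 1500), tr = 3000),
    T1rho = list(times = c(0, 10, 20, 30, 40), tr = 3),
    T2    = list(times = 8.4 * (1:6), tr = 1500)
  )
}

#' Default zonal ground-truth relaxation times
#'
#' Central relaxation-time values (ms) per degeneration subgroup (Pauli
#' grade group I / II / >=III), meniscus zone (apex I, intermediate II,
#' base III), loading state (delta0/delta1/delta2) and contrast. These
#' encode the characteristic response-to-loading patterns of the tissue:
#' T1 falls everywhere under loading; apex T1rho rises in intact and
#' mildly degenerative tissue but falls in moderate-to-severe
#' degeneration; apex T2 falls in degenerative tissue.
#'
#' @return data.frame with columns `group`, `zone`, `load`, `contrast`,
#'   `value`
#' @export
zonal_truth_defaults <- function() {
  groups <- c("I", "II", ">=III")
  zones <- c("I", "II", "III")
  loads <- c("delta0", "delta1", "delta2")
  # values ordered: group (slowest), zone, load (fastest)
  t1 <- c(780, 713, 702,  593, 522, 465,  661, 513, 499,
          887, 877, 837,  624, 532, 482,  676, 528, 511,
          914, 860, 782,  694, 569, 489,  628, 505, 468)
  t1rho <- c(43.6, 58.6, 55.0,  34.8, 44.9, 44.7,  48.2, 46.1, 43.9,
             63.3, 59.7, 58.3,  42.2, 44.2, 42.9,  45.1, 47.9, 48.0,
             65.5, 56.9, 51.3,  49.7, 45.5, 43.4,  49.7, 41.9, 41.0)
  t2 <- c(23.3, 23.0, 22.8,  20.2, 20.3, 20.2,  26.2, 23.6, 22.6,
          30.1, 29.8, 26.0,  25.3, 23.8, 25.0,  26.8, 26.4, 27.0,
          31.0, 32.1, 28.6,  23.7, 21.4, 19.7,  23.5, 23.6, 22.0)
  base <- expand.grid(load = loads, zone = zones, group = groups,
                      stringsAsFactors = FALSE)
  rbind(
    cbind(base, contrast = "T1", value = t1),
    cbind(base, contrast = "T1rho", value = t1rho),
    cbind(base, contrast = "T2", value = t2)
  )
}

#' Specification of a synthetic meniscus cohort
#'
#' Bundles every parameter of the in-silico cohort: sample count and
#' degeneration mix, the imaging grid, the wedge geometry and its
#' load-dependent compression, the zonal relaxation-time ground truth,
#' the signal model (amplitude, Rician noise), biological between-sample
#' spread, and the stress-strain model of the biomechanical reference.
#'
#' Defaults emulate the study conditions: 45 samples split 14/16/15 into
#' the I / II / >=III degeneration subgroups; a 64 x 64 grid at
#' 0.25 mm/pixel; a wedge of 8.4 mm (mediolateral) x 11.9 mm whose
#' unloaded cross section covers about 800 pixels; per-load area-retention
#' factors (1, 718/801, 604/801); and exponential stress-strain
#' parameters centred at b = 4.9, c = 1.3 MPa so that cohort Elastic
#' Moduli at 20% / 80% strain average roughly 16 and 350 MPa. A latent
#' per-sample factor `u` scales all of that sample's relaxation times
#' (log-normal, sd `sample_sigma`) and stiffens/softens its stress
#' response in the opposite direction (`b_coupling`), inducing the
#' inverse qMRI-stiffness association seen in real tissue.
#'
#' @param n number of samples
#' @param image_shape image grid `c(rows, cols)` in pixels
#' @param pixel_size pixel edge length in mm
#' @param wedge_width mean mediolateral wedge width in mm
#' @param wedge_height mean unloaded wedge (base) height in mm
#' @param wedge_width_sd,wedge_height_sd between-sample sd of the wedge
#'   dimensions in mm (draws truncated at 2 sd and clipped to the imaging
#'   field of view); zero gives every sample the same geometry
#' @param grade_fractions proportions of groups I / II / >=III; sum to 1
#' @param zonal_truth data.frame as [zonal_truth_defaults]
#' @param compression_factors per-load area-retention fractions, starting
#'   at 1 (unloaded) and strictly decreasing
#' @param noise_sigma Rician noise scale in signal units
#' @param amplitude signal amplitude (arbitrary units)
#' @param sample_sigma log-scale sd of the per-sample relaxation factor
#' @param jitter_sigma log-scale sd of per-(zone, load) truth jitter
#' @param contrasts contrasts to simulate
#' @param biomech list: `b_mean`, `b_sd`, `b_coupling`, `c_mean`, `c_sd`
#'   (log-scale), `c_coupling`, `noise_frac` (stress noise as a fraction
#'   of max stress), `strain_grid`
#' @param apex_side image side of the meniscus apex
#' @param seed integer RNG seed
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(n = 45,
                         image_shape = c(64, 64),
                         pixel_size = 0.25,
                         wedge_width = 8.4,
                         wedge_height = 11.9,
                         wedge_width_sd = 1.3,
                         wedge_height_sd = 2.4,
                         grade_fractions = c(14, 16, 15) / 45,
                         zonal_truth = zonal_truth_defaults(),
                         compression_factors = c(1, 718 / 801, 604 / 801),
                         noise_sigma = 2,
                         amplitude = 100,
                         sample_sigma = 0.14,
                         jitter_sigma = 0.04,
                         contrasts = c("T1", "T1rho", "T2"),
                         biomech = list(b_mean = 4.9, b_sd = 0.4,
                                        b_coupling = 0.3, c_mean = 1.3,
                                        c_sd = 0.07, c_coupling = 0.1,
                                        noise_frac = 0.02,
                                        strain_grid = seq(0, 1, length.out = 101)),
                         apex_side = "left",
                         seed = 1L) {
  spec <- structure(
    list(n = n, image_shape = image_shape, pixel_size = pixel_size,
         wedge_width = wedge_width, wedge_height = wedge_height,
         wedge_width_sd = wedge_width_sd, wedge_height_sd = wedge_height_sd,
         grade_fractions = grade_fractions, zonal_truth = zonal_truth,
         compression_factors = compression_factors,
         noise_sigma = noise_sigma, amplitude = amplitude,
         sample_sigma = sample_sigma, jitter_sigma = jitter_sigma,
         contrasts = match.arg(contrasts, c("T1", "T1rho", "T2"),
                               several.ok = TRUE),
         biomech = biomech, apex_side = apex_side, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n < 1) stop("invalid spec: n must be >= 1")
    if (length(image_shape) != 2L || any(image_shape < 8))
      stop("invalid spec: image_shape must be two values >= 8")
    if (pixel_size <= 0) stop("invalid spec: pixel_size must be positive")
    if (wedge_width <= 0 || wedge_height <= 0)
      stop("invalid spec: wedge dimensions must be positive")
    if (wedge_width_sd < 0 || wedge_height_sd < 0)
      stop("invalid spec: wedge dimension sds must be >= 0")
    if (abs(sum(grade_fractions) - 1) > 1e-8)
      stop("invalid spec: grade_fractions must sum to 1")
    if (any(grade_fractions < 0))
      stop("invalid spec: grade_fractions must be non-negative")
    if (compression_factors[1] != 1)
      stop("invalid spec: compression_factors must start at 1 (unloaded)")
    if (any(diff(compression_factors) >= 0))
      stop("invalid spec: compression_factors must be strictly decreasing")
    if (any(compression_factors <= 0))
      stop("invalid spec: compression_factors must be positive")
    if (noise_sigma < 0) stop("invalid spec: noise_sigma must be >= 0")
    if (amplitude <= 0) stop("invalid spec: amplitude must be positive")
    if (any(zonal_truth$value <= 0))
      stop("invalid spec: zonal_truth values must be positive")
    if (!apex_side %in% c("left", "right"))
      stop("invalid spec: apex_side must be 'left' or 'right'")
  })
  invisible(spec)
}
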