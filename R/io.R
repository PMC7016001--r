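#' Write / read a signal stack as NIfTI with a JSON sidecar
#'
#' The stack is stored as a 4-D volume (rows x cols x 1 x points) with
#' the acquisition grid, contrast label and repetition time in a JSON
#' sidecar next to the image (same basename, `.json`).
#'
#' @param stack a [signal_stack]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @param pixel_size pixel edge length in mm (isotropic in-plane)
#' @return invisibly, the image path
#' @export
write_signal_stack <- function(stack, path, pixel_size = 0.25) {
  stopifnot(inherits(stack, "signal_stack"))
  d <- dim(stack$data)
  arr <- array(stack$data, c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr, pixdim = c(pixel_size, pixel_size, 1, 1))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(contrast = stack$contrast, times_ms = stack$times,
         tr_ms = stack$tr, pixel_size_mm = pixel_size),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal_stack
#' @export
read_signal_stack <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  d <- dim(img)
  arr <- array(as.array(img), c(d[1], d[2], d[length(d)]))
  signal_stack(arr, meta$times_ms, meta$contrast,
               if (is.null(meta$tr_ms)) NA_real_ else meta$tr_ms)
}

#' Write / read a binary mask as NIfTI
#'
#' @param mask logical or 0/1 matrix
#' @param path output path
#' @param pixel_size pixel edge length in mm
#' @export
write_mask <- function(mask, path, pixel_size = 0.25) {
  m <- check_mask(mask)
  img <- RNifti::asNifti(array(as.integer(m), dim = c(dim(m), 1L)),
                         pixdim = c(pixel_size, pixel_size, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- as.array(RNifti::readNifti(path))
  d <- dim(img)
  if (length(d) > 2L) img <- array(img, d)[, , 1]
  matrix(img > 0.5, d[1], d[2])
}

#' Write a fitted parameter map as NIfTI plus a diagnostics CSV
#'
#' The relaxation-time map goes to `<path>`; per-pixel diagnostics
#' (amplitude, convergence flag, residual norm) go to a CSV with the same
#' basename.
#'
#' @param map a `parameter_map`
#' @param path output `.nii` path
#' @param pixel_size pixel edge length in mm
#' @export
write_parameter_map <- function(map, path, pixel_size = 0.25) {
  stopifnot(inherits(map, "parameter_map"))
  t <- map$relaxation_time
  img <- RNifti::asNifti(array(ifelse(is.na(t), 0, t), c(dim(t), 1L)),
                         pixdim = c(pixel_size, pixel_size, 1))
  RNifti::writeNifti(img, path)
  idx <- which(!is.na(t), arr.ind = TRUE)
  diag <- data.frame(row = idx[, 1], col = idx[, 2],
                     relaxation_ms = t[idx],
                     amplitude = map$amplitude[idx],
                     converged = map$converged[idx],
                     residual_norm = map$residual_norm[idx])
  utils::write.csv(diag, sub("\\.nii(\\.gz)?$", "_diagnostics.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Read a stress-strain curve from CSV
#'
#' Expects columns `strain` (fraction) and `stress_MPa` (or `stress`).
#'
#' @param path CSV path
#' @return data.frame with columns `strain`, `stress`
#' @export
read_stress_strain <- function(path) {
  df <- utils::read.csv(path)
  if (!"strain" %in% names(df)) stop("CSV must contain a 'strain' column")
  stress_col <- intersect(c("stress_MPa", "stress"), names(df))[1]
  if (is.na(stress_col)) stop("CSV must contain 'stress_MPa' or 'stress'")
  data.frame(strain = df$strain, stress = df[[stress_col]])
}

#' Score a Pauli component table from CSV
#'
#' Expects columns `sample`, `surface`, `cellularity`, `collagen`,
#' `staining`; returns the table with `sum`, `grade` and `group` added.
#'
#' @param path CSV path
#' @export
read_pauli_scores <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample", "surface", "cellularity", "collagen", "staining")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  scored <- pauli_score(df$surface, df$cellularity, df$collagen, df$staining)
  cbind(sample = df$sample, scored)
}
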