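#' Remove boundary pixels from a segmentation mask
#'
#' Applies a one-pixel morphological erosion (8-connectivity, i.e. a 3x3
#' box structuring element) to a binary mask, dropping every mask pixel
#' that touches background. This is the standard guard against partial
#' volume effects at segmented tissue borders.
#'
#' @param mask logical or 0/1 integer matrix (rows x cols)
#' @param id optional sample identifier used in error messages
#' @return logical matrix of the same dimensions
#' @export
exclude_boundary <- function(mask, id = NULL) {
  mask <- check_mask(mask)
  # pad with background so pixels on the image border erode too
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  er <- EBImage::erode(padded, EBImage::makeBrush(3, shape = "box")) > 0.5
  eroded <- er[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  if (!any(eroded))
    stop(sprintf("mask%s is empty after boundary exclusion",
                 if (is.null(id)) "" else paste0(" '", id, "'")))
  eroded
}

#' Partition a mask into apex / intermediate / base thirds
#'
#' Projects the mask's most peripheral pixels onto the horizontal
#' (mediolateral) axis, divides the maximum mediolateral diameter into
#' thirds, and back-projects the cuts onto the mask: every mask pixel is
#' labelled by which third its column falls into. Zone I is the apex (the
#' tapering inner tip), zone II intermediate, zone III the base (the
#' peripheral rim). Which image side carries the apex is explicit
#' metadata, never inferred from content.
#'
#' Thirds are computed on the half-open column interval
#' `[x_min, x_max + 1)` and pixels are classified by their column centre
#' (`col + 1/2`); a centre landing exactly on a cut (impossible for
#' integer mask widths) would be assigned to the more apical zone. This
#' makes the partition deterministic, exactly conservative and exactly
#' mirror-equivariant.
#'
#' @param mask logical or 0/1 matrix
#' @param apex_side `"left"` or `"right"`: image side of the meniscus apex
#' @return An object of class `zonal_partition`: list with `labels`
#'   (integer matrix, 0 background, 1 apex, 2 intermediate, 3 base),
#'   `division_x` (the two cut positions in column coordinates) and
#'   `apex_side`.
#' @export
partition_thirds <- function(mask, apex_side = c("left", "right")) {
  apex_side <- match.arg(apex_side)
  mask <- check_mask(mask)
  cols <- which(colSums(mask) > 0)
  x_min <- min(cols); x_max <- max(cols)
  if (x_max - x_min + 1L < 3L)
    stop("mask spans fewer than 3 columns; cannot partition into thirds")
  # thirds of [x_min, x_max + 1); pixel centres at col + 1/2
  width <- x_max + 1 - x_min
  cut1 <- x_min + width / 3
  cut2 <- x_min + 2 * width / 3
  centre <- col(mask) + 0.5
  third <- ifelse(centre <= cut1, 1L, ifelse(centre <= cut2, 2L, 3L))
  if (apex_side == "right") third <- 4L - third
  labels <- ifelse(mask, third, 0L)
  structure(list(labels = labels, division_x = c(cut1, cut2),
                 apex_side = apex_side),
            class = "zonal_partition")
}

#' @export
print.zonal_partition <- function(x, ...) {
  counts <- zone_counts(x)
  cat("Zonal partition (apex on the", x$apex_side, "side)\n")
  cat(sprintf("  apex (I): %d px, intermediate (II): %d px, base (III): %d px\n",
              counts[["I"]], counts[["II"]], counts[["III"]]))
  invisible(x)
}

#' Pixel counts per zone
#'
#' @param partition a `zonal_partition`
#' @return named integer vector (I, II, III)
#' @export
zone_counts <- function(partition) {
  stopifnot(inherits(partition, "zonal_partition"))
  c(I = sum(partition$labels == 1L),
    II = sum(partition$labels == 2L),
    III = sum(partition$labels == 3L))
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.logical(mask)) m <- mask
  else if (all(mask %in% c(0, 1))) m <- mask > 0
  else stop("mask must be logical or 0/1")
  if (!any(m)) stop("mask is empty")
  m
}
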