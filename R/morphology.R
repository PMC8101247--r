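# Binary raster morphology built on the exact Euclidean distance transform.
# Masks are logical matrices; the pixel grid is row-major with origin at the
# top-left, x = column and y = row, 0-based in all user-facing coordinates.

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels (0 = background) with attribute `n`,
#'   the number of components.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  cpp_label(as_mask(mask), as.integer(connectivity))
}

#' Euclidean distance to the nearest foreground pixel
#'
#' Exact Euclidean distance transform: for every pixel, the distance in
#' pixel units to the nearest `TRUE` pixel of `mask` (0 inside the mask,
#' `Inf` everywhere if the mask is empty).
#'
#' @param mask logical matrix.
#' @return numeric matrix of distances in pixels.
#' @export
distance_to <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_edt(as_mask(mask))
}

#' Morphological dilation/erosion with a Euclidean disc
#'
#' Implemented by thresholding the exact distance transform, which gives a
#' true disc structuring element of radius `r_px` pixels.
#'
#' @param mask logical matrix.
#' @param r_px disc radius in pixels (may be fractional).
#' @return logical matrix.
#' @export
mask_dilate <- function(mask, r_px) {
  m <- as_mask(mask)
  if (r_px <= 0 || !any(m)) return(m)
  distance_to(m) <= r_px
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, r_px) {
  m <- as_mask(mask)
  if (r_px <= 0 || !any(m)) return(m)
  m & (distance_to(!m) > r_px)
}

#' @rdname mask_dilate
#' @export
mask_close <- function(mask, r_px) {
  mask_erode(mask_dilate(mask, r_px), r_px)
}

#' Fill holes in a binary mask
#'
#' Background components not connected (4-connectivity) to the image border
#' are switched to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  m <- as_mask(mask)
  bg <- label_components(!m, 4L)
  if (attr(bg, "n") == 0L) return(m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- !(bg %in% c(0L, border))
  m | matrix(hole, nrow(m), ncol(m))
}

#' Remove connected components below an area threshold
#'
#' @param mask logical matrix.
#' @param min_px minimum component size in pixels (components strictly
#'   smaller are removed).
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
remove_small_components <- function(mask, min_px, connectivity = 8L) {
  m <- as_mask(mask)
  if (!any(m) || min_px <= 1) return(m)
  lab <- label_components(m, connectivity)
  sz <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  keep <- which(sz >= min_px)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Box mean filter
#'
#' Mean over a (2r+1) x (2r+1) window, normalized by the number of in-image
#' pixels so borders are handled without padding bias.
#'
#' @param m numeric matrix.
#' @param r_px window half-width in pixels (integer).
#' @return numeric matrix of the same shape.
#' @export
box_mean <- function(m, r_px) {
  r <- as.integer(r_px)
  if (r <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero top row / left column
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- m
  S <- apply(S, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  i0 <- pmax(seq_len(nr) - r, 1L); i1 <- pmin(seq_len(nr) + r, nr)
  j0 <- pmax(seq_len(nc) - r, 1L); j1 <- pmin(seq_len(nc) + r, nc)
  box <- S[i1 + 1L, j1 + 1L, drop = FALSE] - S[i0, j1 + 1L, drop = FALSE] -
    S[i1 + 1L, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  cnt <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  box / cnt
}

#' Marker-based watershed segmentation
#'
#' Floods `mask` from the labelled `markers` in order of increasing
#' `elevation` (4-connectivity); every masked pixel reachable from a marker
#' receives the label of the first basin to arrive.
#'
#' @param elevation numeric matrix.
#' @param markers integer matrix of seed labels (0 = unseeded).
#' @param mask logical matrix restricting the flood.
#' @return integer label matrix.
#' @export
watershed_from_markers <- function(elevation, markers, mask) {
  stopifnot(all(dim(elevation) == dim(markers)),
            all(dim(elevation) == dim(mask)))
  cpp_watershed(elevation, markers, as_mask(mask))
}

# coerce to a logical matrix, preserving shape
as_mask <- function(mask) {
  if (is.logical(mask)) {
    mask
  } else {
    matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
}

#' Rasterize a disc into a logical mask
#'
#' Utility used by fixtures and the synthetic generator: pixels whose centre
#' lies within `r_px` of (`cx`, `cy`) (0-based x = column, y = row).
#'
#' @param nrow,ncol mask shape.
#' @param cx,cy disc centre in 0-based pixel coordinates.
#' @param r_px disc radius in pixels.
#' @return logical matrix.
#' @export
disc_mask <- function(nrow, ncol, cx, cy, r_px) {
  x <- matrix(rep(0:(ncol - 1L), each = nrow), nrow, ncol)
  y <- matrix(rep(0:(nrow - 1L), times = ncol), nrow, ncol)
  (x - cx)^2 + (y - cy)^2 <= r_px^2
}
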