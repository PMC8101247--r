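# Brightfield stain physics: Beer-Lambert optical density, H-DAB color
# deconvolution and the K7-positivity intensity cutoff.

#' H-DAB stain model
#'
#' Unit optical-density direction vectors for hematoxylin and DAB, using the
#' published Ruifrok-Johnston H-DAB convention; the residual vector completes
#' an orthonormal-ish invertible basis (cross product of the two, normalized).
#'
#' @param v_h,v_d numeric 3-vectors: OD directions of hematoxylin and DAB
#'   (normalized internally).
#' @param background_intensity transmitted intensity of unstained glass
#'   (default 255 for 8-bit images).
#' @return object of class `stain_model` with fields `v_h`, `v_d`, `v_r`,
#'   `m` (3x3 stain matrix, rows = stain vectors) and `background_intensity`.
#' @export
stain_model <- function(v_h = c(0.650, 0.704, 0.286),
                        v_d = c(0.268, 0.570, 0.776),
                        background_intensity = 255) {
  stopifnot(length(v_h) == 3L, length(v_d) == 3L, background_intensity > 0)
  v_h <- v_h / sqrt(sum(v_h^2))
  v_d <- v_d / sqrt(sum(v_d^2))
  v_r <- c(v_h[2] * v_d[3] - v_h[3] * v_d[2],
           v_h[3] * v_d[1] - v_h[1] * v_d[3],
           v_h[1] * v_d[2] - v_h[2] * v_d[1])
  nr <- sqrt(sum(v_r^2))
  if (nr < 1e-9) stop("hematoxylin and DAB vectors are collinear")
  v_r <- v_r / nr
  m <- rbind(h = v_h, d = v_d, r = v_r)
  if (abs(det(m)) < 1e-9) stop("singular stain matrix")
  structure(list(v_h = v_h, v_d = v_d, v_r = v_r, m = m,
                 background_intensity = background_intensity),
            class = "stain_model")
}

#' K7 positivity configuration
#'
#' The cutoff that separates deeply DAB-stained (positive) hepatocytes from
#' lightly stained (negative) ones, plus a minimum object area that
#' suppresses sub-cellular speckle. The numeric threshold default (0.7) is a
#' one-time calibration against the synthetic generator: "light" cells are
#' rendered at DAB concentration 0.4 and must be negative, "deep brown"
#' cells at 1.0 and must be positive.
#'
#' @param dab_threshold DAB concentration cutoff (> 0).
#' @param min_object_area_um2 minimum connected-component area in square
#'   micrometres; default is the area of a 10 um-diameter disc, below
#'   plausible hepatocyte size (~25 um).
#' @return object of class `positivity_config`.
#' @export
positivity_config <- function(dab_threshold = 0.7,
                              min_object_area_um2 = pi * 5^2) {
  stopifnot(dab_threshold > 0, min_object_area_um2 > 0)
  structure(list(dab_threshold = dab_threshold,
                 min_object_area_um2 = min_object_area_um2),
            class = "positivity_config")
}

#' RGB image to per-channel optical density
#'
#' Beer-Lambert: `OD_c = -log10(max(I_c, 1) / background)`. Intensities above
#' the background are clipped to it, so OD is always non-negative.
#'
#' @param image numeric array `h x w x 3` of intensities in
#'   `[0, background_intensity]`.
#' @param background_intensity transmitted background intensity (> 0).
#' @return numeric array `h x w x 3` of optical densities.
#' @export
rgb_to_od <- function(image, background_intensity = 255) {
  if (background_intensity <= 0)
    stop("background_intensity must be positive")
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  i <- pmin(pmax(image, 1), background_intensity)
  -log10(i / background_intensity)
}

#' Separate hematoxylin and DAB concentrations from optical density
#'
#' Solves the linear color-deconvolution system per pixel: concentrations =
#' inverse(stain matrix) x OD, clamped at zero.
#'
#' @param od numeric array `h x w x 3` of optical densities.
#' @param model a [stain_model()].
#' @return list of numeric matrices `hematoxylin`, `dab`, `residual`.
#' @export
separate_stains <- function(od, model = stain_model()) {
  stopifnot(inherits(model, "stain_model"),
            length(dim(od)) == 3L, dim(od)[3] == 3L)
  d <- dim(od)
  flat <- matrix(od, d[1] * d[2], 3L)          # pixels x channels
  conc <- flat %*% solve(model$m)              # solve c M = od per pixel
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab = matrix(conc[, 2], d[1], d[2]),
       residual = matrix(conc[, 3], d[1], d[2]))
}

#' K7-positive mask from a DAB concentration grid
#'
#' Thresholds the DAB concentration inside `region`, then removes connected
#' components smaller than the configured minimum object area. The output is
#' always a subset of `region` (the clipping contract).
#'
#' @param dab numeric matrix of DAB concentrations.
#' @param region logical matrix; analysis is restricted to it.
#' @param cfg a [positivity_config()].
#' @param pixel_size_um pixel edge length in micrometres.
#' @return logical matrix.
#' @export
k7_positive_mask <- function(dab, region, cfg = positivity_config(),
                             pixel_size_um) {
  stopifnot(inherits(cfg, "positivity_config"), pixel_size_um > 0)
  if (!all(dim(dab) == dim(region)))
    stop("dab and region shapes differ")
  m <- (dab >= cfg$dab_threshold) & as_mask(region)
  min_px <- cfg$min_object_area_um2 / pixel_size_um^2
  remove_small_components(m, min_px)
}
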