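# Nested three-layer segmentation: tissue -> portal/parenchyma -> K7-positive
# hepatocytes, each layer clipped by its parent. Deterministic optical-density
# and morphology operators stand in for the learned models; the layer
# semantics and the clipping contract are identical, so any stage can be
# replaced by a different backend without touching downstream code.

#' Nested layer masks
#'
#' Container for the pipeline's structural output. Invariants (checked):
#' all masks share one shape; `portal` and `parenchyma` are disjoint and
#' their union is contained in `tissue`; `k7` is contained in `parenchyma`.
#'
#' @param tissue,portal,parenchyma,k7 logical matrices.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return object of class `layer_masks`.
#' @export
layer_masks <- function(tissue, portal, parenchyma, k7, pixel_size_um) {
  tissue <- as_mask(tissue); portal <- as_mask(portal)
  parenchyma <- as_mask(parenchyma); k7 <- as_mask(k7)
  if (!all(dim(tissue) == dim(portal)) ||
      !all(dim(tissue) == dim(parenchyma)) ||
      !all(dim(tissue) == dim(k7)))
    stop("all layer masks must share one shape")
  if (any(portal & parenchyma))
    stop("portal and parenchyma masks overlap")
  if (any((portal | parenchyma) & !tissue))
    stop("portal/parenchyma extend outside the tissue mask")
  if (any(k7 & !parenchyma))
    stop("k7 mask extends outside the parenchyma mask")
  stopifnot(pixel_size_um > 0)
  structure(list(tissue = tissue, portal = portal, parenchyma = parenchyma,
                 k7 = k7, pixel_size_um = pixel_size_um),
            class = "layer_masks")
}

#' Region-of-interest polygon
#'
#' A simple (non-self-intersecting) polygon in 0-based pixel coordinates
#' (x = column, y = row), implicitly closed. Used to restrict analysis to a
#' single biopsy section when a slide carries several.
#'
#' @param vertices numeric matrix (or list of pairs) with columns x, y;
#'   at least 3 vertices.
#' @return object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, unlist))
  vertices <- matrix(as.numeric(vertices), ncol = 2L)
  if (nrow(vertices) < 3L) stop("ROI polygon needs at least 3 vertices")
  if (polygon_self_intersects(vertices))
    stop("ROI polygon is self-intersecting")
  structure(list(vertices = vertices), class = "roi_polygon")
}

# segment-intersection test over all non-adjacent edge pairs (polygons are
# small, O(n^2) is fine)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross_dir <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross_dir(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross_dir(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross_dir(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross_dir(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

# even-odd scanline rasterization of a polygon onto an h x w grid; the
# boundary is treated inclusively (pixels whose centre lies on an edge are
# inside), so a full-frame rectangle validates every pixel
rasterize_polygon <- function(roi, h, w) {
  v <- roi$vertices
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[c(2:n, 1L), 1]; y2 <- v[c(2:n, 1L), 2]
  out <- matrix(FALSE, h, w)
  for (row in 0:(h - 1L)) {
    yc <- row
    crosses <- ((y1 <= yc) & (y2 > yc)) | ((y2 <= yc) & (y1 > yc))
    if (!any(crosses)) next
    xi <- x1[crosses] + (yc - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      c0 <- max(0L, as.integer(ceiling(xi[k])))
      c1 <- min(w - 1L, as.integer(floor(xi[k + 1L])))
      if (c0 <= c1) out[row + 1L, (c0 + 1L):(c1 + 1L)] <- TRUE
    }
  }
  # inclusive boundary: walk each edge and mark traversed pixels
  for (e in seq_len(n)) {
    len <- sqrt((x2[e] - x1[e])^2 + (y2[e] - y1[e])^2)
    t <- seq(0, 1, length.out = max(2L, as.integer(ceiling(len * 2)) + 1L))
    px <- as.integer(round(x1[e] + t * (x2[e] - x1[e])))
    py <- as.integer(round(y1[e] + t * (y2[e] - y1[e])))
    keep <- px >= 0L & px < w & py >= 0L & py < h
    out[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  }
  out
}

#' Pipeline configuration
#'
#' Tunable parameters of the deterministic segmentation backend, in physical
#' units so behaviour is resolution-independent.
#'
#' @param pixel_size_um pixel edge length (um).
#' @param od_tissue_threshold total optical density above which a pixel is
#'   tissue candidate.
#' @param tissue_close_um closing radius for the tissue mask.
#' @param min_tissue_fragment_mm2 minimum tissue fragment kept (default
#'   0.01 mm^2).
#' @param hema_smooth_um box-filter half-width for the hematoxylin density
#'   field used in portal detection.
#' @param portal_hema_threshold smoothed hematoxylin concentration above
#'   which a pixel belongs to a dense portal core.
#' @param portal_dilation_um dilation of the portal core absorbing the
#'   immediately adjacent ductular reaction (default 15 um).
#' @param min_portal_area_um2 minimum portal component area (default: 30 um
#'   diameter disc).
#' @param positivity a [positivity_config()].
#' @param sinusoid_length_um portal sinusoid length used for zones.
#' @param stains a [stain_model()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.221,
                            od_tissue_threshold = 0.1,
                            tissue_close_um = 5,
                            min_tissue_fragment_mm2 = 0.01,
                            hema_smooth_um = 8,
                            portal_hema_threshold = 0.5,
                            portal_dilation_um = 15,
                            min_portal_area_um2 = pi * 15^2,
                            positivity = positivity_config(),
                            sinusoid_length_um = 584,
                            stains = stain_model()) {
  stopifnot(pixel_size_um > 0, od_tissue_threshold > 0,
            inherits(positivity, "positivity_config"),
            inherits(stains, "stain_model"))
  structure(list(pixel_size_um = pixel_size_um,
                 od_tissue_threshold = od_tissue_threshold,
                 tissue_close_um = tissue_close_um,
                 min_tissue_fragment_mm2 = min_tissue_fragment_mm2,
                 hema_smooth_um = hema_smooth_um,
                 portal_hema_threshold = portal_hema_threshold,
                 portal_dilation_um = portal_dilation_um,
                 min_portal_area_um2 = min_portal_area_um2,
                 positivity = positivity,
                 sinusoid_length_um = sinusoid_length_um,
                 stains = stains),
            class = "pipeline_config")
}

#' Apply a region of interest
#'
#' Marks pixels outside the ROI invalid; they are treated as background by
#' every later stage. Absent ROI means the whole image is valid.
#'
#' @param image RGB array `h x w x 3`.
#' @param roi a [roi_polygon()] or `NULL`.
#' @return list with `image` and `validity` (logical matrix).
#' @export
apply_roi <- function(image, roi = NULL) {
  stopifnot(length(dim(image)) == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi)) return(list(image = image, validity = matrix(TRUE, h, w)))
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  if (any(v[, 1] < 0 | v[, 1] > w - 1 | v[, 2] < 0 | v[, 2] > h - 1))
    stop("ROI polygon extends outside the image bounds")
  list(image = image, validity = rasterize_polygon(roi, h, w))
}

#' Layer 1: liver tissue segmentation
#'
#' Pixels whose total optical density exceeds a background threshold,
#' morphologically closed and hole-filled; fragments below the minimum
#' tissue area are discarded, and the mask is clipped to `validity`.
#'
#' @param image RGB array.
#' @param validity logical matrix from [apply_roi()].
#' @param config a [pipeline_config()].
#' @return logical tissue mask.
#' @export
segment_tissue <- function(image, validity = NULL, config = pipeline_config()) {
  px <- config$pixel_size_um
  od <- rgb_to_od(image, config$stains$background_intensity)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  m <- tot > config$od_tissue_threshold
  if (!is.null(validity)) m <- m & as_mask(validity)
  m <- mask_close(m, config$tissue_close_um / px)
  m <- fill_holes(m)
  min_px <- config$min_tissue_fragment_mm2 * 1e6 / px^2
  m <- remove_small_components(m, min_px)
  if (!is.null(validity)) m <- m & as_mask(validity)
  m
}

#' Layer 2: portal areas vs parenchyma within tissue
#'
#' Portal cores are regions of high smoothed hematoxylin density (portal
#' tracts are nuclei- and stroma-dense); DAB-positive ductal structures
#' adjoining a core are merged in, and the result is dilated by
#' `portal_dilation_um` to absorb the periportal ductular reaction.
#' Parenchyma is the exact complement within tissue, so disjointness and
#' coverage hold by construction.
#'
#' @param image RGB array.
#' @param tissue logical tissue mask from [segment_tissue()].
#' @param config a [pipeline_config()].
#' @return list with `portal` and `parenchyma` logical masks.
#' @export
segment_portal_parenchyma <- function(image, tissue,
                                      config = pipeline_config()) {
  px <- config$pixel_size_um
  tissue <- as_mask(tissue)
  if (!any(tissue))
    return(list(portal = tissue & FALSE, parenchyma = tissue & FALSE))
  od <- rgb_to_od(image, config$stains$background_intensity)
  conc <- separate_stains(od, config$stains)
  hema <- conc$hematoxylin
  hema[!tissue] <- 0
  sm <- box_mean(hema, round(config$hema_smooth_um / px))
  core <- sm > config$portal_hema_threshold & tissue
  min_px <- config$min_portal_area_um2 / px^2
  core <- remove_small_components(core, min_px)
  portal <- mask_dilate(core, config$portal_dilation_um / px) & tissue
  # pull in DAB-positive ductal rings touching the dilated core
  if (any(portal)) {
    dabm <- conc$dab >= config$positivity$dab_threshold & tissue
    if (any(dabm)) {
      lab <- label_components(dabm, 8L)
      touching <- unique(lab[lab > 0L & portal])
      if (length(touching) > 0L)
        portal <- portal | matrix(lab %in% touching, nrow(lab), ncol(lab))
    }
    portal <- remove_small_components(portal, min_px) & tissue
  }
  list(portal = portal, parenchyma = tissue & !portal)
}

#' Layer 3: K7-positive hepatocytes within parenchyma
#'
#' Applies the DAB positivity cutoff inside the parenchyma mask only.
#' DAB-positive bile-duct epithelium and ductular reaction are excluded
#' automatically because they lie in the portal mask — clipping, not shape
#' analysis, resolves the ambiguity.
#'
#' @param image RGB array.
#' @param parenchyma logical mask from [segment_portal_parenchyma()].
#' @param config a [pipeline_config()].
#' @return logical K7 mask.
#' @export
segment_k7_hepatocytes <- function(image, parenchyma,
                                   config = pipeline_config()) {
  parenchyma <- as_mask(parenchyma)
  if (!any(parenchyma)) return(parenchyma)
  od <- rgb_to_od(image, config$stains$background_intensity)
  conc <- separate_stains(od, config$stains)
  k7_positive_mask(conc$dab, parenchyma, config$positivity,
                   config$pixel_size_um)
}

#' Run the full nested pipeline
#'
#' `apply_roi` -> `segment_tissue` -> `segment_portal_parenchyma` ->
#' `segment_k7_hepatocytes`, each stage clipped by its parent. An empty
#' tissue mask yields a warning and a valid all-empty result.
#'
#' @param image RGB array `h x w x 3`.
#' @param roi optional [roi_polygon()].
#' @param config a [pipeline_config()].
#' @return a [layer_masks()] with attribute `stage_areas_mm2` (named vector
#'   of per-stage areas).
#' @export
run_pipeline <- function(image, roi = NULL, config = pipeline_config()) {
  st <- apply_roi(image, roi)
  tissue <- segment_tissue(st$image, st$validity, config)
  if (!any(tissue))
    warning("no tissue detected; returning empty layer masks")
  pp <- segment_portal_parenchyma(st$image, tissue, config)
  k7 <- segment_k7_hepatocytes(st$image, pp$parenchyma, config)
  out <- layer_masks(tissue, pp$portal, pp$parenchyma, k7,
                     config$pixel_size_um)
  px2 <- config$pixel_size_um^2 / 1e6
  attr(out, "stage_areas_mm2") <- c(
    tissue = sum(tissue) * px2, portal = sum(pp$portal) * px2,
    parenchyma = sum(pp$parenchyma) * px2, k7 = sum(k7) * px2)
  out
}
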