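# Per-specimen quantities: layer areas and proportions, K7%area, K7-positive
# cell instances, portal distances and periportal zone assignment.

#' Layer areas and tissue proportions
#'
#' Areas are pixel counts times the squared pixel size, reported in mm^2;
#' portal and parenchyma proportions are percentages of the tissue area.
#' With zero tissue all areas are 0 and proportions are `NA`.
#'
#' @param masks a [layer_masks()].
#' @return named list: `tissue_area_mm2`, `portal_area_mm2`,
#'   `parenchyma_area_mm2`, `k7_area_mm2`, `portal_fraction_pct`,
#'   `parenchyma_fraction_pct`.
#' @export
layer_areas <- function(masks) {
  stopifnot(inherits(masks, "layer_masks"))
  px2 <- masks$pixel_size_um^2 / 1e6   # um^2 -> mm^2
  nt <- sum(masks$tissue); np <- sum(masks$portal)
  npa <- sum(masks$parenchyma); nk <- sum(masks$k7)
  list(tissue_area_mm2 = nt * px2,
       portal_area_mm2 = np * px2,
       parenchyma_area_mm2 = npa * px2,
       k7_area_mm2 = nk * px2,
       portal_fraction_pct = if (nt > 0) 100 * np / nt else NA_real_,
       parenchyma_fraction_pct = if (nt > 0) 100 * npa / nt else NA_real_)
}

#' K7%area: percentage of parenchyma occupied by K7-positive hepatocytes
#'
#' The pipeline's core statistic: `100 * |k7| / |parenchyma|` in pixel
#' counts. In `[0, 100]` by the nesting invariant. An empty parenchyma
#' yields `NA` with a warning (not an error).
#'
#' @param masks a [layer_masks()].
#' @return numeric scalar (or `NA`).
#' @export
k7_area_fraction <- function(masks) {
  stopifnot(inherits(masks, "layer_masks"))
  npa <- sum(masks$parenchyma)
  if (npa == 0) {
    warning("empty parenchyma mask; K7%area undefined")
    return(NA_real_)
  }
  100 * sum(masks$k7) / npa
}

#' Detect K7-positive cell instances
#'
#' Connected components (8-connectivity) of the K7 mask. Components with
#' equivalent diameter below `size_bounds_um[1]` are dropped as speckle;
#' components whose interior distance transform shows multiple cores
#' (merged cells, e.g. touching discs) are split by marker-based watershed
#' along the distance-transform valley. Centroids are unweighted pixel
#' means in 0-based pixel coordinates.
#'
#' @param k7 logical K7 mask.
#' @param pixel_size_um pixel edge length (um).
#' @param size_bounds_um `(min, max)` plausible hepatocyte equivalent
#'   diameters, default `c(10, 40)` um.
#' @return data frame with columns `cell_id`, `x`, `y`, `area_um2`,
#'   `equivalent_diameter_um` (distances and zones unset; see
#'   [portal_distances()]).
#' @export
cell_instances <- function(k7, pixel_size_um, size_bounds_um = c(10, 40)) {
  stopifnot(pixel_size_um > 0, length(size_bounds_um) == 2L,
            size_bounds_um[1] < size_bounds_um[2])
  k7 <- as_mask(k7)
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0))
  if (!any(k7)) return(empty)
  lab <- label_components(k7, 8L)
  n <- attr(lab, "n")
  rows <- list()  # each entry: list(idx_y, idx_x) of 0-based pixel coords
  for (id in seq_len(n)) {
    idx <- which(lab == id)
    yy <- (idx - 1L) %% nrow(lab)
    xx <- (idx - 1L) %/% nrow(lab)
    a_um2 <- length(idx) * pixel_size_um^2
    d_um <- 2 * sqrt(a_um2 / pi)
    if (d_um < size_bounds_um[1]) next
    subs <- split_component(yy, xx)
    for (s in subs) rows[[length(rows) + 1L]] <- s
  }
  if (length(rows) == 0L) return(empty)
  out <- lapply(seq_along(rows), function(i) {
    s <- rows[[i]]
    a_um2 <- length(s$y) * pixel_size_um^2
    data.frame(cell_id = i, x = mean(s$x), y = mean(s$y), area_um2 = a_um2,
               equivalent_diameter_um = 2 * sqrt(a_um2 / pi))
  })
  do.call(rbind, out)
}

# Watershed split of one component, given its 0-based pixel coordinates.
# Markers are the connected cores of the interior distance transform above
# 55% of its maximum: a lone convex cell has a single core and is returned
# unsplit; merged cells (e.g. a touching-disc barbell) have one core per
# lobe and are divided along the distance-transform valley. Work is done on
# the component's bounding box only.
split_component <- function(yy, xx) {
  y0 <- min(yy); x0 <- min(xx)
  comp <- matrix(FALSE, max(yy) - y0 + 3L, max(xx) - x0 + 3L)
  comp[cbind(yy - y0 + 2L, xx - x0 + 2L)] <- TRUE
  d <- distance_to(!comp)
  d[!comp] <- 0
  markers <- label_components(d >= 0.55 * max(d), 8L)
  whole <- list(list(y = yy, x = xx))
  if (attr(markers, "n") < 2L) return(whole)
  lab <- watershed_from_markers(-d, markers, comp)
  lapply(seq_len(attr(markers, "n")), function(k) {
    idx <- which(lab == k)
    list(y = (idx - 1L) %% nrow(lab) + y0 - 2L,
         x = (idx - 1L) %/% nrow(lab) + x0 - 2L)
  })
}

#' Distances from cells to the nearest portal area
#'
#' Euclidean distance transform of the portal complement sampled at each
#' cell centroid, scaled to micrometres; zone labels from [assign_zone()].
#' An empty portal mask yields `NA` distances with a warning.
#'
#' @param instances data frame from [cell_instances()].
#' @param portal logical portal mask.
#' @param pixel_size_um pixel edge length (um).
#' @param sinusoid_length_um sinusoid length for zone assignment.
#' @return list: `instances` (with `distance_to_portal_um` and `zone`
#'   columns) and `mean_distance_um` (`NA` when there are no cells or no
#'   portal mask).
#' @export
portal_distances <- function(instances, portal, pixel_size_um,
                             sinusoid_length_um = 584) {
  portal <- as_mask(portal)
  if (nrow(instances) == 0L) {
    instances$distance_to_portal_um <- numeric(0)
    instances$zone <- integer(0)
    return(list(instances = instances, mean_distance_um = NA_real_))
  }
  if (!any(portal)) {
    warning("empty portal mask; portal distances undefined")
    instances$distance_to_portal_um <- NA_real_
    instances$zone <- NA_integer_
    return(list(instances = instances, mean_distance_um = NA_real_))
  }
  d <- distance_to(portal)
  ri <- pmin(pmax(as.integer(round(instances$y)) + 1L, 1L), nrow(portal))
  ci <- pmin(pmax(as.integer(round(instances$x)) + 1L, 1L), ncol(portal))
  dist_um <- d[cbind(ri, ci)] * pixel_size_um
  instances$distance_to_portal_um <- dist_um
  instances$zone <- assign_zone(dist_um, sinusoid_length_um)
  list(instances = instances, mean_distance_um = mean(dist_um))
}

#' Periportal zone from portal distance
#'
#' Zone 1 (periportal) is the nearest third of the portal sinusoid length
#' `L`: zone 1 for `d < L/3`, zone 2 for `L/3 <= d < 2L/3`, zone 3
#' otherwise.
#'
#' @param distance_um non-negative distance(s) in micrometres (vectorized).
#' @param sinusoid_length_um sinusoid length `L` (> 0); default 584, the
#'   midpoint of the 447-721 um normal range.
#' @return integer vector of zones in `{1, 2, 3}`.
#' @export
assign_zone <- function(distance_um, sinusoid_length_um = 584) {
  stopifnot(sinusoid_length_um > 0)
  if (any(distance_um < 0, na.rm = TRUE))
    stop("distance_um must be non-negative")
  l3 <- sinusoid_length_um / 3
  ifelse(distance_um < l3, 1L, ifelse(distance_um < 2 * l3, 2L, 3L))
}

#' Full per-specimen quantification
#'
#' Convenience chain over a [layer_masks()]: areas, K7%area, instances,
#' distances and the automated K7 score.
#'
#' @param masks a [layer_masks()].
#' @param specimen_id identifier for the output row.
#' @param config a [pipeline_config()] (sinusoid length, positivity).
#' @param size_bounds_um passed to [cell_instances()].
#' @return list with `record` (one-row data frame: specimen_id, areas,
#'   fractions, `k7_area_pct`, `n_k7_cells`, `mean_distance_um`, `k7_score`,
#'   `subthreshold_positive`) and `instances` (per-cell data frame).
#' @export
quantify_specimen <- function(masks, specimen_id = "specimen",
                              config = pipeline_config(),
                              size_bounds_um = c(10, 40)) {
  stopifnot(inherits(masks, "layer_masks"))
  ar <- layer_areas(masks)
  k7pct <- if (sum(masks$parenchyma) > 0) k7_area_fraction(masks) else NA_real_
  inst <- cell_instances(masks$k7, masks$pixel_size_um, size_bounds_um)
  pd <- suppressWarnings(
    portal_distances(inst, masks$portal, masks$pixel_size_um,
                     config$sinusoid_length_um))
  regions <- periportal_regions(masks$portal,
                                band_width_um = config$sinusoid_length_um / 3,
                                pixel_size_um = masks$pixel_size_um)
  sc <- k7_score(pd$instances, regions)
  record <- data.frame(
    specimen_id = specimen_id,
    tissue_area_mm2 = ar$tissue_area_mm2,
    portal_area_mm2 = ar$portal_area_mm2,
    parenchyma_area_mm2 = ar$parenchyma_area_mm2,
    portal_fraction_pct = ar$portal_fraction_pct,
    parenchyma_fraction_pct = ar$parenchyma_fraction_pct,
    k7_area_pct = k7pct,
    n_k7_cells = nrow(pd$instances),
    mean_distance_um = pd$mean_distance_um,
    k7_score = sc$score,
    n_periportal = sc$n_periportal,
    n_positive_regions = sc$n_positive_regions,
    positive_fraction = sc$positive_fraction,
    subthreshold_positive = sc$subthreshold_positive)
  list(record = record, instances = pd$instances)
}
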