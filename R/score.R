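# Automated K7 deposition score (ordinal 0-3), emulating the human scoring
# protocol: a periportal region (zone-1 band around one portal tract) is
# positive when it holds at least `min_cells` K7-positive hepatocytes; the
# score follows the fraction of positive regions.

#' Periportal (zone 1) regions around portal components
#'
#' One region per connected portal component; its band is the set of pixels
#' within `band_width_um` of the component, excluding the portal mask
#' itself. Default band width is one third of the sinusoid length (zone 1).
#'
#' @param portal logical portal mask.
#' @param band_width_um band width in micrometres (default 584/3).
#' @param pixel_size_um pixel edge length (um).
#' @return object of class `periportal_regions`: list with `n_periportal`,
#'   `status` (`"ok"` or `"unscorable"` for an empty portal mask),
#'   `band_width_um`, and per-region fields `component_id`, `bands` (list of
#'   logical masks), `dist_px` (list of distance maps to each component).
#' @export
periportal_regions <- function(portal, band_width_um = 584 / 3,
                               pixel_size_um) {
  stopifnot(band_width_um > 0, pixel_size_um > 0)
  portal <- as_mask(portal)
  if (!any(portal))
    return(structure(list(n_periportal = 0L, status = "unscorable",
                          band_width_um = band_width_um,
                          pixel_size_um = pixel_size_um,
                          component_id = integer(0), bands = list(),
                          dist_px = list()),
                     class = "periportal_regions"))
  lab <- label_components(portal, 8L)
  n <- attr(lab, "n")
  band_px <- band_width_um / pixel_size_um
  bands <- vector("list", n)
  dists <- vector("list", n)
  for (k in seq_len(n)) {
    d <- distance_to(lab == k)
    dists[[k]] <- d
    bands[[k]] <- (d <= band_px) & !portal
  }
  structure(list(n_periportal = n, status = "ok",
                 band_width_um = band_width_um,
                 pixel_size_um = pixel_size_um,
                 component_id = seq_len(n), bands = bands, dist_px = dists),
            class = "periportal_regions")
}

#' Automated K7 deposition score (0-3)
#'
#' Each cell is assigned to its nearest portal component (ties broken by
#' lower component id) and counts for that region when it lies within the
#' region's zone-1 band. A region is positive when it holds at least
#' `min_cells` cells. Scoring: 0 with no cells at all, or with cells but no
#' positive region (flagged `subthreshold_positive`); 1 when exactly one
#' region is positive or the positive fraction f is below 1/3; 2 when
#' 1/3 <= f <= 2/3; 3 when f > 2/3.
#'
#' @param instances data frame with columns `x`, `y` (0-based pixel
#'   centroids), e.g. from [cell_instances()].
#' @param regions a [periportal_regions()].
#' @param min_cells minimum cells for a positive region (default 10, "at
#'   least ten hepatocytes").
#' @return object of class `k7_score`: list with `score` (integer, `NA` when
#'   unscorable), `n_periportal`, `n_positive_regions`, `positive_fraction`,
#'   `region_counts`, `subthreshold_positive`, `status`.
#' @export
k7_score <- function(instances, regions, min_cells = 10L) {
  stopifnot(inherits(regions, "periportal_regions"))
  if (min_cells < 1L) stop("min_cells must be at least 1")
  if (regions$status == "unscorable")
    return(structure(list(score = NA_integer_, n_periportal = 0L,
                          n_positive_regions = 0L,
                          positive_fraction = NA_real_,
                          region_counts = integer(0),
                          subthreshold_positive = FALSE,
                          status = "unscorable"),
                     class = "k7_score"))
  n <- regions$n_periportal
  counts <- integer(n)
  n_cells <- nrow(instances)
  if (n_cells > 0L) {
    h <- nrow(regions$bands[[1]]); w <- ncol(regions$bands[[1]])
    ri <- pmin(pmax(as.integer(round(instances$y)) + 1L, 1L), h)
    ci <- pmin(pmax(as.integer(round(instances$x)) + 1L, 1L), w)
    dmat <- vapply(regions$dist_px,
                   function(d) d[cbind(ri, ci)], numeric(n_cells))
    dmat <- matrix(dmat, nrow = n_cells)
    nearest <- apply(dmat, 1L, which.min)          # ties -> lower id
    band_px <- regions$band_width_um / regions$pixel_size_um
    within <- dmat[cbind(seq_len(n_cells), nearest)] <= band_px
    for (k in seq_len(n))
      counts[k] <- sum(nearest == k & within)
  }
  pos <- sum(counts >= min_cells)
  f <- pos / n
  score <- if (n_cells == 0L || pos == 0L) 0L
  else if (pos == 1L || f < 1 / 3) 1L
  else if (f <= 2 / 3) 2L
  else 3L
  structure(list(score = score, n_periportal = n, n_positive_regions = pos,
                 positive_fraction = f, region_counts = counts,
                 subthreshold_positive = (n_cells > 0L && pos == 0L),
                 status = "ok"),
            class = "k7_score")
}
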