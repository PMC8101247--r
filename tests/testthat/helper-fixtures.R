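# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures on disk.

# small, fast generator config used across suites: 2 um/px tiles keep pixel
# counts low while all physical-unit parameters stay at their defaults
small_gen_config <- function(seed = 1L, severity = 0.5, h = 200L, w = 400L,
                             n_portal = 3L, portal_radius = 45,
                             pixel_size = 2, ...) {
  generator_config(image_height_px = h, image_width_px = w,
                   pixel_size_um = pixel_size, n_portal_areas = n_portal,
                   portal_radius_um = portal_radius,
                   severity = severity, seed = seed, ...)
}

small_pipe_config <- function(pixel_size = 2, ...) {
  pipeline_config(pixel_size_um = pixel_size, ...)
}

dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# independent brute-force confusion-matrix oracle: explicit pixel loop,
# no vectorized reuse of the implementation's logic
oracle_layer_metrics <- function(pred, gt, ev) {
  tp <- fp <- fn <- n <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (!ev[i, j]) next
      n <- n + 1L
      p <- pred[i, j]; g <- gt[i, j]
      if (p && g) tp <- tp + 1L
      else if (p && !g) fp <- fp + 1L
      else if (!p && g) fn <- fn + 1L
    }
  }
  list(fp_pct = 100 * fp / n, fn_pct = 100 * fn / n,
       total = 100 * (fp + fn) / n,
       precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
}

# textbook product-moment formula, written independently of pearson_cor
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# mid-ranks by hand: rank = (number strictly smaller) + (ties + 1) / 2
oracle_midrank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# portal mask with n well-separated square components on one row; returns
# the mask plus component centres (0-based x, y)
separated_portal_fixture <- function(n = 6L, h = 120L, w = 60L * n,
                                     half = 8L) {
  m <- matrix(FALSE, h, w)
  centers <- matrix(0, n, 2L)
  for (k in seq_len(n)) {
    cx <- 30L + (k - 1L) * 60L
    cy <- 30L
    m[(cy - half):(cy + half) + 1L, (cx - half):(cx + half) + 1L] <- TRUE
    centers[k, ] <- c(cx, cy)
  }
  list(mask = m, centers = centers)
}

# cell-instance data frame at explicit centroid positions
cells_at <- function(xy) {
  data.frame(cell_id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
             area_um2 = rep(490, nrow(xy)),
             equivalent_diameter_um = rep(25, nrow(xy)))
}

# place k cells clustered just outside one portal component
cells_near_component <- function(center, k, offset = 12L, spacing = 3L) {
  xs <- center[1] + offset + (seq_len(k) - 1L) %% 5L * spacing
  ys <- center[2] + (seq_len(k) - 1L) %/% 5L * spacing
  cbind(xs, ys)
}
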