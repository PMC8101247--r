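test_that("layer areas use pixel count times squared pixel size", {
  t <- matrix(FALSE, 50, 50); t[1:40, 1:25] <- TRUE  # 1000 tissue px
  masks <- layer_masks(t, matrix(FALSE, 50, 50), t, matrix(FALSE, 50, 50),
                       pixel_size_um = 0.221)
  ar <- layer_areas(masks)
  expect_equal(ar$tissue_area_mm2 * 1e6, 1000 * 0.221^2)  # 48.841 um^2
  # portal empty -> parenchyma fraction 100
  expect_equal(ar$parenchyma_fraction_pct, 100)
  expect_equal(ar$portal_fraction_pct + ar$parenchyma_fraction_pct, 100)
  # zero tissue -> zero areas, absent fractions
  f <- matrix(FALSE, 5, 5)
  ar0 <- layer_areas(layer_masks(f, f, f, f, 1))
  expect_equal(ar0$tissue_area_mm2, 0)
  expect_true(is.na(ar0$portal_fraction_pct))
})

test_that("fractions sum to 100 for arbitrary non-empty partitions", {
  set.seed(31)
  for (rep in 1:10) {
    t <- matrix(runif(400) < 0.6, 20, 20)
    if (!any(t)) next
    p <- t & matrix(runif(400) < 0.3, 20, 20)
    masks <- layer_masks(t, p, t & !p, matrix(FALSE, 20, 20), 1)
    ar <- layer_areas(masks)
    expect_equal(ar$portal_fraction_pct + ar$parenchyma_fraction_pct, 100)
  }
})

test_that("k7_area_fraction edge cases and exact generator recovery", {
  t <- matrix(TRUE, 10, 10); f <- matrix(FALSE, 10, 10)
  expect_equal(k7_area_fraction(layer_masks(t, f, t, t, 1)), 100)
  expect_equal(k7_area_fraction(layer_masks(t, f, t, f, 1)), 0)
  expect_warning(v <- k7_area_fraction(layer_masks(t, t, f, f, 1)),
                 "empty parenchyma")
  expect_true(is.na(v))

  for (seed in c(5L, 16L)) {
    sp <- generate_specimen(small_gen_config(seed = seed, severity = 0.6))
    expect_identical(k7_area_fraction(sp$gt_masks),
                     sp$metadata$true_k7_area_pct)
  }
})

test_that("cell instance detection: sizes, speckle, watershed split", {
  expect_equal(nrow(cell_instances(matrix(FALSE, 20, 20), 1)), 0L)

  one <- disc_mask(60, 60, 30, 30, 12.5)
  ci <- cell_instances(one, 1)
  expect_equal(nrow(ci), 1L)
  expect_lt(abs(ci$equivalent_diameter_um - 25), 1)  # +- 1 px quantization
  expect_lt(abs(ci$x - 30), 0.5)
  expect_lt(abs(ci$y - 30), 0.5)
  expect_equal(ci$equivalent_diameter_um, 2 * sqrt(ci$area_um2 / pi),
               tolerance = 1e-9)

  # barbell of two touching 25 um discs splits into two instances
  barbell <- disc_mask(60, 90, 30, 30, 12.5) | disc_mask(60, 90, 55, 30, 12.5)
  cb <- cell_instances(barbell, 1)
  expect_equal(nrow(cb), 2L)
  expect_lt(abs(sort(cb$x)[1] - 30), 2)
  expect_lt(abs(sort(cb$x)[2] - 55), 2)

  # sub-minimum speckle dropped
  speck <- disc_mask(30, 30, 15, 15, 4)  # 8 um diameter < 10 um bound
  expect_equal(nrow(cell_instances(speck, 1)), 0L)

  # exact count recovery on generator ground truth (cells never touch)
  sp <- generate_specimen(small_gen_config(seed = 9L, severity = 0.6))
  ci <- cell_instances(sp$gt_masks$k7, 2)
  expect_equal(nrow(ci), nrow(sp$gt_instances))
})

test_that("portal distances: exact geometry and missing-portal handling", {
  portal <- matrix(FALSE, 20, 20); portal[1, 1] <- TRUE  # pixel (0,0)
  inst <- cells_at(rbind(c(3, 4), c(0, 0)))
  pd <- portal_distances(inst, portal, pixel_size_um = 1)
  expect_equal(pd$instances$distance_to_portal_um, c(5, 0))  # 3-4-5
  expect_equal(pd$mean_distance_um, 2.5)

  # centroid inside the portal mask -> distance 0
  p2 <- disc_mask(30, 30, 15, 15, 5)
  pd2 <- portal_distances(cells_at(rbind(c(15, 15))), p2, 1)
  expect_equal(pd2$instances$distance_to_portal_um, 0)
  expect_equal(pd2$instances$zone, 1L)

  # empty portal -> NA with warning, not an error
  expect_warning(
    pd3 <- portal_distances(inst, matrix(FALSE, 20, 20), 1),
    "empty portal")
  expect_true(all(is.na(pd3$instances$distance_to_portal_um)))
  expect_true(is.na(pd3$mean_distance_um))

  # no cells -> mean absent without warning
  pd4 <- portal_distances(cells_at(matrix(0, 0, 2)), p2, 1)
  expect_true(is.na(pd4$mean_distance_um))
})

test_that("zone assignment uses strict-left/closed-right thirds", {
  expect_equal(assign_zone(0, 584), 1L)
  expect_equal(assign_zone(148, 447), 1L)        # boundary at 149
  expect_equal(assign_zone(149, 447), 2L)
  expect_equal(assign_zone(400, 584), 3L)        # 2L/3 = 389.33
  expect_equal(assign_zone(c(10, 250, 500), 584), c(1L, 2L, 3L))
  expect_error(assign_zone(-1, 584))
  expect_error(assign_zone(10, 0))
})

test_that("quantities are invariant under integer translation of all masks", {
  sp <- generate_specimen(small_gen_config(seed = 11L, severity = 0.5,
                                           h = 150L, w = 250L, n_portal = 2L,
                                           portal_radius = 35))
  gm <- sp$gt_masks
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nrow(m) + dy, ncol(m) + dx)
    out[(dy + 1):(dy + nrow(m)), (dx + 1):(dx + ncol(m))] <- m
    out
  }
  gm2 <- layer_masks(shift(gm$tissue, 7, 11), shift(gm$portal, 7, 11),
                     shift(gm$parenchyma, 7, 11), shift(gm$k7, 7, 11),
                     gm$pixel_size_um)
  expect_equal(k7_area_fraction(gm2), k7_area_fraction(gm))
  expect_equal(layer_areas(gm2)$portal_fraction_pct,
               layer_areas(gm)$portal_fraction_pct)
  c1 <- cell_instances(gm$k7, 2)
  c2 <- cell_instances(gm2$k7, 2)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(sort(c2$x - 11), sort(c1$x))
  p1 <- portal_distances(c1, gm$portal, 2)
  p2 <- portal_distances(c2, gm2$portal, 2)
  expect_equal(p1$mean_distance_um, p2$mean_distance_um)
})

test_that("per-zone counts partition the instance total", {
  sp <- generate_specimen(small_gen_config(seed = 12L, severity = 0.8))
  ci <- cell_instances(sp$gt_masks$k7, 2)
  pd <- portal_distances(ci, sp$gt_masks$portal, 2)
  expect_equal(sum(table(pd$instances$zone)), nrow(pd$instances))
  expect_true(all(pd$instances$zone %in% 1:3))
})

test_that("quantify_specimen assembles a coherent record", {
  cfg <- small_pipe_config()
  sp <- generate_specimen(small_gen_config(seed = 15L, severity = 0.6))
  q <- quantify_specimen(sp$gt_masks, "gt", cfg)
  expect_identical(q$record$k7_area_pct, sp$metadata$true_k7_area_pct)
  expect_equal(q$record$n_k7_cells, nrow(sp$gt_instances))
  expect_true(q$record$k7_score %in% 0:3)
  expect_equal(q$record$portal_fraction_pct + q$record$parenchyma_fraction_pct,
               100)
})
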