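test_that("ROI polygons validate and rasterize correctly", {
  expect_error(roi_polygon(rbind(c(0, 0), c(10, 0))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(roi_polygon(bowtie), "self-intersecting")

  img <- array(255L, c(20, 30, 3))
  # full-frame rectangle -> all valid
  full <- roi_polygon(rbind(c(0, 0), c(29, 0), c(29, 19), c(0, 19)))
  expect_true(all(apply_roi(img, full)$validity))
  # absent roi -> all valid
  expect_true(all(apply_roi(img, NULL)$validity))
  # left half only
  half <- roi_polygon(rbind(c(0, 0), c(14.5, 0), c(14.5, 19), c(0, 19)))
  v <- apply_roi(img, half)$validity
  expect_true(all(v[, 1:14]))
  expect_false(any(v[, 16:30]))
  # out of bounds rejected
  oob <- roi_polygon(rbind(c(-5, 0), c(10, 0), c(10, 10)))
  expect_error(apply_roi(img, oob), "bounds")
})

test_that("blank image yields empty masks through the whole pipeline", {
  img <- array(255L, c(60, 80, 3))
  cfg <- small_pipe_config()
  expect_false(any(segment_tissue(img, NULL, cfg)))
  expect_warning(masks <- run_pipeline(img, NULL, cfg), "no tissue")
  expect_false(any(masks$tissue) || any(masks$portal) ||
               any(masks$parenchyma) || any(masks$k7))
})

test_that("tissue segmentation is accurate and honours the validity mask", {
  cfg <- small_pipe_config()
  for (seed in c(1L, 12L, 23L)) {
    sp <- generate_specimen(small_gen_config(seed = seed, severity = 0.5))
    tis <- segment_tissue(sp$image, NULL, cfg)
    expect_gte(dice(tis, sp$gt_masks$tissue), 0.98)
  }
  # validity clipping: tissue only detected where valid
  sp <- generate_specimen(small_gen_config(seed = 2L, severity = 0.3))
  v <- matrix(FALSE, nrow(sp$gt_masks$tissue), ncol(sp$gt_masks$tissue))
  v[, 1:200] <- TRUE
  tis <- segment_tissue(sp$image, v, cfg)
  expect_false(any(tis & !v))
})

test_that("ROI selects a single strip from a two-strip slide", {
  # compose a two-strip image by stacking two generated tiles vertically
  spA <- generate_specimen(small_gen_config(seed = 4L, severity = 0.4,
                                            h = 120L, w = 300L, n_portal = 2L,
                                            portal_radius = 35))
  spB <- generate_specimen(small_gen_config(seed = 5L, severity = 0.4,
                                            h = 120L, w = 300L, n_portal = 2L,
                                            portal_radius = 35))
  two <- array(255L, c(240, 300, 3))
  two[1:120, , ] <- spA$image
  two[121:240, , ] <- spB$image
  cfg <- small_pipe_config()
  roi <- roi_polygon(rbind(c(0, 0), c(299, 0), c(299, 119), c(0, 119)))
  tis_roi <- segment_tissue(two, apply_roi(two, roi)$validity, cfg)
  tis_single <- segment_tissue(spA$image, NULL, cfg)
  expect_lt(abs(sum(tis_roi) - sum(tis_single)) / sum(tis_single), 0.01)
  expect_false(any(tis_roi[121:240, ]))
})

test_that("portal/parenchyma split: complement construction and accuracy", {
  cfg <- small_pipe_config()
  # no portal structures -> portal empty, parenchyma = tissue
  sp0 <- generate_specimen(small_gen_config(seed = 3L, severity = 0,
                                            n_portal = 0L))
  tis <- segment_tissue(sp0$image, NULL, cfg)
  pp <- segment_portal_parenchyma(sp0$image, tis, cfg)
  expect_false(any(pp$portal))
  expect_equal(pp$parenchyma, tis)

  for (seed in c(6L, 14L, 27L)) {
    sp <- generate_specimen(small_gen_config(seed = seed, severity = 0.5))
    tis <- segment_tissue(sp$image, NULL, cfg)
    pp <- segment_portal_parenchyma(sp$image, tis, cfg)
    # exact partition of tissue, every run
    expect_false(any(pp$portal & pp$parenchyma))
    expect_equal(pp$portal | pp$parenchyma, tis)
    expect_gte(dice(pp$portal, sp$gt_masks$portal), 0.90)
    expect_gte(dice(pp$parenchyma, sp$gt_masks$parenchyma), 0.97)
  }
})

test_that("K7 layer: clipping excludes ductal DAB, accuracy vs ground truth", {
  cfg <- small_pipe_config()
  # severity 0: ductular rings are DAB-positive but inside the portal mask,
  # so the K7 layer must be empty
  sp0 <- generate_specimen(small_gen_config(seed = 7L, severity = 0))
  m0 <- suppressWarnings(run_pipeline(sp0$image, NULL, cfg))
  expect_false(any(m0$k7))

  # empty parenchyma -> empty K7 mask
  sp <- generate_specimen(small_gen_config(seed = 8L, severity = 0.6))
  expect_false(any(segment_k7_hepatocytes(
    sp$image, matrix(FALSE, 200, 400), cfg)))

  for (seed in c(8L, 19L)) {
    sp <- generate_specimen(small_gen_config(seed = seed, severity = 0.6))
    masks <- run_pipeline(sp$image, NULL, cfg)
    m <- layer_metrics(masks$k7, sp$gt_masks$k7, sp$gt_masks$parenchyma)
    expect_gte(m$precision_pct, 90)
    expect_gte(m$sensitivity_pct, 90)
  }
})

test_that("pipeline output satisfies nesting invariants and is idempotent", {
  cfg <- small_pipe_config()
  sp <- generate_specimen(small_gen_config(seed = 10L, severity = 0.7))
  a <- run_pipeline(sp$image, NULL, cfg)
  b <- run_pipeline(sp$image, NULL, cfg)
  expect_identical(a$tissue, b$tissue)
  expect_identical(a$k7, b$k7)
  expect_false(any(a$portal & a$parenchyma))
  expect_true(all(a$tissue[a$portal | a$parenchyma]))
  expect_true(all(a$parenchyma[a$k7]))
})

test_that("corrupting the upstream mask wipes downstream detections (clipping)", {
  cfg <- small_pipe_config()
  sp <- generate_specimen(small_gen_config(seed = 13L, severity = 0.7))
  tis <- segment_tissue(sp$image, NULL, cfg)
  w <- ncol(tis)
  tis_cut <- tis
  tis_cut[, (w %/% 2 + 1):w] <- FALSE  # erase right half upstream
  pp <- segment_portal_parenchyma(sp$image, tis_cut, cfg)
  k7 <- segment_k7_hepatocytes(sp$image, pp$parenchyma, cfg)
  expect_false(any(k7[, (w %/% 2 + 1):w]))
  # clipping monotonicity: shrinking upstream never enlarges downstream
  pp_full <- segment_portal_parenchyma(sp$image, tis, cfg)
  k7_full <- segment_k7_hepatocytes(sp$image, pp_full$parenchyma, cfg)
  expect_true(all(k7_full[k7]))
  # measured child FN is at least the clipped (unreachable) share
  fn <- layer_metrics(k7, sp$gt_masks$k7, sp$gt_masks$parenchyma,
                      parent_pred = pp$parenchyma)
  expect_gte(fn$fn_pct, fn$clipped_fn_pct)
})

test_that("layer_masks constructor rejects invariant violations", {
  t <- matrix(TRUE, 5, 5); f <- matrix(FALSE, 5, 5)
  expect_error(layer_masks(t, t, t, f, 1), "overlap")
  expect_error(layer_masks(f, t, f, f, 1), "outside the tissue")
  expect_error(layer_masks(t, f, f, t, 1), "outside the parenchyma")
  expect_error(layer_masks(t, f, t, matrix(FALSE, 4, 4), 1), "shape")
  expect_s3_class(layer_masks(t, f, t, t, 1), "layer_masks")
})
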