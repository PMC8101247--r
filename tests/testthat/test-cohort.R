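test_that("ln_transform implements both zero policies", {
  r <- ln_transform(c(1, exp(1), exp(2)))
  expect_equal(r$values, c(0, 1, 2))
  expect_equal(r$n_excluded_zeros, 0L)

  r2 <- ln_transform(c(0, 1), "exclude")
  expect_equal(r2$values, 0)
  expect_equal(r2$n_excluded_zeros, 1L)

  r3 <- ln_transform(c(0, 2, 4), "offset")
  expect_equal(r3$epsilon, 1)
  expect_equal(r3$values, log(c(1, 3, 5)))
  expect_equal(r3$n_excluded_zeros, 0L)

  r4 <- ln_transform(c(0, 0), "exclude")
  expect_equal(r4$status, "all_zero")
  expect_length(r4$values, 0)
  expect_error(ln_transform(c(-1, 2)))
})

test_that("pearson_cor: exact cases and t-based p-values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$coefficient, 1)
  expect_equal(pearson_cor(x, -x)$coefficient, -1)

  r <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$coefficient, oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               tolerance = 1e-12)
  # p-value agrees with cor.test's t machinery
  ct <- stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)

  z <- pearson_cor(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_equal(z$status, "undefined")
  expect_true(is.na(z$coefficient))
  expect_equal(pearson_cor(c(1, 2), c(3, 4))$status, "too_few")
})

test_that("spearman_cor: monotone invariance, reversal, tie handling", {
  x <- c(0.3, 1.1, 2.7, 3.2, 5.9)
  expect_equal(spearman_cor(x, exp(x))$coefficient, 1)
  expect_equal(spearman_cor(x, rev(x))$coefficient, -1)

  tx <- c(1, 2, 2, 3); ty <- c(1, 2, 3, 3)
  expect_equal(spearman_cor(tx, ty)$coefficient, oracle_spearman(tx, ty),
               tolerance = 1e-12)

  # invariance under strictly monotone transforms of either variable
  set.seed(41)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- spearman_cor(a, b)$coefficient
    expect_equal(spearman_cor(exp(a), b)$coefficient, r0, tolerance = 1e-12)
    expect_equal(spearman_cor(a, b^3)$coefficient, r0, tolerance = 1e-12)
  }
})

test_that("both correlation routines match hand-formula oracles to 1e-12", {
  set.seed(53)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n), 2)  # rounding induces occasional ties
    y <- round(rnorm(n), 2)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(pearson_cor(x, y)$coefficient, oracle_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_cor(x, y)$coefficient, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("cohort_run batches specimens into one row each", {
  cfg <- small_gen_config(h = 150L, w = 250L, n_portal = 2L,
                          portal_radius = 35)
  coh <- generate_cohort(3L, cfg, function(n) c(0, 0.5, 0.9), seed = 31L)
  tab <- cohort_run(coh$specimens, small_pipe_config())
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$status == "ok"))
  # severity-0 specimen: no K7 area, score 0
  expect_equal(tab$k7_area_pct[1], 0)
  expect_equal(tab$k7_score[1], 0L)
  expect_true(all(tab$elapsed_s >= 0))

  # a broken specimen fails its row, not the batch
  broken <- c(coh$specimens[1:2], list(list(image = "not an image")))
  tab2 <- cohort_run(broken, small_pipe_config())
  expect_equal(nrow(tab2), 3L)
  expect_match(tab2$status[3], "^failed")
  expect_equal(sum(tab2$status == "ok"), 2L)
})

test_that("cohort_run reads a directory of PPM images", {
  dir <- file.path(tempdir(), "k7q-cohort")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  for (s in 1:2) {
    sp <- generate_specimen(small_gen_config(seed = s, severity = 0.4,
                                             h = 120L, w = 200L,
                                             n_portal = 1L,
                                             portal_radius = 30))
    write_ppm(sp$image, file.path(dir, sprintf("img%d.ppm", s)))
  }
  tab <- cohort_run(dir, small_pipe_config())
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$specimen_id, c("img1", "img2"))
  expect_true(all(tab$status == "ok"))
})

test_that("correlation_report: sign recovery, degenerate columns, self-pair", {
  cfg <- small_gen_config()
  m <- generate_cohort(50L, cfg, seed = 61L, render = "metadata")
  rep <- correlation_report(m$table, list(c("severity", "sim_alp")))
  sp_row <- rep[rep$method == "spearman", ]
  expect_gt(sp_row$coefficient, 0)
  pe_row <- rep[rep$method == "pearson", ]
  expect_equal(pe_row$transform, "ln")
  expect_gt(pe_row$coefficient, 0)

  tab <- data.frame(a = c(1, 2, 3, 4), b = c(1, 1, 1, 1), k = c(2, 4, 1, 3))
  r2 <- correlation_report(tab, list(c("a", "b"), c("k", "k"),
                                     c("a", "missing")))
  expect_equal(r2$status[r2$var_b == "b" & r2$method == "spearman"],
               "undefined")
  self <- r2[r2$var_a == "k" & r2$method == "spearman", ]
  expect_equal(self$coefficient, 1)
  expect_true("missing_column" %in% r2$status)
})

test_that("holdout split reports the validation percentage", {
  ids <- sprintf("S%03d", 1:210)
  hs <- holdout_split(ids, 57, seed = 3L)
  expect_equal(hs$holdout_pct, 27.1)
  expect_length(hs$holdout, 57)
  expect_length(intersect(hs$holdout, hs$rest), 0)
})

test_that("cohort CSV round-trips with the documented dialect", {
  tab <- data.frame(specimen_id = c("a", "b"),
                    k7_area_pct = c(1.23456789, NA),
                    n = c(1L, 2L))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_cohort_csv(tab, path)
  txt <- readLines(path)
  expect_match(txt[1], "specimen_id,k7_area_pct,n")
  expect_match(txt[3], ",,2")  # missing value as empty field
  back <- read_cohort_csv(path)
  expect_equal(back$k7_area_pct[1], signif(1.23456789, 6))
})
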