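# Cohort batching and the statistical analyses run on the per-specimen
# table: Spearman on raw values, Pearson on ln-transformed values, with
# explicit handling of zeros under the log transform.

#' Natural-log transform with explicit zero handling
#'
#' @param values non-negative numeric vector.
#' @param zero_policy `"exclude"` drops zeros (count reported); `"offset"`
#'   uses `ln(v + eps)` with `eps` = half the smallest positive value.
#' @return list: `values` (transformed), `kept` (logical index into the
#'   input), `n_excluded_zeros`, `epsilon` (`NA` under exclude), `status`
#'   (`"ok"` or `"all_zero"`).
#' @export
ln_transform <- function(values, zero_policy = c("exclude", "offset")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(all(values >= 0, na.rm = TRUE))
  if (zero_policy == "exclude") {
    kept <- !is.na(values) & values > 0
    if (!any(kept))
      return(list(values = numeric(0), kept = kept, n_excluded_zeros = sum(values == 0, na.rm = TRUE),
                  epsilon = NA_real_, status = "all_zero"))
    list(values = log(values[kept]), kept = kept,
         n_excluded_zeros = sum(!is.na(values) & values == 0),
         epsilon = NA_real_, status = "ok")
  } else {
    pos <- values[!is.na(values) & values > 0]
    if (length(pos) == 0L)
      return(list(values = rep(NA_real_, length(values)),
                  kept = !is.na(values),
                  n_excluded_zeros = 0L, epsilon = NA_real_,
                  status = "all_zero"))
    eps <- min(pos) / 2
    kept <- !is.na(values)
    list(values = log(values[kept] + eps), kept = kept,
         n_excluded_zeros = 0L, epsilon = eps, status = "ok")
  }
}

cor_result <- function(pair, method, transform, coefficient, p_value,
                       n_used, n_excluded_zeros, status = "ok") {
  structure(list(variable_pair = pair, method = method, transform = transform,
                 coefficient = coefficient, p_value = p_value,
                 n_used = n_used, n_excluded_zeros = n_excluded_zeros,
                 status = status),
            class = "cor_result")
}

#' Pearson product-moment correlation with t-based p-value
#'
#' Computed from the covariance/variance sums; the two-sided p-value uses
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom. Zero variance in
#' either variable yields an explicit `"undefined"` status.
#'
#' @param x,y numeric vectors of equal length (>= 3), pairwise-complete.
#' @param transform label recorded in the result (`"none"` or `"ln"`).
#' @param n_excluded_zeros bookkeeping count carried into the result.
#' @return object of class `cor_result`.
#' @export
pearson_cor <- function(x, y, transform = "none", n_excluded_zeros = 0L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pair <- c(deparse(substitute(x)), deparse(substitute(y)))
  if (n < 3L)
    return(cor_result(pair, "pearson", transform, NA_real_, NA_real_, n,
                      n_excluded_zeros, "too_few"))
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0)
    return(cor_result(pair, "pearson", transform, NA_real_, NA_real_, n,
                      n_excluded_zeros, "undefined"))
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  cor_result(pair, "pearson", transform, r, p, n, n_excluded_zeros)
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' Pearson correlation of the mid-rank transforms, with the same t-based
#' p-value approximation.
#'
#' @inheritParams pearson_cor
#' @return object of class `cor_result`.
#' @export
spearman_cor <- function(x, y, transform = "none", n_excluded_zeros = 0L) {
  ok <- is.finite(x) & is.finite(y)
  res <- pearson_cor(rank(x[ok], ties.method = "average"),
                     rank(y[ok], ties.method = "average"),
                     transform = transform,
                     n_excluded_zeros = n_excluded_zeros)
  res$method <- "spearman"
  res
}

#' Run the full pipeline over a cohort
#'
#' Accepts either a list of synthetic specimens (from [generate_cohort()])
#' or a directory of PPM images (with optional matching `<name>.roi.json`
#' polygon files). Each specimen is segmented, quantified and scored;
#' failures are logged per specimen without aborting the batch.
#'
#' @param input list of `synthetic_specimen` objects or a directory path.
#' @param config a [pipeline_config()].
#' @param covariates optional data frame joined on `specimen_id`.
#' @param out_csv optional path; when given the table is written as CSV
#'   (UTF-8, comma-separated, missing values empty).
#' @return data frame: one row per specimen (quantification columns plus
#'   `status` and `elapsed_s`), joined with covariates when supplied.
#' @export
cohort_run <- function(input, config = pipeline_config(), covariates = NULL,
                       out_csv = NULL) {
  if (is.character(input)) {
    paths <- list.files(input, pattern = "\\.ppm$", full.names = TRUE)
    if (length(paths) == 0L) stop("no .ppm images found in ", input)
    items <- lapply(paths, function(p) list(path = p))
    ids <- sub("\\.ppm$", "", basename(paths))
  } else {
    items <- input
    ids <- vapply(seq_along(items), function(i) sprintf("S%04d", i), "")
  }
  rows <- vector("list", length(items))
  for (i in seq_along(items)) {
    t0 <- proc.time()[["elapsed"]]
    row <- tryCatch({
      it <- items[[i]]
      if (!is.null(it$path)) {
        img <- read_ppm(it$path)
        roi_path <- sub("\\.ppm$", ".roi.json", it$path)
        roi <- if (file.exists(roi_path)) read_roi_json(roi_path) else NULL
      } else {
        img <- it$image
        roi <- NULL
      }
      masks <- suppressWarnings(run_pipeline(img, roi, config))
      q <- quantify_specimen(masks, ids[i], config)
      q$record$status <- "ok"
      q$record
    }, error = function(e) {
      data.frame(specimen_id = ids[i], tissue_area_mm2 = NA_real_,
                 portal_area_mm2 = NA_real_, parenchyma_area_mm2 = NA_real_,
                 portal_fraction_pct = NA_real_,
                 parenchyma_fraction_pct = NA_real_, k7_area_pct = NA_real_,
                 n_k7_cells = NA_integer_, mean_distance_um = NA_real_,
                 k7_score = NA_integer_, n_periportal = NA_integer_,
                 n_positive_regions = NA_integer_,
                 positive_fraction = NA_real_,
                 subthreshold_positive = NA,
                 status = paste0("failed: ", conditionMessage(e)))
    })
    row$elapsed_s <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  if (!is.null(covariates))
    tab <- merge(tab, covariates, by = "specimen_id", all.x = TRUE,
                 sort = FALSE)
  if (!is.null(out_csv)) write_cohort_csv(tab, out_csv)
  tab
}

#' Correlation report over cohort-table column pairs
#'
#' For each `(a, b)` pair: Spearman on the raw values and Pearson on the
#' ln-transformed values (zeros handled by `zero_policy`, exclusions
#' reported). Missing columns produce an explicit per-pair error row.
#'
#' @param table cohort data frame.
#' @param pairs list of 2-element character vectors (column names).
#' @param zero_policy passed to [ln_transform()].
#' @return data frame: `var_a`, `var_b`, `method`, `transform`,
#'   `coefficient`, `p_value`, `n_used`, `n_excluded_zeros`, `status`.
#' @export
correlation_report <- function(table, pairs, zero_policy = "exclude") {
  rows <- list()
  add <- function(a, b, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      var_a = a, var_b = b, method = res$method, transform = res$transform,
      coefficient = res$coefficient, p_value = res$p_value,
      n_used = res$n_used, n_excluded_zeros = res$n_excluded_zeros,
      status = res$status)
  }
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    if (!a %in% names(table) || !b %in% names(table)) {
      err <- cor_result(c(a, b), "spearman", "none", NA_real_, NA_real_,
                        0L, 0L, "missing_column")
      add(a, b, err)
      next
    }
    x <- table[[a]]; y <- table[[b]]
    ok <- is.finite(x) & is.finite(y)
    add(a, b, spearman_cor(x[ok], y[ok]))
    # Pearson on ln scale: drop (or offset) zeros jointly
    lx <- ln_transform(x[ok], zero_policy)
    ly <- ln_transform(y[ok], zero_policy)
    keep <- lx$kept & ly$kept
    nz <- sum(ok) - sum(keep)
    if (lx$status == "all_zero" || ly$status == "all_zero") {
      add(a, b, cor_result(c(a, b), "pearson", "ln", NA_real_, NA_real_,
                           0L, nz, "all_zero"))
    } else {
      xr <- x[ok][keep]; yr <- y[ok][keep]
      epsx <- if (is.na(lx$epsilon)) 0 else lx$epsilon
      epsy <- if (is.na(ly$epsilon)) 0 else ly$epsilon
      add(a, b, pearson_cor(log(xr + epsx), log(yr + epsy),
                            transform = "ln", n_excluded_zeros = nz))
    }
  }
  do.call(rbind, rows)
}

#' Hold out a validation subset
#'
#' Splits specimen ids into validation/training sets and reports the
#' holdout percentage rounded to one decimal (e.g. 57 of 210 gives 27.1).
#'
#' @param ids character vector of specimen ids.
#' @param n_holdout number held out.
#' @param seed RNG seed for the draw.
#' @return list: `holdout`, `rest`, `holdout_pct`.
#' @export
holdout_split <- function(ids, n_holdout, seed = 1L) {
  stopifnot(n_holdout >= 0, n_holdout <= length(ids))
  withr_seed(seed)
  pick <- sample(seq_along(ids), n_holdout)
  list(holdout = ids[pick], rest = ids[-pick],
       holdout_pct = round(100 * n_holdout / length(ids), 1))
}

#' Write / read the cohort CSV
#'
#' Comma-separated, UTF-8, header row, missing values as empty fields,
#' floats at six significant digits.
#'
#' @param table data frame.
#' @param path file path.
#' @return (write) the path, invisibly; (read) a data frame.
#' @export
write_cohort_csv <- function(table, path) {
  tf <- table
  num <- vapply(tf, is.double, logical(1))
  tf[num] <- lapply(tf[num], function(v) signif(v, 6))
  chr <- vapply(tf, is.character, logical(1))
  tf[chr] <- lapply(tf[chr], function(v) gsub(",", ";", v, fixed = TRUE))
  write.csv(tf, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
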