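# Plain-format image I/O. The environment ships no PNG/TIFF codec for R, so
# images travel as portable pixmaps: P6/P3 PPM for RGB, P5/P2 PGM for label
# masks. ROI polygons and specimen metadata are JSON; tables are CSV.

#' Write / read an RGB image as PPM
#'
#' @param image integer array `h x w x 3`, values 0-255.
#' @param path file path (`.ppm`).
#' @param ascii write text P3 instead of binary P6 (default binary).
#' @return (write) the path invisibly; (read) an `h x w x 3` integer array.
#' @export
write_ppm <- function(image, path, ascii = FALSE) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  # interleave channels row-major: R,G,B per pixel, rows top to bottom
  flat <- as.integer(aperm(image, c(3L, 2L, 1L)))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(w, h), "255"), con, sep = "\n")
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  hdr <- read_pnm_header(path)
  n <- 3L * hdr$w * hdr$h
  vals <- if (hdr$magic == "P6") {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, hdr$offset)
    as.integer(readBin(con, "raw", n))
  } else if (hdr$magic == "P3") {
    as.integer(scan(path, what = integer(), skip = hdr$skip_lines,
                    quiet = TRUE))
  } else stop("not a PPM file: ", path)
  if (length(vals) != n) stop("truncated PPM: ", path)
  img <- array(0L, c(hdr$h, hdr$w, 3L))
  m <- matrix(vals, nrow = 3L)          # channels x pixels (row-major)
  for (c in 1:3)
    img[, , c] <- matrix(m[c, ], hdr$h, hdr$w, byrow = TRUE)
  img
}

#' Write / read a label mask as PGM
#'
#' Hierarchical label encoding (documented with the generator): 0 =
#' background, 1 = tissue not otherwise classified, 2 = parenchyma,
#' 3 = portal area, 4 = K7-positive hepatocyte.
#'
#' @param labels integer matrix of labels 0-255.
#' @param path file path (`.pgm`).
#' @param ascii write text P2 instead of binary P5.
#' @return (write) the path invisibly; (read) an integer matrix.
#' @export
write_pgm <- function(labels, path, ascii = FALSE) {
  stopifnot(is.matrix(labels))
  h <- nrow(labels); w <- ncol(labels)
  flat <- as.integer(t(labels))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), "255"), con, sep = "\n")
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  hdr <- read_pnm_header(path)
  n <- hdr$w * hdr$h
  vals <- if (hdr$magic == "P5") {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, hdr$offset)
    as.integer(readBin(con, "raw", n))
  } else if (hdr$magic == "P2") {
    as.integer(scan(path, what = integer(), skip = hdr$skip_lines,
                    quiet = TRUE))
  } else stop("not a PGM file: ", path)
  if (length(vals) != n) stop("truncated PGM: ", path)
  matrix(vals, hdr$h, hdr$w, byrow = TRUE)
}

# minimal PNM header reader (no comment lines in files we write; comment
# lines starting with '#' are tolerated)
read_pnm_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  lines <- 0L
  offset <- 0L
  while (length(toks) < 4L) {
    line <- readLines(con, 1L)
    if (length(line) == 0L) stop("malformed PNM header: ", path)
    lines <- lines + 1L
    offset <- offset + nchar(line, type = "bytes") + 1L
    line <- sub("#.*$", "", line)
    toks <- c(toks, strsplit(trimws(line), "\\s+")[[1]])
    toks <- toks[toks != ""]
  }
  list(magic = toks[1], w = as.integer(toks[2]), h = as.integer(toks[3]),
       maxval = as.integer(toks[4]), offset = offset, skip_lines = lines)
}

#' Encode / decode layer masks as a hierarchical label image
#'
#' @param masks a [layer_masks()].
#' @return integer matrix (see [write_pgm()] for the encoding).
#' @export
masks_to_labels <- function(masks) {
  stopifnot(inherits(masks, "layer_masks"))
  lab <- matrix(0L, nrow(masks$tissue), ncol(masks$tissue))
  lab[masks$tissue] <- 1L
  lab[masks$parenchyma] <- 2L
  lab[masks$portal] <- 3L
  lab[masks$k7] <- 4L
  lab
}

#' @rdname masks_to_labels
#' @param labels integer label matrix.
#' @param pixel_size_um pixel edge length (um).
#' @export
labels_to_masks <- function(labels, pixel_size_um) {
  tissue <- labels >= 1L
  parenchyma <- labels == 2L | labels == 4L
  portal <- labels == 3L
  k7 <- labels == 4L
  layer_masks(tissue, portal, parenchyma, k7, pixel_size_um)
}

#' Read / write an ROI polygon JSON file
#'
#' Format: `{"vertices": [[x, y], ...]}` in 0-based pixel coordinates.
#'
#' @param path file path.
#' @return a [roi_polygon()].
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices)) stop("ROI JSON lacks a 'vertices' field")
  roi_polygon(matrix(as.numeric(obj$vertices), ncol = 2L))
}

#' @rdname read_roi_json
#' @param roi a [roi_polygon()].
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "roi_polygon"))
  jsonlite::write_json(list(vertices = roi$vertices), path, digits = NA)
  invisible(path)
}

#' Write a synthetic specimen to a directory
#'
#' Emits `<id>.ppm` (image), `<id>.masks.pgm` (label image), `<id>.cells.csv`
#' (ground-truth instances) and `<id>.json` (metadata).
#'
#' @param specimen a `synthetic_specimen`.
#' @param dir output directory (created if needed).
#' @param id file stem.
#' @return the directory, invisibly.
#' @export
write_specimen <- function(specimen, dir, id = "specimen") {
  stopifnot(inherits(specimen, "synthetic_specimen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ppm(specimen$image, file.path(dir, paste0(id, ".ppm")))
  write_pgm(masks_to_labels(specimen$gt_masks),
            file.path(dir, paste0(id, ".masks.pgm")))
  write.csv(specimen$gt_instances,
            file.path(dir, paste0(id, ".cells.csv")), row.names = FALSE)
  jsonlite::write_json(specimen$metadata,
                       file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
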