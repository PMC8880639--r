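# Reading and writing external artifacts: scans, ground-truth overlays,
# ROI masks and feature tables.

#' Construct a grayscale scan object
#'
#' A scan is stored as a numeric matrix of intensities (row 1 = top of the
#' page), 0 = black ink, 255 = white paper, together with its resolution.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param dpi Scan resolution in dots per inch.
#' @return An object of class `last_image`.
#' @export
gray_image <- function(pixels, dpi = 600) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop_validation("a scan must be a non-empty matrix of intensities")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("scan intensities must lie in [0, 255]")
  }
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0) {
    stop_validation("dpi must be a single positive number")
  }
  structure(list(pixels = pixels, dpi = dpi), class = "last_image")
}

#' @exportS3Method base::print
print.last_image <- function(x, ...) {
  cat(sprintf("<last_image> %d x %d px, %g dpi, intensity range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$dpi,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.last_image <- function(x) dim(x$pixels)

# Rec. 601 luminance weights used when collapsing RGB scans to grayscale.
.lum <- c(0.299, 0.587, 0.114)

#' Load a scanned LAST form
#'
#' Reads an 8- or 16-bit grayscale (or RGB, converted by luminance) PNG or
#' TIFF scan and attaches the stated resolution. 16-bit intensities are
#' rescaled to `[0, 255]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param dpi Scan resolution in dots per inch (default 600, the acquisition
#'   convention for LAST forms).
#' @return A [gray_image()] object.
#' @export
load_scan <- function(path, dpi = 600) {
  if (!file.exists(path)) stop_io("scan file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop_io("unsupported scan format '%s' (use PNG or TIFF)", ext)
    ),
    error = function(e) {
      if (inherits(e, "lastkit_io_error")) stop(e)
      stop_io("could not decode %s: %s", path, conditionMessage(e))
    }
  )
  px <- collapse_channels(arr)
  if (length(px) == 0L) stop_validation("zero-area image: %s", path)
  gray_image(round(px * 255), dpi = dpi)
}

# readPNG/readTIFF return values in [0, 1]; collapse RGB(A) by luminance.
collapse_channels <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  nc <- dim(arr)[3]
  if (nc >= 3L) {
    arr[, , 1] * .lum[1] + arr[, , 2] * .lum[2] + arr[, , 3] * .lum[3]
  } else {
    arr[, , 1]
  }
}

#' Read the per-scan sidecar metadata
#'
#' Each scan may be accompanied by a JSON sidecar holding the resolution and
#' the number of leading characters drawn by the examiner,
#' e.g. `{"dpi": 600, "examiner_n": 5}`.
#'
#' @param path Path to the sidecar JSON file.
#' @return A list with elements `dpi` and `examiner_n`.
#' @export
load_sidecar <- function(path) {
  if (!file.exists(path)) stop_io("sidecar file does not exist: %s", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(dpi = meta$dpi %||% 600, examiner_n = meta$examiner_n %||% 5L)
}

#' Load an expert label overlay
#'
#' Ground-truth overlays are RGB copies of the scan in which each character's
#' stroke has been recolored: red for rectangles, blue for triangles. A pixel
#' counts as red when `R - max(G, B) > margin` (8-bit scale) and symmetrically
#' for blue, which tolerates the anti-aliased strokes of raster editors.
#' Same-color 8-connected components become per-character masks, ordered
#' left-to-right by centroid; the first `examiner_n` characters are flagged as
#' drawn by the examiner.
#'
#' @param path Path to an RGB PNG/TIFF overlay, or an `H x W x 3` array in
#'   `[0, 1]`.
#' @param base The matching [gray_image()]; dimensions must agree.
#' @param examiner_n Number of leading examiner characters (default 5).
#' @param margin Color-dominance margin on the 8-bit scale (default 40).
#' @return A list of class `last_overlay` with elements `rois` (list of
#'   [character_roi()]) and `labels` (character vector of `"R"`/`"T"`).
#' @export
load_label_overlay <- function(path, base, examiner_n = 5L, margin = 40) {
  arr <- if (is.character(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop_io("unsupported overlay format '%s'", ext)
    )
  } else {
    path
  }
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L) {
    stop_validation("overlay must be an RGB image")
  }
  if (!all(dim(arr)[1:2] == dim(base$pixels))) {
    stop_validation("overlay dimensions (%d x %d) do not match the scan (%d x %d)",
                    dim(arr)[1], dim(arr)[2], nrow(base$pixels), ncol(base$pixels))
  }
  r <- arr[, , 1] * 255; g <- arr[, , 2] * 255; b <- arr[, , 3] * 255
  red <- (r - pmax(g, b)) > margin
  blue <- (b - pmax(r, g)) > margin
  if (!any(red) && !any(blue)) stop_validation("overlay contains no colored strokes")
  rois <- c(masks_from_binary(red, "R"), masks_from_binary(blue, "T"))
  cx <- vapply(rois, function(x) x$cx, numeric(1))
  rois <- rois[order(cx)]
  labels <- vapply(rois, function(x) x$label, character(1))
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    out[[i]] <- character_roi(rois[[i]]$mask, rois[[i]]$bbox,
                              index = i - 1L, examiner = i <= examiner_n)
  }
  structure(list(rois = out, labels = labels), class = "last_overlay")
}

# Split a binary mask into 8-connected components, as bbox-cropped ROIs.
masks_from_binary <- function(mask, label) {
  lab <- label_components(mask)
  n <- max(lab)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    sub <- lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k
    # bbox is 0-based half-open: [x0, x1) x [y0, y1)
    bbox <- c(cc[1] - 1L, cc[2], rr[1] - 1L, rr[2])
    out[[k]] <- list(mask = sub, bbox = bbox, label = label,
                     cx = mean(idx[, 2]))
  }
  out
}

#' Write the per-subject outputs of a processed scan
#'
#' Writes the aggregated feature vector as a one-row CSV, the full
#' per-character detail as JSON and the character masks as an indexed PNG
#' (pixel value = character index + 1). Reading the CSV back reproduces the
#' feature values (bit-exactly for integers, to 1e-9 for reals).
#'
#' @param record A series record from [series_features()].
#' @param rois List of [character_roi()] objects for the same scan.
#' @param out_dir Output directory (created if needed).
#' @param image_dim Dimensions (rows, cols) of the source scan, used to place
#'   ROI masks on the page; taken from the ROIs' extent when omitted.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(record, rois, out_dir, image_dim = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io("cannot create output directory %s", out_dir)
  wide <- as_tibble(record)
  csv_path <- file.path(out_dir, "features.csv")
  json_path <- file.path(out_dir, "features.json")
  png_path <- file.path(out_dir, "rois.png")
  if (nrow(record$characters) == 0L) {
    warn("empty record: writing header-only CSV")
  }
  write.csv(wide, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(subject = record$subject, group = record$group,
         sequence = record$sequence, nw = record$nw,
         characters = record$characters),
    json_path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  if (length(rois) > 0L) {
    if (is.null(image_dim)) {
      image_dim <- c(max(vapply(rois, function(r) r$bbox[4], numeric(1))),
                     max(vapply(rois, function(r) r$bbox[2], numeric(1))))
    }
    lab <- matrix(0L, image_dim[1], image_dim[2])
    for (r in rois) {
      rows <- (r$bbox[3] + 1L):r$bbox[4]
      cols <- (r$bbox[1] + 1L):r$bbox[2]
      block <- lab[rows, cols, drop = FALSE]
      block[r$mask] <- r$index + 1L
      lab[rows, cols] <- block
    }
    png::writePNG(lab / 255, png_path)
  }
  invisible(c(csv = csv_path, json = json_path, png = png_path))
}

#' Read a feature table written by [write_outputs()] or [cohort_features()]
#'
#' @param path CSV path; one row per subject, `subject` and `group` columns
#'   plus named numeric features.
#' @return A tibble with `group` as a factor when present.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_io("feature table does not exist: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_tibble(df)
}
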