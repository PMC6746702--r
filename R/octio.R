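# On-disk formats: 8-bit grayscale PNG/TIFF scans with JSON sidecar scales,
# per-column boundary CSVs, label-PNG area masks, JSON dataset manifests.

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z]+$", "", path), ".json")

#' Read a B-scan image
#'
#' Reads an 8-bit grayscale PNG or TIFF B-scan. RGB input is converted to
#' grayscale (channel mean) with a warning. Pixel scales are taken from a
#' JSON sidecar (`<name>.json` next to the image, keys `scale_vertical`,
#' `scale_horizontal`) when present, otherwise the Spectralis defaults
#' (3.9, 5.7) um/px are used.
#'
#' @param path image file path (`.png`, `.tif`, `.tiff`).
#' @return A [bscan()].
#' @export
read_bscan <- function(path) {
  if (!file.exists(path)) stop_octseg("cannot read '", path, "': no such file")
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_octseg("the 'tiff' package is required to read TIFF scans")
      tiff::readTIFF(path)
    },
    bmp = stop_octseg("BMP input is not supported; convert to PNG or TIFF"),
    stop_octseg("unsupported image format '.", ext, "'"))
  if (length(dim(arr)) == 3L) {
    warning("RGB image converted to grayscale (channel mean)", call. = FALSE)
    arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  }
  px <- round(arr * 255)
  sv <- 3.9; sh <- 5.7; id <- sub("\\.[A-Za-z]+$", "", basename(path))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    sv <- meta$scale_vertical %||% sv
    sh <- meta$scale_horizontal %||% sh
    id <- meta$identifier %||% id
  }
  bscan(px, scale_vertical = sv, scale_horizontal = sh, identifier = id)
}

#' Write a B-scan image
#'
#' Writes the scan as an 8-bit grayscale PNG plus a JSON sidecar carrying the
#' pixel scales and identifier.
#'
#' @param scan a [bscan()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(scan, path) {
  stopifnot(inherits(scan, "bscan"))
  png::writePNG(round(scan$pixels) / 255, path)
  jsonlite::write_json(
    list(scale_vertical = scan$scale_vertical,
         scale_horizontal = scan$scale_horizontal,
         identifier = scan$identifier),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-column boundary annotations
#'
#' CSV dialect: header `column,ilm,rpe,csi`, 0-based column indices, row
#' positions with 3-decimal precision, empty cells marking missing
#' annotations. Columns absent from the file are missing. Ordering
#' violations are rejected with the offending column reported.
#'
#' @param path CSV file path.
#' @param width scan width in pixels (number of columns of the result).
#' @param validate reject ordering violations (default). Predicted
#'   boundaries are delineated independently per boundary and may cross, so
#'   evaluation re-reads them with `validate = FALSE`.
#' @return A [boundary_set()].
#' @export
read_boundaries <- function(path, width, validate = TRUE) {
  df <- read.csv(path)
  need <- c("column", "ilm", "rpe", "csi")
  if (!all(need %in% names(df)))
    stop_octseg("boundary CSV must have columns ", paste(need, collapse = ","))
  if (any(df$column < 0 | df$column >= width))
    stop_octseg("boundary CSV contains column indices outside [0, width-1]")
  ilm <- rpe <- csi <- rep(NA_real_, width)
  i <- df$column + 1L
  ilm[i] <- df$ilm; rpe[i] <- df$rpe; csi[i] <- df$csi
  if (validate) {
    ok <- !is.na(ilm) & !is.na(rpe) & !is.na(csi)
    bad <- which(ok & !(ilm < rpe & rpe < csi))
    if (length(bad))
      stop_octseg(sprintf(
        "boundary ordering ilm < rpe < csi violated at column %d",
        bad[1L] - 1L))
    boundary_set(ilm, rpe, csi)
  } else {
    structure(list(ilm = ilm, rpe = rpe, csi = csi), width = width,
              class = "boundary_set")
  }
}

#' Write per-column boundary annotations
#'
#' @param boundaries a [boundary_set()].
#' @param path output CSV path.
#' @param keep_missing if `TRUE` (default) unannotated columns are written
#'   with empty cells; otherwise they are omitted from the file.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path, keep_missing = TRUE) {
  stopifnot(inherits(boundaries, "boundary_set"))
  w <- attr(boundaries, "width")
  df <- data.frame(column = seq_len(w) - 1L,
                   ilm = round(boundaries$ilm, 3),
                   rpe = round(boundaries$rpe, 3),
                   csi = round(boundaries$csi, 3))
  if (!keep_missing)
    df <- df[!(is.na(df$ilm) & is.na(df$rpe) & is.na(df$csi)), ]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write area masks
#'
#' Area masks are H x W integer matrices with region codes 0 = vitreous,
#' 1 = retina, 2 = choroid, 3 = sclera, stored as label PNGs (gray value =
#' code / 255). Values outside 0..3 are rejected.
#'
#' @param mask integer H x W matrix over 0..3.
#' @param path PNG file path.
#' @return `read_area_mask` returns the label matrix; `write_area_mask`
#'   returns `path` invisibly.
#' @export
write_area_mask <- function(mask, path) {
  if (anyNA(mask) || any(mask < 0 | mask > 3))
    stop_octseg("area mask labels must lie in 0..3")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_area_mask
#' @export
read_area_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  m <- round(arr * 255)
  if (any(m < 0 | m > 3))
    stop_octseg("file is not a 0..3 label mask (found code ", max(m), ")")
  storage.mode(m) <- "integer"
  m
}

#' Write a dataset to disk with a JSON manifest
#'
#' Writes every scan (PNG + sidecar), its boundary annotations (CSV) and its
#' area mask (label PNG) under `dir`, plus a `manifest.json` listing
#' participant, split tag and file paths for each entry.
#'
#' @param dataset an `oct_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return The manifest file path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oct_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in names(dataset)) {
    for (e in dataset[[split]]) {
      scan_file <- file.path(dir, paste0(e$id, ".png"))
      ann_file <- file.path(dir, paste0(e$id, "_boundaries.csv"))
      mask_file <- file.path(dir, paste0(e$id, "_mask.png"))
      write_bscan(e$scan, scan_file)
      write_boundaries(e$boundaries, ann_file)
      write_area_mask(
        boundaries_to_area_mask(e$boundaries, nrow(e$scan$pixels),
                                ncol(e$scan$pixels)),
        mask_file)
      rows[[length(rows) + 1L]] <- list(
        scan_path = basename(scan_file), annotation_path = basename(ann_file),
        mask_path = basename(mask_file), participant = e$participant,
        split_tag = split, id = e$id)
    }
  }
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(rows, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Load a dataset manifest written by [write_dataset()]
#'
#' Validates that every referenced file exists and that split tags are among
#' train/validation/evaluation, then loads scans and annotations.
#'
#' @param manifest path to `manifest.json`.
#' @return An `oct_dataset`.
#' @export
read_dataset <- function(manifest) {
  rows <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  ds <- list()
  for (r in rows) {
    if (!r$split_tag %in% c("train", "validation", "evaluation"))
      stop_octseg("invalid split tag '", r$split_tag, "' in manifest")
    sp <- file.path(dir, r$scan_path); ap <- file.path(dir, r$annotation_path)
    for (f in c(sp, ap))
      if (!file.exists(f))
        stop_octseg("manifest references missing file '", f, "'")
    scan <- read_bscan(sp)
    entry <- list(scan = scan,
                  boundaries = read_boundaries(ap, ncol(scan$pixels)),
                  participant = r$participant, id = r$id)
    ds[[r$split_tag]] <- c(ds[[r$split_tag]], list(entry))
  }
  structure(ds, class = "oct_dataset")
}
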