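#' Construct a B-scan object
#'
#' A B-scan is a single grayscale OCT cross-section, stored as an H x W
#' intensity matrix in `[0, 255]` together with the physical pixel scales of
#' the instrument. Default scales correspond to enhanced-depth-imaging
#' Spectralis scans (3.9 um/pixel vertically, 5.7 um/pixel horizontally).
#'
#' @param pixels numeric H x W matrix of intensities in `[0, 255]`;
#'   row 1 is the top of the scan.
#' @param scale_vertical,scale_horizontal physical pixel size in micrometres.
#' @param identifier character scan id.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, scale_vertical = 3.9, scale_horizontal = 5.7,
                  identifier = "scan") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_octseg("'pixels' must be a non-empty numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_octseg("B-scan intensities must lie in [0, 255]")
  if (scale_vertical <= 0 || scale_horizontal <= 0)
    stop_octseg("pixel scales must be positive")
  structure(
    list(pixels = pixels, scale_vertical = scale_vertical,
         scale_horizontal = scale_horizontal,
         identifier = as.character(identifier)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s'> %d x %d px (%.1f x %.1f um/px)\n",
              x$identifier, nrow(x$pixels), ncol(x$pixels),
              x$scale_vertical, x$scale_horizontal))
  invisible(x)
}

#' @export
plot.bscan <- function(x, ...) {
  h <- nrow(x$pixels)
  image(t(x$pixels)[, h:1], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = h / ncol(x$pixels), main = x$identifier, ...)
  invisible(x)
}

#' Construct a boundary set
#'
#' Per-column row positions of the three chorio-retinal boundaries: the inner
#' limiting membrane (ILM), the outer retinal pigment epithelium boundary
#' (RPE) and the choroid-scleral interface (CSI). Rows are 0-based (row 0 is
#' the top of the scan) and real-valued; `NA` marks a column without an
#' annotation. Wherever all three are present the ordering
#' `ilm < rpe < csi` must hold.
#'
#' @param ilm,rpe,csi numeric vectors of length W (row positions or `NA`).
#' @param height scan height in pixels, used to validate the row range.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(ilm, rpe, csi, height = NULL) {
  w <- length(ilm)
  if (length(rpe) != w || length(csi) != w)
    stop_octseg("ilm, rpe and csi must have the same length")
  b <- list(ilm = as.numeric(ilm), rpe = as.numeric(rpe),
            csi = as.numeric(csi))
  ok <- !is.na(b$ilm) & !is.na(b$rpe) & !is.na(b$csi)
  bad <- which(ok & !(b$ilm < b$rpe & b$rpe < b$csi))
  if (length(bad))
    stop_octseg(sprintf(
      "boundary ordering ilm < rpe < csi violated at column %d (0-based %d)",
      bad[1L], bad[1L] - 1L))
  if (!is.null(height)) {
    vals <- unlist(b, use.names = FALSE)
    vals <- vals[!is.na(vals)]
    if (length(vals) && (min(vals) < 0 || max(vals) > height - 1))
      stop_octseg("boundary rows must lie within [0, height - 1]")
  }
  structure(b, width = w, class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  w <- attr(x, "width")
  miss <- sum(is.na(x$ilm) | is.na(x$rpe) | is.na(x$csi))
  cat(sprintf("<boundary_set> %d columns (%d unannotated)\n", w, miss))
  invisible(x)
}

# columns (1-based) where all three boundaries are annotated
annotated_columns <- function(b) {
  which(!is.na(b$ilm) & !is.na(b$rpe) & !is.na(b$csi))
}
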