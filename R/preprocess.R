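#' Crop region used for patch sampling and evaluation
#'
#' Columns within `left` of the left edge and `right` of the right edge are
#' excluded from patch construction and error calculation (in the study
#' format these regions contain the optic nerve head and edge shadows).
#'
#' @param left,right margins in columns; defaults 100 and 250.
#' @return A list of class `crop_region`.
#' @export
crop_region <- function(left = 100L, right = 250L) {
  if (left < 0 || right < 0) stop_octseg("crop margins must be >= 0")
  structure(list(left = as.integer(left), right = as.integer(right)),
            class = "crop_region")
}

# 1-based eligible column indices of a width-W scan under a crop region
crop_columns <- function(crop, width) {
  if (crop$left + crop$right >= width)
    stop_octseg("crop margins leave no columns (left + right >= width)")
  seq.int(crop$left + 1L, width - crop$right)
}

#' Attenuation-compensation contrast enhancement
#'
#' Compensates depth-dependent signal attenuation by dividing the local
#' backscatter by the remaining signal below it: per pixel
#' `E(i, j) = I(i, j)^n / (2 * sum_{k >= i} I(k, j)^n + eps)`, where the sum
#' runs from row `i` to the bottom of the column. The result is rescaled to
#' `[0, 255]` by its per-image maximum. This markedly improves the contrast
#' of the choroid-scleral interface and suppresses vessel shadows.
#'
#' @param scan a [bscan()].
#' @param exponent signal exponent `n >= 1` (default 2).
#' @param floor stabiliser `eps > 0` preventing division by zero in empty
#'   columns.
#' @return A contrast-enhanced [bscan()].
#' @export
contrast_enhance <- function(scan, exponent = 2, floor = 1e-6) {
  stopifnot(inherits(scan, "bscan"))
  if (exponent < 1) stop_octseg("'exponent' must be >= 1")
  if (floor <= 0) stop_octseg("'floor' must be > 0")
  p <- scan$pixels^exponent
  # per-column cumulative sum from row i to the bottom
  tailsum <- apply(p, 2, function(col) rev(cumsum(rev(col))))
  e <- p / (2 * tailsum + floor)
  mx <- max(e)
  if (mx > 0) e <- e * (255 / mx)
  out <- scan
  out$pixels <- e
  out
}

# raw (unscaled) enhancement values, used by closed-form tests
attenuation_compensate_raw <- function(pixels, exponent = 2, floor = 1e-6) {
  p <- pixels^exponent
  tailsum <- apply(p, 2, function(col) rev(cumsum(rev(col))))
  p / (2 * tailsum + floor)
}

#' Convert boundaries to a per-pixel area mask
#'
#' Pixel `(r, c)` (0-based rows) is labelled vitreous (0) above the ILM,
#' retina (1) from the ILM to the RPE, choroid (2) from the RPE to the CSI
#' and sclera (3) below; each boundary row belongs to the region below it.
#' Real-valued boundary rows are rounded half-up. Columns missing any
#' boundary are labelled entirely vitreous.
#'
#' @param boundaries a [boundary_set()].
#' @param height,width mask size in pixels.
#' @return Integer H x W matrix over 0..3.
#' @export
boundaries_to_area_mask <- function(boundaries, height, width) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (attr(boundaries, "width") != width)
    stop_octseg("boundary width does not match 'width'")
  ilm <- round_half_up(boundaries$ilm)
  rpe <- round_half_up(boundaries$rpe)
  csi <- round_half_up(boundaries$csi)
  miss <- is.na(ilm) | is.na(rpe) | is.na(csi)
  ilm[miss] <- rpe[miss] <- csi[miss] <- height  # below image: all vitreous
  rows <- matrix(seq_len(height) - 1, height, width)
  m <- (rows >= matrix(ilm, height, width, byrow = TRUE)) +
    (rows >= matrix(rpe, height, width, byrow = TRUE)) +
    (rows >= matrix(csi, height, width, byrow = TRUE))
  storage.mode(m) <- "integer"
  m
}

#' Recover integer boundaries from an area mask
#'
#' Inverse of [boundaries_to_area_mask()] for fully-labelled columns: each
#' boundary is the first row of its lower region. Columns without all four
#' transitions (e.g. all-vitreous columns) are returned as missing.
#'
#' @param mask integer H x W matrix over 0..3.
#' @return A [boundary_set()].
#' @export
area_mask_to_boundaries <- function(mask) {
  first_row_of <- function(col, lab) {
    i <- which(col >= lab)
    if (length(i)) i[1L] - 1 else NA_real_
  }
  ilm <- apply(mask, 2, first_row_of, 1L)
  rpe <- apply(mask, 2, first_row_of, 2L)
  csi <- apply(mask, 2, first_row_of, 3L)
  bad <- is.na(ilm) | is.na(rpe) | is.na(csi)
  ilm[bad] <- rpe[bad] <- csi[bad] <- NA_real_
  boundary_set(ilm, rpe, csi, height = nrow(mask))
}

#' Zero image columns that lack a boundary annotation
#'
#' Every column missing at least one of the three annotations has all its
#' pixel intensities set to 0 (matching the all-vitreous labelling of such
#' columns in the training masks); other columns are untouched.
#'
#' @param scan a [bscan()].
#' @param boundaries a [boundary_set()] of matching width.
#' @return A [bscan()].
#' @export
zero_missing_columns <- function(scan, boundaries) {
  stopifnot(inherits(scan, "bscan"), inherits(boundaries, "boundary_set"))
  miss <- is.na(boundaries$ilm) | is.na(boundaries$rpe) |
    is.na(boundaries$csi)
  if (any(miss)) scan$pixels[, miss] <- 0
  scan
}

#' Random horizontal flip augmentation
#'
#' With the given probability, reverses both the image and its area mask
#' along columns (consistently). Draws from the current RNG state, so the
#' augmentation stream is reproducible under `set.seed()`.
#'
#' @param pixels H x W image matrix.
#' @param mask H x W area mask (or any aligned matrix).
#' @param probability flip probability (default 0.5).
#' @return `list(pixels, mask, flipped)`.
#' @export
random_horizontal_flip <- function(pixels, mask, probability = 0.5) {
  if (!all(dim(pixels) == dim(mask)))
    stop_octseg("image and mask shapes differ")
  flipped <- runif(1) < probability
  if (flipped) {
    pixels <- pixels[, ncol(pixels):1, drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  list(pixels = pixels, mask = mask, flipped = flipped)
}
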