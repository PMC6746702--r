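#' Patch geometry for patch-based classification
#'
#' Patches are small `height x width` windows of a B-scan, each assigned one
#' of four classes: ILM, RPE or CSI when anchored on (the rounded row of)
#' that boundary, or background (BG) otherwise. The anchor pixel sits one
#' pixel above and to the left of the patch centre, i.e. at 0-based patch
#' position `(height/2 - 1, width/2 - 1)`. Sizes 32x32, 64x32, 64x64 and
#' 128x32 (height x width) are the standard choices; any even size works.
#'
#' @param height,width patch size in pixels (both even).
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(height = 32L, width = 32L) {
  if (height %% 2L || width %% 2L)
    stop_octseg("patch height and width must be even")
  structure(list(height = as.integer(height), width = as.integer(width),
                 classes = c("ILM", "RPE", "CSI", "BG")),
            class = "patch_spec")
}

#' Extract one patch around an anchor pixel
#'
#' The anchor `(row, column)` (0-based) is placed at patch position
#' `(height/2 - 1, width/2 - 1)`; pixels outside the image are mirror-padded
#' (symmetric reflection), which avoids the artificial dark borders that
#' would otherwise bias boundary probabilities at the image edges.
#'
#' @param scan a [bscan()].
#' @param anchor length-2 integer `(row, column)`, 0-based.
#' @param spec a [patch_spec()].
#' @return A `height x width` intensity matrix.
#' @export
extract_patch <- function(scan, anchor, spec) {
  stopifnot(inherits(scan, "bscan"), inherits(spec, "patch_spec"))
  h <- nrow(scan$pixels); w <- ncol(scan$pixels)
  r0 <- anchor[1] - (spec$height %/% 2L - 1L)
  c0 <- anchor[2] - (spec$width %/% 2L - 1L)
  ri <- reflect_index(seq.int(r0, length.out = spec$height), h) + 1L
  ci <- reflect_index(seq.int(c0, length.out = spec$width), w) + 1L
  scan$pixels[ri, ci, drop = FALSE]
}

#' Sample class-balanced training patches from one scan
#'
#' From every eligible column (inside the crop region and with all three
#' boundaries annotated), takes one patch anchored on each rounded boundary
#' row plus one background patch anchored on a uniformly drawn row at least
#' 2 px away from every boundary row, giving exactly equal class counts.
#' Draws from the current RNG state.
#'
#' @param scan a [bscan()].
#' @param boundaries the matching [boundary_set()].
#' @param spec a [patch_spec()].
#' @param crop a [crop_region()].
#' @return A list with `x` (array `height x width x 1 x N`, intensities
#'   scaled to `[0, 1]`), `label` (factor over ILM/RPE/CSI/BG) and `source`
#'   (data frame of scan id and 0-based anchor coordinates).
#' @export
sample_training_patches <- function(scan, boundaries, spec,
                                    crop = crop_region()) {
  stopifnot(inherits(scan, "bscan"), inherits(boundaries, "boundary_set"),
            inherits(spec, "patch_spec"))
  h <- nrow(scan$pixels); w <- ncol(scan$pixels)
  cols <- intersect(crop_columns(crop, w), annotated_columns(boundaries))
  n <- length(cols)
  if (!n) stop_octseg("no eligible columns to sample patches from")
  anchors_r <- integer(0); anchors_c <- integer(0); labels <- character(0)
  brows <- rbind(round_half_up(boundaries$ilm[cols]),
                 round_half_up(boundaries$rpe[cols]),
                 round_half_up(boundaries$csi[cols]))
  for (k in 1:3) {
    anchors_r <- c(anchors_r, as.integer(brows[k, ]))
    anchors_c <- c(anchors_c, cols - 1L)
    labels <- c(labels, rep(spec$classes[k], n))
  }
  # background anchors: uniform over rows more than 1 px from any boundary
  bg <- integer(n)
  for (j in seq_len(n)) {
    excl <- unique(as.vector(outer(brows[, j], -1:1, `+`)))
    ok <- setdiff(0:(h - 1L), excl)
    bg[j] <- ok[sample.int(length(ok), 1L)]
  }
  anchors_r <- c(anchors_r, bg)
  anchors_c <- c(anchors_c, cols - 1L)
  labels <- c(labels, rep("BG", n))
  x <- array(0, c(spec$height, spec$width, 1L, length(labels)))
  for (i in seq_along(labels))
    x[, , 1L, i] <- extract_patch(scan, c(anchors_r[i], anchors_c[i]),
                                  spec) / 255
  list(x = x,
       label = factor(labels, levels = spec$classes),
       source = data.frame(id = scan$identifier, row = anchors_r,
                           column = anchors_c))
}

#' Dense anchor grid covering the crop region
#'
#' Anchors for dense per-pixel classification: every pixel of every eligible
#' column, in row-major order starting at `(0, left_margin)` (0-based).
#'
#' @param scan a [bscan()].
#' @param crop a [crop_region()].
#' @return Integer matrix with columns `row`, `column` (0-based).
#' @export
dense_anchor_grid <- function(scan, crop = crop_region()) {
  stopifnot(inherits(scan, "bscan"))
  h <- nrow(scan$pixels); w <- ncol(scan$pixels)
  cols <- crop_columns(crop, w) - 1L
  cbind(row = rep(0:(h - 1L), each = length(cols)),
        column = rep(cols, h))
}
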