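# Boundary delineation: probability maps -> shortest-path graph search.

#' Edge weight between two probability-map vertices
#'
#' `w = 2 - (P_s + P_d) + w_min`, where `P_s` and `P_d` are the source and
#' destination vertex probabilities in `[0, 1]` and `w_min` (default 1e-5)
#' is a small positive stabiliser keeping every weight strictly positive.
#' High-probability corridors therefore have near-zero traversal cost.
#'
#' @param p_source,p_dest vertex probabilities in `[0, 1]` (vectorised).
#' @param w_min small positive stabiliser.
#' @return Numeric edge weight(s).
#' @export
edge_weight <- function(p_source, p_dest, w_min = 1e-5) {
  if (any(p_source < 0 | p_source > 1 | p_dest < 0 | p_dest > 1))
    stop_octseg("vertex probabilities must lie in [0, 1]")
  2 - (p_source + p_dest) + w_min
}

#' Delineate a boundary through a probability map
#'
#' Builds a directed graph with one vertex per pixel, edges from each pixel
#' to its right, upper-right and lower-right neighbours weighted by
#' [edge_weight()], and one auxiliary column of probability-1 vertices on
#' each side (connected top-to-bottom and fanned into/out of the adjacent
#' real column) so no manual start or end point is needed. Dijkstra's
#' algorithm then finds the minimum-cost path from the top-left auxiliary
#' vertex to the bottom-right one; equal-cost alternatives resolve to the
#' smaller row. The returned path has exactly one row per real column and
#' steps at most one row between adjacent columns.
#'
#' @param map H x W numeric matrix of probabilities in `[0, 1]`.
#' @param w_min stabiliser passed to the edge weights.
#' @return Integer vector of length W: the 0-based path row in each column.
#' @export
shortest_path_boundary <- function(map, w_min = 1e-5) {
  if (!is.matrix(map) || ncol(map) < 2L)
    stop_octseg("'map' must be a matrix with at least 2 columns")
  if (anyNA(map) || any(!is.finite(map)))
    stop_octseg("'map' must be finite")
  if (min(map) < 0 || max(map) > 1)
    stop_octseg("'map' values must lie in [0, 1]")
  .dijkstra_boundary(map, w_min)
}

#' Boundary probability maps from semantic area probabilities
#'
#' Boundary k separates area class k (above) from class k + 1 (below), so
#' its probability map is the positive part of the vertical Sobel response
#' (top-to-bottom increase) of the lower region's probability plane:
#' ILM from the retina plane, RPE from the choroid plane, CSI from the
#' sclera plane. With `align = "lower"` (default) the response is shifted
#' half a pixel onto the lower pixel of each transition (averaging adjacent
#' response rows), matching the convention that a boundary row belongs to
#' the region below it; `align = "centered"` keeps the raw 3x3 Sobel
#' response. Each map is rescaled to `[0, 1]` by its maximum (all-zero maps
#' stay zero).
#'
#' @param probs `(H, W, 4)` area probability array.
#' @param align `"lower"` or `"centered"`.
#' @return Named list of H x W probability maps (`ilm`, `rpe`, `csi`).
#' @export
semantic_boundary_maps <- function(probs, align = c("lower", "centered")) {
  align <- match.arg(align)
  if (length(dim(probs)) == 4L) probs <- array(probs, dim(probs)[1:3])
  if (dim(probs)[3] != 4L) stop_octseg("'probs' must have 4 class planes")
  maps <- lapply(1:3, function(k) {
    m <- sobel_vertical(probs[, , k + 1L])
    m[m < 0] <- 0
    if (align == "lower") {
      h <- nrow(m)
      m <- (m[c(1L, seq_len(h - 1L)), , drop = FALSE] + m) / 2
    }
    mx <- max(m)
    if (mx > 0) m <- m / mx
    m
  })
  names(maps) <- BOUNDARIES
  maps
}

# 3x3 vertical Sobel response (positive for top-to-bottom increase),
# replicate padding at the borders
sobel_vertical <- function(x) {
  h <- nrow(x); w <- ncol(x)
  up <- x[c(1L, seq_len(h - 1L)), , drop = FALSE]
  dn <- x[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  d <- dn - up
  d[, c(1L, seq_len(w - 1L)), drop = FALSE] + 2 * d +
    d[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
}

#' Boundary probability maps from a patch classifier
#'
#' Classifies a patch centred on every pixel of the crop region and uses
#' the per-boundary class probabilities as map values; columns outside the
#' crop are filled with 0.
#'
#' @param net a `patch_net` (or an `oct_patch_model`, whose network is
#'   used).
#' @param scan a [bscan()] (already contrast-enhanced if the model was
#'   trained that way).
#' @param crop a [crop_region()].
#' @param batch_size patches classified per forward pass.
#' @return Named list of H x W probability maps (`ilm`, `rpe`, `csi`).
#' @export
patch_probability_maps <- function(net, scan, crop = crop_region(),
                                   batch_size = 1024L) {
  if (inherits(net, "oct_patch_model")) net <- net$net
  stopifnot(inherits(net, "patch_net"), inherits(scan, "bscan"))
  h <- nrow(scan$pixels); w <- ncol(scan$pixels)
  anchors <- dense_anchor_grid(scan, crop)
  spec <- net$spec
  maps <- lapply(1:3, function(k) matrix(0, h, w))
  n <- nrow(anchors)
  probs <- matrix(0, 4, n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- array(0, c(spec$height, spec$width, 1L, length(idx)))
    for (j in seq_along(idx))
      xb[, , 1L, j] <- extract_patch(scan, anchors[idx[j], ], spec) / 255
    probs[, idx] <- patch_net_predict(net, xb)
  }
  for (k in 1:3)
    maps[[k]][cbind(anchors[, 1] + 1L, anchors[, 2] + 1L)] <- probs[k, ]
  names(maps) <- BOUNDARIES
  maps
}

# run the graph search on each of the three maps and assemble a predicted
# boundary set (a warning is issued if the independent searches violate the
# anatomical ordering anywhere)
maps_to_boundaries <- function(maps, w_min = 1e-5) {
  rows <- lapply(maps, function(m) as.numeric(shortest_path_boundary(m, w_min)))
  b <- structure(list(ilm = rows$ilm, rpe = rows$rpe, csi = rows$csi),
                 width = length(rows$ilm), class = "boundary_set")
  bad <- which(!(b$ilm < b$rpe & b$rpe < b$csi))
  if (length(bad))
    warning(sprintf(
      "predicted boundaries violate ilm < rpe < csi ordering in %d column(s)",
      length(bad)), call. = FALSE)
  b
}

#' Segment a B-scan end to end
#'
#' Runs the full chain for a fitted model: probability-map construction
#' (dense patch classification, or semantic segmentation followed by the
#' Sobel conversion) on the full-width scan, then one shortest-path graph
#' search per boundary on the full-size maps.
#'
#' @param model an `oct_patch_model` or `oct_semantic_model`.
#' @param scan a [bscan()] (raw; contrast enhancement is applied
#'   automatically if the model was trained with it).
#' @param ... passed to the model's `predict` method.
#' @return A [boundary_set()] with a predicted row for every column.
#' @export
segment_scan <- function(model, scan, ...) {
  stopifnot(inherits(model, "oct_model"))
  predict(model, scan, type = "boundaries", ...)
}
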