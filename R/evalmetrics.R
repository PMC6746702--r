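# Evaluation: post-segmentation Dice per region, signed and absolute
# boundary position errors, per-scan and aggregate statistics.

#' Post-segmentation Dice overlap percentage for one region
#'
#' Builds region masks from the predicted and true boundary sets (via
#' [boundaries_to_area_mask()]) restricted to the crop columns and returns
#' `100 * 2|X n Y| / (|X| + |Y|)`. Two empty regions count as 100; disjoint
#' regions give 0. Computed from boundaries only, so a perfect boundary
#' prediction scores 100 regardless of raw network misclassifications.
#'
#' @param pred,truth [boundary_set()] objects over the same width.
#' @param region one of `"vitreous"`, `"retina"`, `"choroid"`, `"sclera"`
#'   (or its 0-based integer code).
#' @param height scan height in pixels.
#' @param crop a [crop_region()].
#' @return Dice percentage in `[0, 100]`.
#' @export
dice_percent <- function(pred, truth, region, height, crop = crop_region()) {
  if (is.character(region)) region <- match(region, REGIONS) - 1L
  if (is.na(region) || region < 0L || region > 3L)
    stop_octseg("unknown region")
  w <- attr(truth, "width")
  cols <- crop_columns(crop, w)
  mp <- boundaries_to_area_mask(pred, height, w)[, cols, drop = FALSE]
  mt <- boundaries_to_area_mask(truth, height, w)[, cols, drop = FALSE]
  x <- mp == region; y <- mt == region
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) return(100)
  200 * sum(x & y) / (nx + ny)
}

#' Signed and absolute boundary position errors for one scan
#'
#' Per boundary, over the crop columns: mean error
#' `ME = mean(pred - truth)` (positive = prediction deeper than truth) and
#' mean absolute error `MAE = mean(|pred - truth|)`, in pixels. Errors are
#' computed against the un-rounded truth values. Crop columns where the
#' truth is unannotated are skipped; a missing prediction is an error.
#'
#' @param pred,truth [boundary_set()] objects over the same width.
#' @param crop a [crop_region()].
#' @return Data frame with columns `boundary`, `me`, `mae`.
#' @export
boundary_errors <- function(pred, truth, crop = crop_region()) {
  w <- attr(truth, "width")
  cols <- crop_columns(crop, w)
  out <- data.frame(boundary = BOUNDARIES, me = NA_real_, mae = NA_real_)
  for (k in 1:3) {
    b <- BOUNDARIES[k]
    tv <- truth[[b]][cols]
    pv <- pred[[b]][cols]
    keep <- !is.na(tv)
    if (any(is.na(pv[keep])))
      stop_octseg("prediction missing at annotated crop columns (", b, ")")
    err <- pv[keep] - tv[keep]
    out$me[k] <- mean(err)
    out$mae[k] <- mean(abs(err))
  }
  out
}

#' Aggregate per-scan evaluation results
#'
#' Given one result row per scan (Dice percentages per region and ME/MAE
#' per boundary), returns the mean and the per-B-scan standard deviation
#' (sample, n - 1) of every quantity across scans. With a single scan the
#' standard deviation is reported as 0 (with a message).
#'
#' @param per_scan data frame with one row per scan; columns
#'   `dice_<region>`, `me_<boundary>`, `mae_<boundary>` (as produced by
#'   [evaluate_model()]).
#' @return A list of class `eval_report` with `per_scan` and `aggregate`.
#' @export
aggregate_eval <- function(per_scan) {
  if (!nrow(per_scan)) stop_octseg("no scans to aggregate")
  num <- per_scan[vapply(per_scan, is.numeric, TRUE)]
  if (nrow(per_scan) == 1L) {
    message("single scan: per-B-scan standard deviation reported as 0")
    sds <- vapply(num, function(x) 0, 0)
  } else {
    sds <- vapply(num, sd, 0)
  }
  agg <- data.frame(quantity = names(num),
                    mean = vapply(num, mean, 0),
                    sd = sds, row.names = NULL)
  structure(list(per_scan = per_scan, aggregate = agg),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d scan(s)\n", nrow(x$per_scan)))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a fitted model on a set of scans
#'
#' Segments every entry, scores it against its ground truth (Dice for the
#' four regions, ME/MAE for the three boundaries, all within the crop) and
#' aggregates across scans.
#'
#' @param model an `oct_model`.
#' @param entries list of `list(scan, boundaries)` entries (e.g. the
#'   `evaluation` element of an `oct_dataset`).
#' @param crop a [crop_region()].
#' @param ... passed to [segment_scan()].
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, entries, crop = crop_region(), ...) {
  rows <- lapply(entries, function(e) {
    pred <- segment_scan(model, e$scan, ...)
    score_prediction(pred, e$boundaries, nrow(e$scan$pixels), crop,
                     id = e$id %||% e$scan$identifier)
  })
  aggregate_eval(do.call(rbind, rows))
}

# one per-scan result row from a predicted and true boundary set
score_prediction <- function(pred, truth, height, crop = crop_region(),
                             id = "scan") {
  be <- boundary_errors(pred, truth, crop)
  row <- data.frame(id = id)
  for (r in REGIONS)
    row[[paste0("dice_", r)]] <- dice_percent(pred, truth, r, height, crop)
  for (k in 1:3) {
    row[[paste0("me_", BOUNDARIES[k])]] <- be$me[k]
    row[[paste0("mae_", BOUNDARIES[k])]] <- be$mae[k]
  }
  row
}

#' Convert a pixel count to millimetres
#'
#' @param n_pixels number of pixels (>= 0).
#' @param scale_um_per_pixel physical pixel size in micrometres.
#' @return Length in millimetres (`n * scale / 1000`).
#' @export
pixels_to_mm <- function(n_pixels, scale_um_per_pixel) {
  if (any(n_pixels < 0) || any(scale_um_per_pixel <= 0))
    stop_octseg("'n_pixels' must be >= 0 and the scale > 0")
  n_pixels * scale_um_per_pixel / 1000
}
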