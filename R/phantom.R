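#' Parameters of the synthetic chorio-retinal phantom
#'
#' The phantom emulates the structure of an enhanced-depth-imaging OCT B-scan
#' of the posterior eye: three smooth, ordered boundaries (ILM, RPE, CSI)
#' separating four intensity regions (vitreous, retina, choroid, sclera),
#' multiplicative speckle, exponential depth attenuation, vertical vessel
#' shadows below the ILM, and occasional unannotated columns near the image
#' edges. Defaults mirror a 1536 x 496 px Spectralis EDI scan: mean boundary
#' depths place a ~310 um retina and ~350 um choroid at 3.9 um/px; speckle
#' with 30% contrast; attenuation losing ~63% of signal over the scan depth.
#'
#' @param width,height image size in pixels.
#' @param mean_depths length-3 numeric, mean rows of (ILM, RPE, CSI), strictly
#'   increasing, inside `(0, height)`.
#' @param curvature_amplitude peak boundary deviation from its mean depth, px.
#' @param curvature_smoothness shortest sinusoid wavelength used for the
#'   boundary curves, in columns (larger = smoother).
#' @param region_intensities length-4 mean gray levels for
#'   (vitreous, retina, choroid, sclera) before attenuation.
#' @param speckle_level standard deviation of the multiplicative (mean-1)
#'   gamma speckle; 0 disables speckle.
#' @param attenuation_rate per-row exponential intensity decay; 0 disables.
#' @param shadow_count number of vertical vessel-shadow bands.
#' @param shadow_width width of each shadow band, columns.
#' @param shadow_attenuation multiplicative factor in `[0, 1]` applied below
#'   the ILM inside shadow bands (1 = no shadow).
#' @param missing_margin number of columns at each edge whose annotations may
#'   be dropped (each such column is dropped with probability 1/2).
#' @param seed integer seed controlling all phantom randomness.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(width = 1536L, height = 496L,
                           mean_depths = c(120, 200, 290),
                           curvature_amplitude = 15,
                           curvature_smoothness = 200,
                           region_intensities = c(15, 130, 90, 150),
                           speckle_level = 0.3,
                           attenuation_rate = 0.002,
                           shadow_count = 3L, shadow_width = 15L,
                           shadow_attenuation = 0.5,
                           missing_margin = 20L, seed = 1L) {
  if (length(mean_depths) != 3L || any(diff(mean_depths) <= 0))
    stop_octseg("'mean_depths' must be 3 strictly increasing values")
  if (min(mean_depths) <= 0 || max(mean_depths) >= height)
    stop_octseg("'mean_depths' must lie inside (0, height)")
  if (length(region_intensities) != 4L ||
      any(region_intensities < 0 | region_intensities > 255))
    stop_octseg("'region_intensities' must be 4 values in [0, 255]")
  if (speckle_level < 0 || attenuation_rate < 0)
    stop_octseg("'speckle_level' and 'attenuation_rate' must be >= 0")
  if (shadow_attenuation < 0 || shadow_attenuation > 1)
    stop_octseg("'shadow_attenuation' must lie in [0, 1]")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         mean_depths = as.numeric(mean_depths),
         curvature_amplitude = curvature_amplitude,
         curvature_smoothness = curvature_smoothness,
         region_intensities = as.numeric(region_intensities),
         speckle_level = speckle_level,
         attenuation_rate = attenuation_rate,
         shadow_count = as.integer(shadow_count),
         shadow_width = as.integer(shadow_width),
         shadow_attenuation = shadow_attenuation,
         missing_margin = as.integer(missing_margin),
         seed = as.integer(seed)),
    class = "phantom_params")
}

#' Phantom parameters rescaled to a smaller raster
#'
#' Rescales the default study-format phantom geometry (depths, curvature,
#' smoothness, shadow width, margins, attenuation) to a different image size,
#' keeping the relative anatomy and the total depth attenuation unchanged.
#'
#' @param width,height target image size in pixels.
#' @param ... overrides passed on to [phantom_params()].
#' @return A `phantom_params` object.
#' @export
phantom_params_scaled <- function(width, height, ...) {
  base <- phantom_params()
  fy <- height / base$height
  fx <- width / base$width
  args <- list(
    width = width, height = height,
    mean_depths = base$mean_depths * fy,
    curvature_amplitude = base$curvature_amplitude * fy,
    curvature_smoothness = max(8, base$curvature_smoothness * fx),
    attenuation_rate = base$attenuation_rate / fy,
    shadow_width = max(2L, as.integer(round(base$shadow_width * fx))),
    missing_margin = max(2L, as.integer(round(base$missing_margin * fx))))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_params, args)
}

#' Generate smooth ground-truth boundaries for a phantom scan
#'
#' Each boundary is its mean depth plus a sum of three random-phase sinusoids
#' with wavelengths at and above `curvature_smoothness`, rescaled so the peak
#' deviation is at most `curvature_amplitude`. Ordering is enforced by
#' clamping each lower boundary to at least 2 px below the one above, and all
#' curves are kept inside the image. Columns within `missing_margin` of
#' either edge lose their annotation with probability 1/2. Deterministic
#' given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @return A [boundary_set()] of width `params$width`.
#' @export
generate_boundaries <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  w <- params$width; h <- params$height
  with_seed(params$seed, {
    x <- seq_len(w) - 1
    curve1 <- function(mean_depth) {
      dev <- numeric(w)
      for (j in 1:3) {
        lambda <- params$curvature_smoothness * runif(1, 1, 4)
        dev <- dev + runif(1, 0.3, 1) * sin(2 * pi * x / lambda +
                                            runif(1, 0, 2 * pi))
      }
      peak <- max(abs(dev))
      if (peak > 0)
        dev <- dev * (params$curvature_amplitude * runif(1, 0.6, 1) / peak)
      mean_depth + dev
    }
    ilm <- curve1(params$mean_depths[1])
    rpe <- curve1(params$mean_depths[2])
    csi <- curve1(params$mean_depths[3])
    # ordering and range enforcement
    ilm <- pmin(pmax(ilm, 1), h - 6)
    rpe <- pmin(pmax(rpe, ilm + 2), h - 4)
    csi <- pmin(pmax(csi, rpe + 2), h - 2)
    # drop annotations near the edges
    m <- params$missing_margin
    if (m > 0) {
      edge <- unique(c(seq_len(min(m, w)), seq.int(max(1L, w - m + 1L), w)))
      drop <- edge[runif(length(edge)) < 0.5]
      ilm[drop] <- rpe[drop] <- csi[drop] <- NA_real_
    }
    boundary_set(ilm, rpe, csi, height = h)
  })
}

# Fill unannotated columns by extending the nearest annotated value; used for
# rendering (the tissue exists even where the annotation is missing).
fill_boundary_na <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (!length(idx)) stop_octseg("boundary has no annotated columns")
  filled <- v
  nas <- which(is.na(v))
  # findInterval gives the annotated column at or before each NA; for leading
  # NAs take the first annotated column
  before <- findInterval(nas, idx)
  nearest <- ifelse(before == 0L, idx[1L], idx[before])
  filled[nas] <- v[nearest]
  filled
}

#' Render a phantom B-scan from ground-truth boundaries
#'
#' Pixels take the mean intensity of their region (determined by the
#' half-up-rounded boundary rows, with unannotated columns filled from the
#' nearest annotated column), multiplied by `exp(-attenuation_rate * row)`,
#' by mean-1 gamma speckle with standard deviation `speckle_level`, and by
#' `shadow_attenuation` below the ILM inside `shadow_count` randomly placed
#' vertical bands of `shadow_width` columns. Intensities are clipped to
#' `[0, 255]`. Deterministic given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @param boundaries the matching [boundary_set()].
#' @param identifier scan id for the returned [bscan()].
#' @return A [bscan()].
#' @export
render_bscan <- function(params, boundaries, identifier = "phantom") {
  stopifnot(inherits(params, "phantom_params"),
            inherits(boundaries, "boundary_set"))
  w <- params$width; h <- params$height
  if (attr(boundaries, "width") != w)
    stop_octseg("boundary width does not match params$width")
  ilm <- round_half_up(fill_boundary_na(boundaries$ilm))
  rpe <- round_half_up(fill_boundary_na(boundaries$rpe))
  csi <- round_half_up(fill_boundary_na(boundaries$csi))
  rows <- matrix(seq_len(h) - 1, h, w)                     # 0-based row index
  region <- 1L + (rows >= matrix(ilm, h, w, byrow = TRUE)) +
    (rows >= matrix(rpe, h, w, byrow = TRUE)) +
    (rows >= matrix(csi, h, w, byrow = TRUE))
  img <- matrix(params$region_intensities[region], h, w)
  if (params$attenuation_rate > 0)
    img <- img * exp(-params$attenuation_rate * (seq_len(h) - 1))
  with_seed(params$seed + 1L, {
    if (params$speckle_level > 0) {
      shape <- 1 / params$speckle_level^2
      img <- img * matrix(rgamma(h * w, shape = shape, scale = 1 / shape),
                          h, w)
    }
    if (params$shadow_count > 0 && params$shadow_attenuation < 1) {
      starts <- sample.int(max(1L, w - params$shadow_width + 1L),
                           params$shadow_count, replace = TRUE)
      below <- rows >= matrix(ilm, h, w, byrow = TRUE)
      for (s in starts) {
        cols <- s:min(w, s + params$shadow_width - 1L)
        band <- below[, cols, drop = FALSE]
        img[, cols][band] <- img[, cols][band] * params$shadow_attenuation
      }
    }
  })
  img <- pmin(pmax(img, 0), 255)
  bscan(img, identifier = identifier)
}

#' Generate a participant-structured synthetic dataset
#'
#' Generates `scans_per_participant` phantom B-scans for each of
#' `n_participants` participants and splits the participants (never
#' individual scans) into training and validation partitions, so no
#' participant contributes to both. With `split_fraction = NULL` a single
#' evaluation partition is produced. Deterministic given `params$seed`.
#'
#' @param n_participants number of participants (>= 2 when splitting).
#' @param scans_per_participant scans generated per participant.
#' @param split_fraction fraction of participants assigned to training
#'   (`floor(n * fraction)`, clamped so both partitions are non-empty), or
#'   `NULL` for a single evaluation partition.
#' @param params a [phantom_params()] object; per-scan seeds are derived from
#'   `params$seed`.
#' @return A list of class `oct_dataset` with elements `train`,
#'   `validation` and/or `evaluation`; each is a list of entries
#'   `list(scan, boundaries, participant, id)`.
#' @export
generate_dataset <- function(n_participants, scans_per_participant,
                             split_fraction = 0.8,
                             params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is.null(split_fraction)) {
    if (n_participants < 2L)
      stop_octseg("need at least 2 participants to split by participant")
    if (split_fraction <= 0 || split_fraction >= 1)
      stop_octseg("'split_fraction' must lie in (0, 1)")
  }
  make_entry <- function(pid, sid, seed) {
    p <- params
    p$seed <- as.integer(seed %% .Machine$integer.max)
    b <- generate_boundaries(p)
    id <- sprintf("p%03d_s%02d", pid, sid)
    list(scan = render_bscan(p, b, identifier = id), boundaries = b,
         participant = pid, id = id)
  }
  entries <- vector("list", n_participants * scans_per_participant)
  k <- 0L
  for (pid in seq_len(n_participants))
    for (sid in seq_len(scans_per_participant)) {
      k <- k + 1L
      entries[[k]] <- make_entry(pid, sid,
                                 params$seed + 1000L * pid + 2L * sid)
    }
  pid_of <- vapply(entries, `[[`, 0, "participant")
  if (is.null(split_fraction)) {
    ds <- list(evaluation = entries)
  } else {
    n_train <- max(1L, min(n_participants - 1L,
                           floor(n_participants * split_fraction)))
    train_pids <- with_seed(params$seed + 7L,
                            sample.int(n_participants, n_train))
    ds <- list(train = entries[pid_of %in% train_pids],
               validation = entries[!(pid_of %in% train_pids)])
  }
  structure(ds, params = params, class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  cat("<oct_dataset>\n")
  for (nm in names(x))
    cat(sprintf("  %-11s %4d scans, %d participants\n", nm, length(x[[nm]]),
                length(unique(vapply(x[[nm]], `[[`, 0, "participant")))))
  invisible(x)
}
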