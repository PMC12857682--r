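#' Granularity (granulometry) parameters
#'
#' Defaults follow the screening configuration: a background structuring
#' element of radius 60 px, a granular-spectrum length of 5, and the second
#' spectrum element as the clustering score. Subsampling fractions default
#' to 1 (off) and are exposed so other conventions (e.g. 0.25) can be
#' reproduced.
#'
#' @param background_radius disc radius for background subtraction, pixels.
#' @param spectrum_length number of erosion scales L.
#' @param score_index 1-based spectrum element reported as the clustering
#'   score.
#' @param subsample_fraction linear downscale applied to the raster before
#'   analysis, in (0, 1].
#' @param background_sample_fraction additional downscale factor applied to
#'   the background radius, in (0, 1].
#' @return an object of class `granularity_params`.
#' @export
granularity_params <- function(background_radius = 60L,
                               spectrum_length = 5L,
                               score_index = 2L,
                               subsample_fraction = 1,
                               background_sample_fraction = 1) {
  p <- list(background_radius = as.integer(background_radius),
            spectrum_length = as.integer(spectrum_length),
            score_index = as.integer(score_index),
            subsample_fraction = subsample_fraction,
            background_sample_fraction = background_sample_fraction)
  stopifnot(p$background_radius >= 1, p$spectrum_length >= 1,
            p$score_index >= 1, p$score_index <= p$spectrum_length,
            p$subsample_fraction > 0, p$subsample_fraction <= 1,
            p$background_sample_fraction > 0, p$background_sample_fraction <= 1)
  structure(p, class = "granularity_params")
}

#' Background subtraction by morphological opening
#'
#' Estimates the local background as the grayscale opening of the raster
#' with a disc of the given radius and returns the non-negative residue
#' `max(raster - opening, 0)`. The opening is computed over the supplied
#' rectangular raster (the mask's bounding region); the mask determines
#' where downstream statistics are evaluated. Structures much smaller than
#' the disc survive; the additive offset of the field cancels.
#'
#' @param raster numeric matrix.
#' @param mask logical matrix of the same shape; must be nonempty.
#' @param radius disc radius in pixels.
#' @return numeric matrix of residues.
#' @export
subtract_background <- function(raster, mask, radius) {
  stopifnot(all(dim(raster) == dim(mask)), radius >= 1)
  if (!any(mask)) stop("empty mask: no region to subtract background over")
  bg <- gray_opening(raster, disc_brush(radius))
  pmax(raster - bg, 0)
}

#' Per-region granularity spectrum
#'
#' Computes the morphological size spectrum of bright structures inside a
#' mask: after optional downscaling and background subtraction, the raster
#' is repeatedly eroded with a radius-1 disc and reconstructed under the
#' background-subtracted raster by geodesic dilation; the percent of the
#' starting in-mask mean signal lost at each scale forms the spectrum.
#' Pixels outside the mask are set to zero for the erosion/reconstruction
#' iteration, and means are taken over the mask.
#'
#' @param raster numeric matrix (marker channel).
#' @param mask logical matrix; the region scored (typically one nucleus).
#' @param params a [granularity_params()].
#' @return an object of class `granularity_spectrum`: numeric vector
#'   `g_1..g_L` (percent of initial mean signal removed per scale) with
#'   attributes `start_mean` and `zero_signal`.
#' @export
granularity_spectrum <- function(raster, mask, params = granularity_params()) {
  stopifnot(inherits(params, "granularity_params"),
            all(dim(raster) == dim(mask)))
  if (!any(mask)) stop("empty mask: nothing to score")
  mask <- mask != 0

  # crop to the mask bounding box
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  img <- raster[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  if (params$subsample_fraction < 1) {
    nh <- max(1L, round(nrow(img) * params$subsample_fraction))
    nw <- max(1L, round(ncol(img) * params$subsample_fraction))
    img <- as.matrix(EBImage::resize(img, nh, nw))          # bilinear
    msk <- as.matrix(EBImage::resize(msk * 1, nh, nw, filter = "none")) > 0.5
    if (!any(msk)) msk <- matrix(TRUE, nh, nw)
  }
  radius <- max(1L, as.integer(round(params$background_radius *
                                       params$subsample_fraction *
                                       params$background_sample_fraction)))
  img <- subtract_background(img, msk, radius)
  img[!msk] <- 0

  L <- params$spectrum_length
  g <- numeric(L)
  start_mean <- mean(img[msk])
  if (start_mean <= 0) {
    out <- structure(g, start_mean = start_mean, zero_signal = TRUE,
                     class = "granularity_spectrum")
    return(out)
  }
  kern <- cross_brush()
  ero <- img
  prev_mean <- start_mean
  for (i in seq_len(L)) {
    ero <- gray_erode(ero, kern)
    ero[!msk] <- 0
    rec <- reconstruct_dilation(ero, img, kern)
    cur_mean <- mean(rec[msk])
    g[i] <- 100 * (prev_mean - cur_mean) / start_mean
    prev_mean <- cur_mean
  }
  structure(g, start_mean = start_mean, zero_signal = FALSE,
            class = "granularity_spectrum")
}

#' @export
print.granularity_spectrum <- function(x, ...) {
  cat("granularity spectrum (% signal removed per erosion scale):\n")
  print(round(unclass(x), 4))
  cat("start mean:", format(attr(x, "start_mean")),
      if (isTRUE(attr(x, "zero_signal"))) "(zero signal)" else "", "\n")
  invisible(x)
}

#' Clustering score from a granularity spectrum
#'
#' Returns the spectrum element used as the clustering statistic; the
#' screen used the second instance of a length-5 spectrum.
#'
#' @param spectrum a [granularity_spectrum()] or numeric vector.
#' @param index 1-based element (default 2).
#' @return scalar score, percent of initial signal.
#' @export
clustering_score <- function(spectrum, index = 2L) {
  if (index < 1 || index > length(spectrum))
    stop("score index ", index, " outside spectrum of length ", length(spectrum))
  as.numeric(spectrum[[index]])
}

#' Score every nucleus in a field
#'
#' Computes the granularity spectrum and clustering score per labeled
#' nucleus of the marker channel.
#'
#' @param marker_raster numeric matrix (marker channel).
#' @param label_raster integer matrix of nucleus labels (0 = background),
#'   aligned with `marker_raster`.
#' @param params a [granularity_params()].
#' @return data frame with one row per nucleus: `label`, `n_pixels`,
#'   `g_1..g_L`, `score`, `zero_signal`.
#' @export
score_field <- function(marker_raster, label_raster,
                        params = granularity_params()) {
  if (!all(dim(marker_raster) == dim(label_raster)))
    stop("marker raster and label raster shapes differ")
  labs <- sort(unique(label_raster[label_raster > 0]))
  rows <- vector("list", length(labs))
  for (j in seq_along(labs)) {
    msk <- label_raster == labs[j]
    sp <- granularity_spectrum(marker_raster, msk, params)
    row <- data.frame(label = labs[j], n_pixels = sum(msk))
    gvals <- as.numeric(sp)
    names(gvals) <- paste0("g_", seq_along(gvals))
    row <- cbind(row, as.data.frame(as.list(gvals)))
    row$score <- clustering_score(sp, params$score_index)
    row$zero_signal <- isTRUE(attr(sp, "zero_signal"))
    rows[[j]] <- row
  }
  if (length(rows) == 0) {
    gn <- paste0("g_", seq_len(params$spectrum_length))
    out <- as.data.frame(c(list(label = integer(), n_pixels = integer()),
                           stats::setNames(rep(list(numeric()), length(gn)), gn),
                           list(score = numeric(), zero_signal = logical())))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
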