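#' Two-class Otsu threshold
#'
#' Computes the intensity threshold maximizing between-class variance over a
#' histogram of the raster's observed range. Pixels strictly above the
#' returned value are foreground. Candidate thresholds are the internal bin
#' edges; ties are broken toward the smallest candidate.
#'
#' @param raster numeric matrix with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return threshold intensity (scalar).
#' @export
otsu_threshold <- function(raster, n_bins = 256L) {
  x <- as.vector(raster)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("cannot Otsu-threshold a constant raster (no intensity contrast)")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- as.numeric(tabulate(bin, nbins = n_bins))
  sums <- numeric(n_bins)              # exact intensity sum per bin
  agg <- rowsum(x, bin)
  sums[as.integer(rownames(agg))] <- agg
  n <- sum(counts)
  w0 <- cumsum(counts)                 # pixels in bins 1..k
  s0 <- cumsum(sums)
  total <- s0[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- n - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[k][valid] / w0[k][valid]
  mu1 <- (total - s0[k][valid]) / w1[valid]
  bcv[valid] <- w0[k][valid] * w1[valid] * (mu0 - mu1)^2
  best <- which.max(bcv)               # first maximum = smallest threshold
  breaks[best + 1L]
}

#' Nucleus segmentation parameters
#'
#' @param min_area smallest nucleus area kept, pixels.
#' @param exclude_border drop components touching the image border.
#' @param fill_holes fill interior holes before measuring.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_area = 200L, exclude_border = TRUE,
                                fill_holes = TRUE) {
  stopifnot(min_area >= 0)
  structure(list(min_area = as.integer(min_area),
                 exclude_border = isTRUE(exclude_border),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

#' Segment nuclei from a DAPI raster
#'
#' Thresholds the DAPI channel with two-class Otsu, labels 8-connected
#' foreground components, optionally fills holes and drops border-touching
#' components, and filters by minimum area. A constant raster yields an
#' empty result with a warning so plate processing can continue.
#'
#' @param dapi_raster numeric matrix.
#' @param params a [segmentation_params()].
#' @return list with `labels` (integer matrix, 0 = background) and `nuclei`,
#'   a data frame with label, area, centroid_row, centroid_col and the
#'   0-based half-open bounding box.
#' @export
segment_nuclei <- function(dapi_raster, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  h <- nrow(dapi_raster); w <- ncol(dapi_raster)
  empty <- list(labels = matrix(0L, h, w),
                nuclei = data.frame(label = integer(), area = integer(),
                                    centroid_row = numeric(), centroid_col = numeric(),
                                    bbox_r0 = integer(), bbox_r1 = integer(),
                                    bbox_c0 = integer(), bbox_c1 = integer()))
  if (min(dapi_raster) == max(dapi_raster)) {
    warning("constant DAPI raster: returning empty segmentation")
    return(empty)
  }
  thr <- otsu_threshold(dapi_raster)
  fg <- dapi_raster > thr
  if (params$fill_holes) fg <- as.matrix(EBImage::fillHull(fg * 1)) > 0
  lab <- label_components_8(fg)
  if (max(lab) == 0) return(empty)

  keep <- integer()
  recs <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < params$min_area) next
    touches <- any(idx[, 1] %in% c(1L, h)) || any(idx[, 2] %in% c(1L, w))
    if (params$exclude_border && touches) next
    keep <- c(keep, id)
    recs[[length(recs) + 1L]] <- data.frame(
      label = id, area = area,
      centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
      bbox_r0 = min(idx[, 1]) - 1L, bbox_r1 = max(idx[, 1]),
      bbox_c0 = min(idx[, 2]) - 1L, bbox_c1 = max(idx[, 2]))
  }
  if (length(keep) == 0) return(empty)
  out_lab <- matrix(0L, h, w)
  nuclei <- do.call(rbind, recs)
  for (j in seq_along(keep)) out_lab[lab == keep[j]] <- j
  nuclei$label <- seq_along(keep)
  list(labels = out_lab, nuclei = nuclei)
}
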