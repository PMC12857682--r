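# Grayscale morphology primitives.
#
# EBImage's grayscale erode/dilate operate on intensities clamped to [0, 1],
# with min/max taken over the in-bounds kernel pixels only (outside-image
# pixels are ignored). Erosion and dilation commute with positive affine
# intensity maps, so arbitrary-range rasters are rescaled into [0, 1], run
# through EBImage, and mapped back.

disc_brush <- function(radius) {
  stopifnot(radius >= 1)
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# radius-1 disc: the 4-neighbourhood cross
cross_brush <- function() {
  EBImage::makeBrush(3L, shape = "diamond")
}

.affine_morph <- function(x, kern, op) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x)  # flat raster is a fixpoint of both ops
  span <- rng[2] - rng[1]
  y <- (x - rng[1]) / span
  z <- if (op == "erode") EBImage::erode(y, kern) else EBImage::dilate(y, kern)
  as.matrix(z) * span + rng[1]
}

gray_erode <- function(x, kern) .affine_morph(x, kern, "erode")

gray_dilate <- function(x, kern) .affine_morph(x, kern, "dilate")

gray_opening <- function(x, kern) gray_dilate(gray_erode(x, kern), kern)

#' Morphological reconstruction by geodesic dilation
#'
#' Iterates `marker <- pmin(dilate(marker, kern), mask)` to its fixpoint.
#' Requires `marker <= mask` everywhere; the result is the largest raster
#' below `mask` reachable from `marker` by dilation, i.e. the grayscale
#' reconstruction of `mask` from `marker`.
#'
#' @param marker numeric matrix, pointwise `<= mask`.
#' @param mask numeric matrix, the ceiling of the reconstruction.
#' @param kern structuring element (default: radius-1 disc).
#' @param max_iter iteration cap; reaching it raises an error.
#' @return reconstructed numeric matrix.
#' @keywords internal
reconstruct_dilation <- function(marker, mask, kern = cross_brush(),
                                 max_iter = sum(dim(mask)) * 4L) {
  stopifnot(all(dim(marker) == dim(mask)))
  if (any(marker > mask + 1e-12)) stop("reconstruction marker exceeds its mask")
  cur <- pmin(marker, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(gray_dilate(cur, kern), mask)
    if (identical(dim(nxt), dim(cur)) && all(nxt == cur)) return(cur)
    cur <- nxt
  }
  stop("geodesic reconstruction did not converge within ", max_iter, " iterations")
}

#' 8-connected component labeling
#'
#' Labels foreground pixels of a logical matrix by min-label propagation over
#' the 8-neighbourhood until stable. Labels are renumbered 1..n in order of
#' first (column-major) occurrence; background is 0.
#'
#' @param fg logical matrix.
#' @return integer matrix of the same shape.
#' @keywords internal
label_components_8 <- function(fg) {
  stopifnot(is.logical(fg) || all(fg %in% c(0, 1)))
  fg <- fg != 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  if (!any(fg)) return(lab)
  lab[fg] <- which(fg)

  shift <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]

  big <- .Machine$integer.max
  repeat {
    cur <- lab
    cur[!fg] <- big
    best <- cur
    for (k in seq_len(nrow(offs))) {
      best <- pmin(best, shift(cur, offs$dr[k], offs$dc[k], fill = big))
    }
    best[!fg] <- 0L
    if (all(best == lab)) break
    lab <- best
  }
  ids <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  storage.mode(lab) <- "integer"
  lab
}
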