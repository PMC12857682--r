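# Literal-definition reference implementations used as independent oracles.
# These transcribe the textbook definitions directly (padding, per-offset
# shifts, fixpoint loops) and share no code with the package internals.

# kernel offsets of a disc of the given radius (cross for radius "x1")
oracle_disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[sqrt(g$dr^2 + g$dc^2) <= radius + 0.5, ]   # disc inclusion rule
}

oracle_cross_offsets <- function() {
  data.frame(dr = c(-1, 0, 0, 0, 1), dc = c(0, -1, 0, 1, 0))
}

.oracle_shift <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# erosion: min over in-bounds kernel pixels (pad +Inf)
oracle_erode <- function(m, off) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmin(out, .oracle_shift(m, off$dr[i], off$dc[i], Inf))
  out
}

# dilation: max over in-bounds kernel pixels (pad -Inf)
oracle_dilate <- function(m, off) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- pmax(out, .oracle_shift(m, off$dr[i], off$dc[i], -Inf))
  out
}

oracle_opening <- function(m, off) oracle_dilate(oracle_erode(m, off), off)

# geodesic reconstruction by dilation, plain fixpoint loop
oracle_reconstruct <- function(marker, mask, off = oracle_cross_offsets()) {
  cur <- pmin(marker, mask)
  repeat {
    nxt <- pmin(oracle_dilate(cur, off), mask)
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}

# literal granularity spectrum: background subtraction by opening, then the
# erode / reconstruct-under-original loop, means over the mask
oracle_granularity <- function(raster, mask, radius, L) {
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  img <- raster[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  img <- pmax(img - oracle_opening(img, oracle_disc_offsets(radius)), 0)
  img[!msk] <- 0
  cross <- oracle_cross_offsets()
  start_mean <- mean(img[msk])
  g <- numeric(L)
  if (start_mean <= 0) return(g)
  ero <- img
  prev <- start_mean
  for (i in seq_len(L)) {
    ero <- oracle_erode(ero, cross)
    ero[!msk] <- 0
    rec <- oracle_reconstruct(ero, img, cross)
    cur <- mean(rec[msk])
    g[i] <- 100 * (prev - cur) / start_mean
    prev <- cur
  }
  g
}

# exhaustive Otsu: try every internal bin edge of the observed-range
# histogram, computing class weights and means from the raw pixel values
oracle_otsu <- function(raster, n_bins = 256L) {
  x <- as.vector(raster)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  best_t <- NA_real_
  best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    t <- breaks[k + 1L]
    lo <- x[x < t]; hi <- x[x >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }   # first maximum wins ties
  }
  best_t
}

# greedy pairing oracle: sort the full pair list, consume destructively
oracle_greedy_pairs <- function(ax, ay, bx, by, cutoff) {
  cand <- expand.grid(ia = seq_along(ax), ib = seq_along(bx))
  cand$d <- sqrt((ax[cand$ia] - bx[cand$ib])^2 + (ay[cand$ia] - by[cand$ib])^2)
  cand <- cand[order(cand$d, cand$ia, cand$ib), ]
  used_a <- c(); used_b <- c(); res <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$d[i] > cutoff) next
    if (cand$ia[i] %in% used_a || cand$ib[i] %in% used_b) next
    res[[length(res) + 1]] <- cand[i, ]
    used_a <- c(used_a, cand$ia[i]); used_b <- c(used_b, cand$ib[i])
  }
  if (length(res) == 0)
    return(data.frame(ia = integer(), ib = integer(), d = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# small clustered test field: k Gaussian blobs on a plain background
make_blob_field <- function(n = 64, k = 4, amplitude = 100, sigma = 1.5,
                            background = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(background, n, n)
  pos <- cbind(runif(k, 8, n - 8), runif(k, 8, n - 8))
  for (i in seq_len(k)) {
    rr <- matrix(seq_len(n), n, n) - pos[i, 1]
    cc <- matrix(seq_len(n), n, n, byrow = TRUE) - pos[i, 2]
    m <- m + amplitude * exp(-(rr^2 + cc^2) / (2 * sigma^2))
  }
  m
}
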