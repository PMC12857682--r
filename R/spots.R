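#' FISH spot detection parameters
#'
#' Robust-background thresholding: within each nucleus the brightest and
#' dimmest `trim_fraction` of pixel intensities are discarded and the
#' threshold is the trimmed mean plus `k_sd` trimmed standard deviations.
#'
#' @param trim_fraction proportion trimmed from each intensity tail,
#'   in \[0, 0.45).
#' @param k_sd standard-deviation multiplier above the trimmed mean.
#' @param min_spot_area,max_spot_area area bounds for accepted spots,
#'   pixels. A diffraction-limited FISH spot thresholded near its base
#'   covers at least a 3x3 core at ~0.1 um/px, so the default minimum of 9
#'   rejects single-pixel noise excursions without touching real spots.
#' @param pairing_cutoff_um maximum center-to-center distance accepted when
#'   pairing cross-channel spots, micrometres.
#' @return an object of class `spot_params`.
#' @export
spot_params <- function(trim_fraction = 0.05, k_sd = 2,
                        min_spot_area = 9L, max_spot_area = 400L,
                        pairing_cutoff_um = 2) {
  p <- list(trim_fraction = trim_fraction, k_sd = k_sd,
            min_spot_area = as.integer(min_spot_area),
            max_spot_area = as.integer(max_spot_area),
            pairing_cutoff_um = pairing_cutoff_um)
  stopifnot(p$trim_fraction >= 0, p$trim_fraction < 0.45, p$k_sd > 0,
            p$min_spot_area >= 0, p$max_spot_area >= p$min_spot_area,
            p$pairing_cutoff_um > 0)
  structure(p, class = "spot_params")
}

#' Detect FISH spots within nuclei
#'
#' Per nucleus, thresholds the channel at the robust-background level
#' (trimmed mean + `k_sd` x trimmed SD of in-nucleus intensities), labels
#' 8-connected components above threshold, filters them by area, and
#' reports intensity-weighted centroids. Pixels outside every nucleus are
#' ignored, so spots centred outside nuclei are never reported. Nuclei with
#' fewer than 10 pixels are skipped with a warning.
#'
#' @param channel_raster numeric matrix (one FISH channel).
#' @param label_raster integer nucleus-label matrix aligned with the
#'   channel.
#' @param params a [spot_params()].
#' @return data frame with one row per spot: `nucleus`, `spot`, `row`,
#'   `col` (intensity-weighted centroid, pixels), `area`, `peak`.
#' @export
detect_spots <- function(channel_raster, label_raster, params = spot_params()) {
  if (!all(dim(channel_raster) == dim(label_raster)))
    stop("channel raster and label raster shapes differ")
  stopifnot(inherits(params, "spot_params"))
  empty <- data.frame(nucleus = integer(), spot = integer(), row = numeric(),
                      col = numeric(), area = integer(), peak = numeric())
  labs <- sort(unique(label_raster[label_raster > 0]))
  out <- list()
  for (lb in labs) {
    pix <- which(label_raster == lb, arr.ind = TRUE)
    npix <- nrow(pix)
    if (npix < 10L) {
      warning("nucleus ", lb, " has only ", npix, " pixels; skipped")
      next
    }
    # work inside the nucleus bounding box
    r0 <- min(pix[, 1]); r1 <- max(pix[, 1])
    c0 <- min(pix[, 2]); c1 <- max(pix[, 2])
    chan <- channel_raster[r0:r1, c0:c1, drop = FALSE]
    in_nuc <- label_raster[r0:r1, c0:c1, drop = FALSE] == lb
    vals <- sort(chan[in_nuc])
    k <- floor(npix * params$trim_fraction)
    kept <- vals[(k + 1L):(npix - k)]
    thr <- mean(kept) + params$k_sd * stats::sd(kept)
    fg <- chan > thr & in_nuc
    if (!any(fg)) next
    slab <- label_components_8(fg)
    for (sid in seq_len(max(slab))) {
      idx <- which(slab == sid, arr.ind = TRUE)
      area <- nrow(idx)
      if (area < params$min_spot_area || area > params$max_spot_area) next
      wts <- chan[cbind(idx[, 1], idx[, 2])]
      out[[length(out) + 1L]] <- data.frame(
        nucleus = lb, spot = length(out) + 1L,
        row = sum((idx[, 1] + r0 - 1L) * wts) / sum(wts),
        col = sum((idx[, 2] + c0 - 1L) * wts) / sum(wts),
        area = area, peak = max(wts))
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all A x B candidate pairs in one nucleus, sorted by (distance, iA, iB)
.candidate_pairs <- function(sa, sb) {
  grid <- expand.grid(ia = seq_len(nrow(sa)), ib = seq_len(nrow(sb)))
  grid$d_px <- sqrt((sa$row[grid$ia] - sb$row[grid$ib])^2 +
                      (sa$col[grid$ia] - sb$col[grid$ib])^2)
  grid[order(grid$d_px, grid$ia, grid$ib), ]
}

#' Pair cross-channel FISH spots by destructive greedy iteration
#'
#' Within each nucleus, all channel-A x channel-B spot distances are
#' enumerated and consumed in ascending order (ties broken by A index,
#' then B index); a pair is accepted when both spots are still unassigned
#' and the distance is within the cutoff. Accepted spots are removed from
#' further consideration, so no spot appears in two pairs.
#'
#' @param spots_a,spots_b data frames from [detect_spots()] for the two
#'   channels (columns `nucleus`, `row`, `col`).
#' @param cutoff_um maximum accepted center-to-center distance, um.
#' @param pixel_size micrometres per pixel.
#' @param method `"greedy"` (the screen's rule) or `"optimal"`, a
#'   minimum-total-distance bipartite assignment offered for sensitivity
#'   analysis on small per-nucleus spot sets.
#' @return data frame of allele pairs: `nucleus`, `spot_a`, `spot_b`
#'   (row indices into the inputs), `ccd_px`, `ccd_um`.
#' @export
pair_spots <- function(spots_a, spots_b, cutoff_um, pixel_size,
                       method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(cutoff_um > 0, pixel_size > 0)
  empty <- data.frame(nucleus = integer(), spot_a = integer(),
                      spot_b = integer(), ccd_px = numeric(), ccd_um = numeric())
  if (nrow(spots_a) == 0 || nrow(spots_b) == 0) return(empty)
  cutoff_px <- cutoff_um / pixel_size
  out <- list()
  for (nuc in sort(intersect(unique(spots_a$nucleus), unique(spots_b$nucleus)))) {
    ia_all <- which(spots_a$nucleus == nuc)
    ib_all <- which(spots_b$nucleus == nuc)
    sa <- spots_a[ia_all, , drop = FALSE]
    sb <- spots_b[ib_all, , drop = FALSE]
    cand <- .candidate_pairs(sa, sb)
    cand <- cand[cand$d_px <= cutoff_px, , drop = FALSE]
    if (nrow(cand) == 0) next
    sel <- if (method == "greedy") .greedy_consume(cand)
           else .optimal_assign(cand, nrow(sa), nrow(sb))
    if (nrow(sel) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      nucleus = nuc, spot_a = ia_all[sel$ia], spot_b = ib_all[sel$ib],
      ccd_px = sel$d_px, ccd_um = sel$d_px * pixel_size)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# destructively consume the sorted candidate list
.greedy_consume <- function(cand) {
  used_a <- integer(); used_b <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$ia[i] %in% used_a || cand$ib[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$ia[i])
    used_b <- c(used_b, cand$ib[i])
  }
  cand[keep, , drop = FALSE]
}

# exhaustive maximum-cardinality, minimum-total-distance matching;
# per-nucleus spot counts are tiny (a few alleles), so recursion suffices
.optimal_assign <- function(cand, na, nb) {
  best <- list(n = -1L, d = Inf, rows = integer())
  recurse <- function(i, used_a, used_b, rows, d) {
    if (i > nrow(cand)) {
      n <- length(rows)
      if (n > best$n || (n == best$n && d < best$d))
        best <<- list(n = n, d = d, rows = rows)
      return()
    }
    # upper bound: even taking every remaining candidate cannot beat best
    if (length(rows) + (nrow(cand) - i + 1L) < best$n) return()
    recurse(i + 1L, used_a, used_b, rows, d)
    if (!(cand$ia[i] %in% used_a) && !(cand$ib[i] %in% used_b))
      recurse(i + 1L, c(used_a, cand$ia[i]), c(used_b, cand$ib[i]),
              c(rows, i), d + cand$d_px[i])
  }
  recurse(1L, integer(), integer(), integer(), 0)
  cand[best$rows, , drop = FALSE]
}

#' Summarize center-to-center distances per well
#'
#' Aggregates allele-pair CCDs to per-well means and medians and computes
#' the fold change of each well mean against the mean of the nontargeting
#' control wells. When a `locus` column is present, fold changes are also
#' averaged per gene across loci.
#'
#' @param pairs data frame of pairs carrying `ccd_um` plus metadata columns
#'   `well`, `gene`, `condition` (and optionally `locus`).
#' @param control_condition condition token identifying control wells.
#' @return list with `wells` (per-well n, mean, median CCD and `fc`) and,
#'   when loci are present, `genes` (per-gene mean fold change across loci).
#' @export
summarize_ccd <- function(pairs, control_condition = "control") {
  stopifnot(all(c("ccd_um", "well", "gene", "condition") %in% names(pairs)))
  has_locus <- "locus" %in% names(pairs)
  key <- if (has_locus) c("locus", "well") else "well"
  grp <- interaction(pairs[key], drop = TRUE)
  wells <- do.call(rbind, lapply(split(pairs, grp), function(d) {
    data.frame(locus = if (has_locus) d$locus[1] else NA_character_,
               well = d$well[1], gene = d$gene[1], condition = d$condition[1],
               n_pairs = nrow(d), mean_ccd_um = mean(d$ccd_um),
               median_ccd_um = stats::median(d$ccd_um))
  }))
  rownames(wells) <- NULL
  fc <- rep(NA_real_, nrow(wells))
  for (lc in unique(wells$locus)) {
    in_locus <- if (has_locus) wells$locus %in% lc else rep(TRUE, nrow(wells))
    ctl <- in_locus & wells$condition == control_condition
    if (!any(ctl))
      stop("no control wells (condition '", control_condition, "')",
           if (has_locus) paste0(" for locus ", lc))
    fc[in_locus] <- wells$mean_ccd_um[in_locus] / mean(wells$mean_ccd_um[ctl])
  }
  wells$fc <- fc
  out <- list(wells = wells)
  if (has_locus) {
    assay <- wells[wells$condition != control_condition, ]
    out$genes <- do.call(rbind, lapply(split(assay, assay$gene), function(d) {
      data.frame(gene = d$gene[1], n_loci = length(unique(d$locus)),
                 mean_fc = mean(d$fc))
    }))
    rownames(out$genes) <- NULL
  }
  out
}
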