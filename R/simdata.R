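#' Configuration for a synthetic immunofluorescence field
#'
#' Describes a two-channel (DAPI + marker) 2D field of non-overlapping
#' elliptical nuclei whose marker channel carries a diffuse nucleoplasmic
#' level plus punctate Gaussian-profile clusters, degraded by Poisson shot
#' noise and additive Gaussian read noise. Intensities are in arbitrary
#' camera units on a 16-bit scale.
#'
#' @param image_shape integer length-2, (rows, cols) in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range (min, max) semi-major axis, pixels.
#' @param dapi_level DAPI intensity inside nuclei.
#' @param diffuse_level diffuse marker intensity inside nuclei.
#' @param cluster_count_per_nucleus punctate clusters per nucleus.
#' @param cluster_radius cluster extent in pixels; the Gaussian profile has
#'   `sigma = cluster_radius / 2`.
#' @param cluster_amplitude peak cluster intensity above the diffuse level.
#' @param noise_sd additive Gaussian read-noise standard deviation.
#' @param shot_scale photons per intensity unit for Poisson shot noise;
#'   `0` disables the shot-noise term.
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `field_sim_config`.
#' @export
field_sim_config <- function(image_shape = c(256L, 256L),
                             n_nuclei = 12L,
                             nucleus_radius_range = c(18, 28),
                             dapi_level = 2000,
                             diffuse_level = 500,
                             cluster_count_per_nucleus = 10L,
                             cluster_radius = 4,
                             cluster_amplitude = 1500,
                             noise_sd = 50,
                             shot_scale = 1,
                             pixel_size = 0.108,
                             seed = 0L) {
  cfg <- list(image_shape = as.integer(image_shape), n_nuclei = as.integer(n_nuclei),
              nucleus_radius_range = as.numeric(nucleus_radius_range),
              dapi_level = dapi_level, diffuse_level = diffuse_level,
              cluster_count_per_nucleus = as.integer(cluster_count_per_nucleus),
              cluster_radius = cluster_radius, cluster_amplitude = cluster_amplitude,
              noise_sd = noise_sd, shot_scale = shot_scale,
              pixel_size = pixel_size, seed = as.integer(seed))
  class(cfg) <- "field_sim_config"
  validate_field_sim_config(cfg)
  cfg
}

validate_field_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2, all(cfg$image_shape >= 8),
            cfg$n_nuclei >= 0, cfg$cluster_count_per_nucleus >= 0,
            length(cfg$nucleus_radius_range) == 2,
            all(cfg$nucleus_radius_range > 0),
            cfg$nucleus_radius_range[1] <= cfg$nucleus_radius_range[2],
            cfg$cluster_radius > 0, cfg$cluster_amplitude >= 0,
            cfg$noise_sd >= 0, cfg$shot_scale >= 0,
            cfg$dapi_level > 0, cfg$diffuse_level >= 0,
            cfg$pixel_size > 0)
  invisible(cfg)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# rejection-sample non-overlapping ellipse parameters
place_nuclei <- function(cfg, max_tries = 200L) {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  rmax <- cfg$nucleus_radius_range[2]
  margin <- rmax + 2
  if (cfg$n_nuclei > 0 && (h <= 2 * margin || w <= 2 * margin))
    stop("image too small to place nuclei of radius ", rmax)
  out <- data.frame(id = integer(), row = numeric(), col = numeric(),
                    a = numeric(), b = numeric(), theta = numeric())
  for (i in seq_len(cfg$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, margin, h - margin)
      c <- stats::runif(1, margin, w - margin)
      a <- stats::runif(1, cfg$nucleus_radius_range[1], cfg$nucleus_radius_range[2])
      b <- a * stats::runif(1, 0.75, 1)    # mild eccentricity jitter
      th <- stats::runif(1, 0, pi)
      if (nrow(out) == 0 ||
          all(sqrt((out$row - r)^2 + (out$col - c)^2) > out$a + a + 2)) {
        out <- rbind(out, data.frame(id = i, row = r, col = c, a = a, b = b,
                                     theta = th))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", cfg$n_nuclei, " non-overlapping nuclei of radius up to ",
           rmax, " in a ", h, "x", w, " field after ", max_tries, " tries per nucleus")
  }
  out
}

# add a Gaussian profile in a local window (+-6 sigma), optionally clipped
# to a mask
add_gaussian <- function(m, row, col, amplitude, sigma, mask = NULL) {
  h <- nrow(m); w <- ncol(m)
  ext <- ceiling(6 * sigma)
  rs <- max(1L, floor(row - ext)):min(h, ceiling(row + ext))
  cs <- max(1L, floor(col - ext)):min(w, ceiling(col + ext))
  rr <- matrix(rs, length(rs), length(cs)) - row
  cc <- matrix(cs, length(rs), length(cs), byrow = TRUE) - col
  g <- amplitude * exp(-(rr^2 + cc^2) / (2 * sigma^2))
  if (!is.null(mask)) g[!mask[rs, cs]] <- 0
  m[rs, cs] <- m[rs, cs] + g
  m
}

# logical mask of one ellipse on the field grid
ellipse_mask <- function(h, w, row, col, a, b, theta) {
  rr <- matrix(seq_len(h), h, w) - row
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - col
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Poisson shot noise then Gaussian read noise; intensities stay >= 0
.noise_field <- function(m, cfg) {
  x <- as.vector(m)
  if (cfg$shot_scale > 0)
    x <- stats::rpois(length(x), lambda = x * cfg$shot_scale) / cfg$shot_scale
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(length(x), sd = cfg$noise_sd)
  matrix(pmax(x, 0), nrow(m), ncol(m))
}

#' Simulate a two-channel nuclear field
#'
#' Places non-overlapping elliptical nuclei, fills the DAPI channel, and
#' builds the marker channel as diffuse nucleoplasmic signal plus
#' Gaussian-profile clusters, then applies the Poisson-Gaussian noise model.
#'
#' @param config a [field_sim_config()].
#' @return list with `dapi` and `marker` numeric matrices and `truth`, a list
#'   of `nuclei` and `clusters` data frames.
#' @export
simulate_field <- function(config) {
  validate_field_sim_config(config)
  with_seed(config$seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    nuc <- place_nuclei(config)
    dapi <- matrix(0, h, w)
    marker <- matrix(0, h, w)
    clusters <- data.frame(nucleus = integer(), row = numeric(), col = numeric(),
                           amplitude = numeric(), radius = numeric())
    sigma <- config$cluster_radius / 2
    for (i in seq_len(nrow(nuc))) {
      msk <- ellipse_mask(h, w, nuc$row[i], nuc$col[i], nuc$a[i], nuc$b[i],
                          nuc$theta[i])
      dapi[msk] <- config$dapi_level
      marker[msk] <- marker[msk] + config$diffuse_level
      for (k in seq_len(config$cluster_count_per_nucleus)) {
        # cluster centres inside the inner 80% of the ellipse
        repeat {
          u <- stats::runif(1, -0.8, 0.8); v <- stats::runif(1, -0.8, 0.8)
          if (u^2 / 0.64 + v^2 / 0.64 <= 1) break
        }
        cr <- nuc$row[i] + u * nuc$a[i] * cos(nuc$theta[i]) -
          v * nuc$b[i] * sin(nuc$theta[i])
        cc <- nuc$col[i] + u * nuc$a[i] * sin(nuc$theta[i]) +
          v * nuc$b[i] * cos(nuc$theta[i])
        if (config$cluster_amplitude > 0)
          marker <- add_gaussian(marker, cr, cc, config$cluster_amplitude,
                                 sigma, msk)
        clusters <- rbind(clusters,
                          data.frame(nucleus = i, row = cr, col = cc,
                                     amplitude = config$cluster_amplitude,
                                     radius = config$cluster_radius))
      }
    }
    dapi <- .noise_field(dapi, config)
    marker <- .noise_field(marker, config)
    list(dapi = dapi, marker = marker,
         truth = list(nuclei = nuc, clusters = clusters))
  })
}

#' Configuration for a synthetic two-colour DNA-FISH field
#'
#' Extends [field_sim_config()] with paired allele spots: each nucleus holds
#' `alleles_per_nucleus` spot pairs, one Gaussian spot per channel, whose
#' centre separation (the true center-to-center distance, CCD) is drawn from
#' a truncated-normal distribution in micrometres.
#'
#' @inheritParams field_sim_config
#' @param alleles_per_nucleus spot pairs per nucleus.
#' @param true_ccd_mean,true_ccd_sd mean and SD of the planted CCD, um.
#' @param spot_sigma Gaussian spot width, pixels.
#' @param spot_amplitude peak spot intensity.
#' @return an object of class `fish_sim_config`.
#' @export
fish_sim_config <- function(image_shape = c(512L, 512L),
                            n_nuclei = 16L,
                            nucleus_radius_range = c(24, 32),
                            dapi_level = 2000,
                            diffuse_level = 100,
                            noise_sd = 20,
                            shot_scale = 1,
                            pixel_size = 0.108,
                            alleles_per_nucleus = 2L,
                            true_ccd_mean = 1.0,
                            true_ccd_sd = 0.25,
                            spot_sigma = 1.5,
                            spot_amplitude = 3000,
                            seed = 0L) {
  cfg <- field_sim_config(image_shape = image_shape, n_nuclei = n_nuclei,
                          nucleus_radius_range = nucleus_radius_range,
                          dapi_level = dapi_level, diffuse_level = diffuse_level,
                          cluster_count_per_nucleus = 0L,
                          noise_sd = noise_sd, shot_scale = shot_scale,
                          pixel_size = pixel_size, seed = seed)
  cfg$alleles_per_nucleus <- as.integer(alleles_per_nucleus)
  cfg$true_ccd_mean <- true_ccd_mean
  cfg$true_ccd_sd <- true_ccd_sd
  cfg$spot_sigma <- spot_sigma
  cfg$spot_amplitude <- spot_amplitude
  stopifnot(cfg$alleles_per_nucleus >= 0, cfg$true_ccd_mean >= 0,
            cfg$true_ccd_sd >= 0, cfg$spot_sigma > 0, cfg$spot_amplitude > 0)
  class(cfg) <- c("fish_sim_config", "field_sim_config")
  cfg
}

#' Simulate a two-colour DNA-FISH field with paired allele spots
#'
#' @param config a [fish_sim_config()].
#' @return list with `dapi`, `channel_a`, `channel_b` matrices and `truth`
#'   (`nuclei`, `spots`, `pairs` with the planted CCD per allele in um).
#' @export
simulate_fish_field <- function(config) {
  stopifnot(inherits(config, "fish_sim_config"))
  with_seed(config$seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    nuc <- place_nuclei(config)
    dapi <- matrix(0, h, w)
    cha <- matrix(0, h, w)
    chb <- matrix(0, h, w)
    spots <- data.frame(nucleus = integer(), allele = integer(),
                        channel = character(), row = numeric(), col = numeric())
    pairs <- data.frame(nucleus = integer(), allele = integer(),
                        ccd_um = numeric())
    inside <- function(i, r, c)
      ((r - nuc$row[i]) * cos(nuc$theta[i]) + (c - nuc$col[i]) * sin(nuc$theta[i]))^2 / nuc$a[i]^2 +
      (-(r - nuc$row[i]) * sin(nuc$theta[i]) + (c - nuc$col[i]) * cos(nuc$theta[i]))^2 / nuc$b[i]^2 <= 0.92
    for (i in seq_len(nrow(nuc))) {
      msk <- ellipse_mask(h, w, nuc$row[i], nuc$col[i], nuc$a[i], nuc$b[i],
                          nuc$theta[i])
      dapi[msk] <- config$dapi_level
      cha[msk] <- cha[msk] + config$diffuse_level
      chb[msk] <- chb[msk] + config$diffuse_level
      # Allele territories: pair midpoints are kept far enough apart that
      # every cross-allele spot distance exceeds the true pair distances,
      # as in real nuclei where homologous loci occupy separate chromosome
      # territories. An early allele can land where no later allele fits,
      # so the whole allele set is placed jointly and restarted on failure.
      placement <- NULL
      for (restart in seq_len(40L)) {
        placed <- list()
        placed_mid <- matrix(numeric(), ncol = 2)
        placed_d <- numeric()
        failed <- FALSE
        for (al in seq_len(config$alleles_per_nucleus)) {
          ok <- FALSE
          for (draw in seq_len(10L)) {     # resample the CCD
            ccd_um <- stats::rnorm(1, config$true_ccd_mean, config$true_ccd_sd)
            if (ccd_um < 0) next
            d_px <- ccd_um / config$pixel_size
            if (d_px > 2 * nuc$b[i]) next  # cannot fit in this nucleus
            for (try in seq_len(100L)) {   # geometry tries for this CCD
              ang <- stats::runif(1, 0, 2 * pi)
              repeat {
                u <- stats::runif(1, -0.8, 0.8); v <- stats::runif(1, -0.8, 0.8)
                if (u^2 + v^2 <= 0.64) break
              }
              mr <- nuc$row[i] + u * nuc$a[i] * cos(nuc$theta[i]) -
                v * nuc$b[i] * sin(nuc$theta[i])
              mc <- nuc$col[i] + u * nuc$a[i] * sin(nuc$theta[i]) +
                v * nuc$b[i] * cos(nuc$theta[i])
              ra <- mr - d_px / 2 * sin(ang); ca <- mc - d_px / 2 * cos(ang)
              rb <- mr + d_px / 2 * sin(ang); cb <- mc + d_px / 2 * cos(ang)
              sep_ok <- nrow(placed_mid) == 0 ||
                all(sqrt((placed_mid[, 1] - mr)^2 + (placed_mid[, 2] - mc)^2) >
                      2 * pmax(placed_d, d_px) + 2 * config$spot_sigma)
              if (inside(i, ra, ca) && inside(i, rb, cb) && sep_ok) {
                placed[[al]] <- list(ra = ra, ca = ca, rb = rb, cb = cb,
                                     ccd_um = ccd_um)
                placed_mid <- rbind(placed_mid, c(mr, mc))
                placed_d <- c(placed_d, d_px)
                ok <- TRUE
                break
              }
            }
            if (ok) break
          }
          if (!ok) { failed <- TRUE; break }
        }
        if (!failed) { placement <- placed; break }
      }
      if (is.null(placement) && config$alleles_per_nucleus > 0)
        stop("could not place ", config$alleles_per_nucleus,
             " allele pairs with CCD ~N(", config$true_ccd_mean, ", ",
             config$true_ccd_sd, ") um inside nucleus ", i)
      for (al in seq_along(placement)) {
        p <- placement[[al]]
        cha <- add_gaussian(cha, p$ra, p$ca, config$spot_amplitude,
                            config$spot_sigma)
        chb <- add_gaussian(chb, p$rb, p$cb, config$spot_amplitude,
                            config$spot_sigma)
        spots <- rbind(spots,
                       data.frame(nucleus = i, allele = al,
                                  channel = c("A", "B"),
                                  row = c(p$ra, p$rb), col = c(p$ca, p$cb)))
        pairs <- rbind(pairs, data.frame(nucleus = i, allele = al,
                                         ccd_um = p$ccd_um))
      }
    }
    dapi <- .noise_field(dapi, config)
    cha <- .noise_field(cha, config)
    chb <- .noise_field(chb, config)
    list(dapi = dapi, channel_a = cha, channel_b = chb,
         truth = list(nuclei = nuc, spots = spots, pairs = pairs))
  })
}

#' Configuration for a synthetic siRNA screen table
#'
#' Emulates the well-level structure of a pooled-siRNA plate screen: genes
#' occupy assay wells across plates, outer wells carry nontargeting
#' controls, and a planted fraction of genes multiplicatively shifts the
#' well-level clustering score (suppressors shrink it, enhancers grow it).
#'
#' @param n_genes genes screened (one well per gene per replicate).
#' @param n_plates plates per replicate.
#' @param wells_per_plate total wells on a plate (default 384).
#' @param n_control_wells nontargeting control wells per plate, placed on
#'   the plate border (default 104, leaving 280 assay wells).
#' @param replicate_count biological replicates.
#' @param planted_suppressor_fraction,planted_enhancer_fraction proportions
#'   of genes planted as suppressors/enhancers.
#' @param suppressor_effect,enhancer_effect multiplicative shift on the true
#'   clustering score (suppressor < 1 < enhancer).
#' @param baseline_score baseline well-level clustering score (percent
#'   signal in the granularity sense).
#' @param well_noise_sd additive well-level noise SD, score units.
#' @param mean_nuclei mean segmented-nucleus count per well.
#' @param low_count_fraction fraction of wells planted as low-count
#'   (imaging dropouts).
#' @param low_count_mean mean nucleus count in low-count wells.
#' @param seed integer seed.
#' @return an object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 1000L,
                              n_plates = NULL,
                              wells_per_plate = 384L,
                              n_control_wells = 104L,
                              replicate_count = 2L,
                              planted_suppressor_fraction = 0.02,
                              planted_enhancer_fraction = 0.02,
                              suppressor_effect = 0.5,
                              enhancer_effect = 1.5,
                              baseline_score = 5,
                              well_noise_sd = 0.25,
                              mean_nuclei = 300,
                              low_count_fraction = 0,
                              low_count_mean = 100,
                              seed = 0L) {
  cap_per_plate <- wells_per_plate - n_control_wells
  if (is.null(n_plates)) n_plates <- ceiling(n_genes / cap_per_plate)
  cfg <- list(n_genes = as.integer(n_genes), n_plates = as.integer(n_plates),
              wells_per_plate = as.integer(wells_per_plate),
              n_control_wells = as.integer(n_control_wells),
              replicate_count = as.integer(replicate_count),
              planted_suppressor_fraction = planted_suppressor_fraction,
              planted_enhancer_fraction = planted_enhancer_fraction,
              suppressor_effect = suppressor_effect,
              enhancer_effect = enhancer_effect,
              baseline_score = baseline_score,
              well_noise_sd = well_noise_sd,
              mean_nuclei = mean_nuclei,
              low_count_fraction = low_count_fraction,
              low_count_mean = low_count_mean,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 0, cfg$n_plates >= 1,
            cfg$wells_per_plate >= 1,
            cfg$n_control_wells >= 0,
            cfg$wells_per_plate >= cfg$n_control_wells,
            cfg$replicate_count >= 1,
            cfg$planted_suppressor_fraction >= 0,
            cfg$planted_enhancer_fraction >= 0,
            cfg$planted_suppressor_fraction + cfg$planted_enhancer_fraction <= 1,
            cfg$suppressor_effect > 0, cfg$suppressor_effect < 1,
            cfg$enhancer_effect > 1,
            cfg$baseline_score > 0, cfg$well_noise_sd >= 0,
            cfg$mean_nuclei > 0, cfg$low_count_fraction >= 0,
            cfg$low_count_fraction <= 1, cfg$low_count_mean > 0)
  class(cfg) <- "screen_sim_config"
  cfg
}

# well ids for an nr x nc plate: "A01".."P24" for 384
plate_well_ids <- function(wells_per_plate) {
  if (wells_per_plate == 384L) { nr <- 16L; nc <- 24L }
  else if (wells_per_plate == 96L) { nr <- 8L; nc <- 12L }
  else {
    nr <- max(1L, as.integer(floor(sqrt(wells_per_plate / 1.5))))
    nc <- as.integer(ceiling(wells_per_plate / nr))
  }
  rows <- rep(LETTERS[seq_len(nr)], each = nc)
  cols <- rep(seq_len(nc), nr)
  ids <- sprintf("%s%02d", rows, cols)
  border <- rep(seq_len(nr), each = nc) %in% c(1L, nr) | cols %in% c(1L, nc)
  data.frame(well = ids, border = border)[seq_len(wells_per_plate), ]
}

#' Simulate well-level screen tables with planted effects
#'
#' @param config a [screen_sim_config()].
#' @return list with `wells` (plate, well, gene, sirna_id, condition,
#'   replicate, n_nuclei, median_score) and `truth` (gene, class, effect).
#' @export
simulate_screen_tables <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  capacity <- config$n_plates * (config$wells_per_plate - config$n_control_wells)
  if (config$n_genes > capacity)
    stop("n_genes (", config$n_genes, ") exceeds screen capacity (",
         capacity, " assay wells across ", config$n_plates, " plates)")
  with_seed(config$seed, {
    n_sup <- round(config$n_genes * config$planted_suppressor_fraction)
    n_enh <- round(config$n_genes * config$planted_enhancer_fraction)
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    cls <- rep("none", config$n_genes)
    if (config$n_genes > 0) {
      planted <- sample.int(config$n_genes, n_sup + n_enh)
      cls[planted[seq_len(n_sup)]] <- "suppressor"
      if (n_enh > 0) cls[planted[n_sup + seq_len(n_enh)]] <- "enhancer"
    }
    effect <- ifelse(cls == "suppressor", config$suppressor_effect,
                     ifelse(cls == "enhancer", config$enhancer_effect, 1))
    truth <- data.frame(gene = genes, class = cls, effect = effect)

    grid <- plate_well_ids(config$wells_per_plate)
    ctl_idx <- which(grid$border)
    if (length(ctl_idx) < config$n_control_wells)
      ctl_idx <- c(ctl_idx, setdiff(seq_len(nrow(grid)), ctl_idx))
    ctl_idx <- ctl_idx[seq_len(config$n_control_wells)]
    assay_idx <- setdiff(seq_len(nrow(grid)), ctl_idx)

    rows <- list()
    gi <- 1L
    for (p in seq_len(config$n_plates)) {
      n_here <- min(length(assay_idx), config$n_genes - gi + 1L)
      plate_genes <- if (n_here > 0) genes[gi:(gi + n_here - 1L)] else character()
      gi <- gi + n_here
      wells <- c(grid$well[ctl_idx],
                 if (n_here > 0) grid$well[assay_idx[seq_len(n_here)]])
      gene_col <- c(rep("NTC", config$n_control_wells), plate_genes)
      cond <- c(rep("control", config$n_control_wells), rep("assay", n_here))
      rows[[p]] <- data.frame(plate = p, well = wells, gene = gene_col,
                              sirna_id = ifelse(cond == "control", "NTC_pool",
                                                paste0("pool_", gene_col)),
                              condition = cond)
    }
    layout <- do.call(rbind, rows)

    out <- list()
    for (rep_i in seq_len(config$replicate_count)) {
      df <- layout
      df$replicate <- rep_i
      true_score <- ifelse(df$condition == "control", config$baseline_score,
                           config$baseline_score *
                             truth$effect[match(df$gene, truth$gene)])
      df$median_score <- pmax(
        true_score + stats::rnorm(nrow(df), sd = config$well_noise_sd), 0)
      low <- stats::runif(nrow(df)) < config$low_count_fraction
      mu <- ifelse(low, config$low_count_mean, config$mean_nuclei)
      df$n_nuclei <- pmax(0L, as.integer(round(
        stats::rnorm(nrow(df), mean = mu, sd = 0.1 * mu))))
      out[[rep_i]] <- df
    }
    wells <- do.call(rbind, out)
    rownames(wells) <- NULL
    wells <- wells[, c("plate", "well", "gene", "sirna_id", "condition",
                       "replicate", "n_nuclei", "median_score")]
    list(wells = wells, truth = truth)
  })
}
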