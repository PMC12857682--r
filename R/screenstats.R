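#' Default hit-calling thresholds
#'
#' The committed defaults are the published calling rules of the screen:
#' primary-round plate z-score gates, de-pooled two-best-siRNA fold-change
#' gates, secondary-round dual gates per assay with a two-of-three overlap
#' rule for enhancers, the CTCF stratification band, and the nontargeting
#' control band. All inequalities are strict; boundary values fail.
#'
#' @return nested list of class `screen_thresholds`.
#' @export
screen_thresholds <- function() {
  structure(list(
    primary = list(z_nipbl_both = -2.1, z_nipbl_any = -2.45,
                   z_wapl_both = 2.45, z_wapl_any = 2.9),
    depooled = list(nipbl_best = 0.80, nipbl_second = 0.90,
                    wapl_best = 1.30, wapl_second = 1.10),
    secondary = list(
      suppressor = list(ko = 0.87, degron = 0.90),
      enhancer = list(ko = list(assay = 1.1, degron = 1.1),
                      siwapl = list(assay = 1.15, degron = 1.1),
                      alone = list(assay = 1.15, degron = 1.1)),
      overlap_min = 2L),
    ctcf_band = 0.07,
    control_band = 0.07,
    exclusion_genes = character()
  ), class = "screen_thresholds")
}

#' Per-well median clustering scores
#'
#' Collapses a per-nucleus score table to one record per layout well:
#' the nucleus count and the median clustering score.
#'
#' @param scores data frame with columns `plate`, `well`, `score` (one row
#'   per nucleus).
#' @param layout layout table with columns `plate`, `well`, `gene`,
#'   `sirna_id`, `condition`, `replicate`.
#' @return the layout with `n_nuclei` and `median_score` columns appended;
#'   wells without nuclei carry `n_nuclei = 0` and `median_score = NA`.
#' @export
well_medians <- function(scores, layout) {
  stopifnot(all(c("plate", "well", "score") %in% names(scores)))
  key <- function(d) paste(d$plate, d$well)
  unknown <- !(key(scores) %in% key(layout))
  if (any(unknown))
    stop("score rows reference wells absent from the layout, e.g. row ",
         which(unknown)[1], " (plate ", scores$plate[which(unknown)[1]],
         ", well ", scores$well[which(unknown)[1]], ")")
  out <- layout
  sk <- split(scores$score, key(scores))
  out$n_nuclei <- vapply(key(layout), function(k) {
    v <- sk[[k]]; if (is.null(v)) 0L else length(v)
  }, integer(1))
  out$median_score <- vapply(key(layout), function(k) {
    v <- sk[[k]]; if (is.null(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Filter wells by nucleus count
#'
#' @param wells well table with an `n_nuclei` column.
#' @param min_nuclei retention threshold (wells with `n_nuclei >=
#'   min_nuclei` are kept); the screen imaged >200 nuclei per well, so the
#'   default is 200.
#' @return list with `retained` and `dropped` well tables; the dropped
#'   table carries a `drop_reason` column.
#' @export
retain_wells <- function(wells, min_nuclei = 200L) {
  stopifnot(min_nuclei >= 0, "n_nuclei" %in% names(wells))
  keep <- wells$n_nuclei >= min_nuclei
  dropped <- wells[!keep, , drop = FALSE]
  if (nrow(dropped) > 0)
    dropped$drop_reason <- sprintf("n_nuclei %d < %d", dropped$n_nuclei,
                                   as.integer(min_nuclei))
  list(retained = wells[keep, , drop = FALSE], dropped = dropped)
}

#' Plate-wise z-scores of well medians
#'
#' Normalizes each well's median score against its plate (within
#' replicate): `z = (median_score - plate_mean) / plate_sd`, with the
#' sample (n-1) standard deviation. The normalization population is the
#' assay wells only; control wells receive z-scores relative to the same
#' population but do not contribute to the mean or SD.
#'
#' @param wells well table with `plate`, `replicate`, `condition`,
#'   `median_score`.
#' @param population condition token of the normalization population.
#' @return the well table with a `z` column appended.
#' @export
plate_zscores <- function(wells, population = "assay") {
  stopifnot(all(c("plate", "replicate", "condition", "median_score")
                %in% names(wells)))
  out <- wells
  out$z <- NA_real_
  for (grp in split(seq_len(nrow(wells)),
                    paste(wells$plate, wells$replicate))) {
    pop <- grp[wells$condition[grp] == population &
                 !is.na(wells$median_score[grp])]
    if (length(pop) < 2)
      stop("normalization population has fewer than 2 wells on plate ",
           wells$plate[grp[1]], " replicate ", wells$replicate[grp[1]])
    m <- mean(wells$median_score[pop])
    s <- stats::sd(wells$median_score[pop])
    if (s == 0)
      stop("zero spread in normalization population on plate ",
           wells$plate[grp[1]], " replicate ", wells$replicate[grp[1]])
    out$z[grp] <- (wells$median_score[grp] - m) / s
  }
  out
}

#' Primary-round hit calls from replicate z-scores
#'
#' A gene is NIPBL-like (suppressor) when its z-score is below
#' `z_nipbl_both` in both replicates or below `z_nipbl_any` in any
#' replicate; WAPL/PDS5-like (enhancer) when above `z_wapl_both` in both
#' or above `z_wapl_any` in any. Genes on the exclusion list (degron and
#' proteasome machinery) are forced to `none`. Genes missing a replicate
#' are flagged and not called.
#'
#' @param z_table data frame with `gene`, `z_rep1`, `z_rep2`.
#' @param thresholds a [screen_thresholds()].
#' @param exclusion_genes character vector of genes never called.
#' @return data frame of hit calls: `gene`, `round`, `class`, `z_rep1`,
#'   `z_rep2`, `excluded`, `insufficient`.
#' @export
call_primary_hits <- function(z_table, thresholds = screen_thresholds(),
                              exclusion_genes = thresholds$exclusion_genes) {
  stopifnot(all(c("gene", "z_rep1", "z_rep2") %in% names(z_table)))
  th <- thresholds$primary
  z1 <- z_table$z_rep1; z2 <- z_table$z_rep2
  insufficient <- is.na(z1) | is.na(z2)
  nip <- !insufficient &
    ((z1 < th$z_nipbl_both & z2 < th$z_nipbl_both) |
       (pmin(z1, z2) < th$z_nipbl_any))
  wap <- !insufficient &
    ((z1 > th$z_wapl_both & z2 > th$z_wapl_both) |
       (pmax(z1, z2) > th$z_wapl_any))
  cls <- ifelse(nip, "NIPBL-like", ifelse(wap, "WAPL/PDS5-like", "none"))
  excluded <- z_table$gene %in% exclusion_genes
  cls[excluded] <- "none"
  data.frame(gene = z_table$gene, round = "primary", class = cls,
             z_rep1 = z1, z_rep2 = z2, excluded = excluded,
             insufficient = insufficient)
}

#' Fold changes of well medians against nontargeting controls
#'
#' Per plate (within replicate), the fold change of each well's median
#' score relative to the median of the control well medians.
#'
#' @param wells well table with `plate`, `replicate`, `condition`,
#'   `median_score`.
#' @param control_condition condition token of the nontargeting controls.
#' @return the well table with an `fc` column appended.
#' @export
fold_changes <- function(wells, control_condition = "control") {
  stopifnot(all(c("plate", "replicate", "condition", "median_score")
                %in% names(wells)))
  out <- wells
  out$fc <- NA_real_
  for (grp in split(seq_len(nrow(wells)),
                    paste(wells$plate, wells$replicate))) {
    ctl <- grp[wells$condition[grp] == control_condition &
                 !is.na(wells$median_score[grp])]
    if (length(ctl) == 0)
      stop("no control wells on plate ", wells$plate[grp[1]],
           " replicate ", wells$replicate[grp[1]])
    cm <- stats::median(wells$median_score[ctl])
    if (cm <= 0)
      stop("nonpositive control median on plate ", wells$plate[grp[1]])
    out$fc[grp] <- wells$median_score[grp] / cm
  }
  out
}

#' De-pooled prioritization from per-siRNA fold changes
#'
#' Ranks a gene's individual-siRNA fold changes by effect in the called
#' direction and applies the two-best rule: suppressors pass when the most
#' effective siRNA decreases clustering by more than 20% (fc < 0.80) and
#' the second best by more than 10% (fc < 0.90); enhancers pass when the
#' best increases clustering by more than 30% (fc > 1.30) and the second
#' by more than 10% (fc > 1.10). Inequalities are strict.
#'
#' @param fcs numeric fold changes for the gene's siRNAs (nominally 4;
#'   missing siRNAs are dropped and flagged).
#' @param direction `"suppressor"` or `"enhancer"`.
#' @param thresholds a [screen_thresholds()].
#' @return list with `pass`, `best`, `second`, `n_sirna`, `incomplete`.
#' @export
prioritize_depooled <- function(fcs, direction = c("suppressor", "enhancer"),
                                thresholds = screen_thresholds()) {
  direction <- match.arg(direction)
  th <- thresholds$depooled
  incomplete <- length(fcs) != 4L || anyNA(fcs)
  fcs <- fcs[!is.na(fcs)]
  if (length(fcs) < 2)
    return(list(pass = FALSE, best = NA_real_, second = NA_real_,
                n_sirna = length(fcs), incomplete = TRUE))
  sorted <- if (direction == "suppressor") sort(fcs) else sort(fcs, decreasing = TRUE)
  best <- sorted[1]; second <- sorted[2]
  pass <- if (direction == "suppressor")
    best < th$nipbl_best && second < th$nipbl_second
  else
    best > th$wapl_best && second > th$wapl_second
  list(pass = pass, best = best, second = second, n_sirna = length(fcs),
       incomplete = incomplete)
}

#' Secondary-round hit call across orthogonal WAPL-depletion assays
#'
#' Each assay gate pairs the assay fold change with the same siRNA's
#' primary-screen (WAPL degron) fold change. Suppressors are hits when any
#' siRNA passes the WAPL KO gate (KO fc < 0.87 and degron fc < 0.90).
#' Enhancers are hits when at least `overlap_min` (default 2) of the three
#' assays (WAPL KO, WAPL siRNA codepletion, hit siRNA alone) have any
#' siRNA passing their dual gate.
#'
#' @param gene gene symbol (carried into the call record).
#' @param fc_table data frame with one row per siRNA: `sirna_id`,
#'   `degron`, and the tested assay columns among `ko`, `siwapl`, `alone`
#'   (fold changes; `NA` = not tested).
#' @param direction `"suppressor"` or `"enhancer"`.
#' @param thresholds a [screen_thresholds()].
#' @return one-row data frame: `gene`, `round`, `class`, per-assay pass
#'   flags, `n_assays_passed`, `supporting_sirna`.
#' @export
call_secondary <- function(gene, fc_table,
                           direction = c("suppressor", "enhancer"),
                           thresholds = screen_thresholds()) {
  direction <- match.arg(direction)
  stopifnot("degron" %in% names(fc_table))
  assays <- intersect(c("ko", "siwapl", "alone"), names(fc_table))
  if (length(assays) == 0 || all(vapply(fc_table[assays],
                                        function(x) all(is.na(x)), logical(1))))
    stop("no assay data for gene ", gene)
  th <- thresholds$secondary
  if (direction == "suppressor") {
    ok <- !is.na(fc_table$ko) & !is.na(fc_table$degron) &
      fc_table$ko < th$suppressor$ko & fc_table$degron < th$suppressor$degron
    hit <- any(ok)
    data.frame(gene = gene, round = "secondary",
               class = if (hit) "NIPBL-like" else "none",
               pass_ko = any(ok), pass_siwapl = NA, pass_alone = NA,
               n_assays_passed = as.integer(any(ok)),
               supporting_sirna = sum(ok))
  } else {
    pass <- vapply(assays, function(a) {
      g <- th$enhancer[[a]]
      any(!is.na(fc_table[[a]]) & !is.na(fc_table$degron) &
            fc_table[[a]] > g$assay & fc_table$degron > g$degron)
    }, logical(1))
    n_pass <- sum(pass)
    support <- sum(vapply(assays, function(a) {
      g <- th$enhancer[[a]]
      sum(!is.na(fc_table[[a]]) & !is.na(fc_table$degron) &
            fc_table[[a]] > g$assay & fc_table$degron > g$degron)
    }, numeric(1)))
    hit <- n_pass >= th$overlap_min
    data.frame(gene = gene, round = "secondary",
               class = if (hit) "WAPL/PDS5-like" else "none",
               pass_ko = if ("ko" %in% assays) pass[["ko"]] else NA,
               pass_siwapl = if ("siwapl" %in% assays) pass[["siwapl"]] else NA,
               pass_alone = if ("alone" %in% assays) pass[["alone"]] else NA,
               n_assays_passed = n_pass, supporting_sirna = support)
  }
}

#' Stratify a confirmed enhancer by CTCF clustering
#'
#' Enhancers of cohesin clustering split into WAPL-like and PDS5-like
#' classes by their effect on CTCF clustering: PDS5-like hits decrease
#' CTCF granularity below the control band (`ctcf_fc < 1 - band`, default
#' band 7%), WAPL-like hits do not.
#'
#' @param gene gene symbol.
#' @param rad21_fc RAD21 granularity fold change; must exceed 1 (the gene
#'   must be a confirmed enhancer).
#' @param ctcf_fc CTCF granularity fold change.
#' @param band half-width of the no-change band (default 0.07).
#' @return one-row data frame: `gene`, `round`, `class`, `rad21_fc`,
#'   `ctcf_fc`, `margin` (distance of `ctcf_fc` below the band edge;
#'   negative for WAPL-like).
#' @export
stratify_ctcf <- function(gene, rad21_fc, ctcf_fc, band = 0.07) {
  if (rad21_fc <= 1)
    stop("CTCF stratification applies to confirmed enhancers only ",
         "(rad21_fc = ", rad21_fc, " is not > 1)")
  stopifnot(band > 0, band < 1, ctcf_fc > 0)
  edge <- 1 - band
  cls <- if (ctcf_fc < edge) "PDS5-like" else "WAPL-like"
  data.frame(gene = gene, round = "stratified", class = cls,
             rad21_fc = rad21_fc, ctcf_fc = ctcf_fc, margin = edge - ctcf_fc)
}

#' Fraction of control fold changes inside the band
#'
#' Returns the fraction of control fold changes within `band` of the band
#' centre. By default the centre is the median of the controls themselves
#' (the band is drawn around the control median); pass `center = 1` to
#' take the fold changes as already normalized. With well-behaved controls
#' and a 7% band this fraction is ~98%.
#'
#' @param control_fcs numeric vector of control fold changes.
#' @param band half-width of the band (default 0.07).
#' @param center `"median"` or a numeric centre value.
#' @return fraction in \[0, 1\].
#' @export
control_band_fraction <- function(control_fcs, band = 0.07,
                                  center = "median") {
  control_fcs <- control_fcs[!is.na(control_fcs)]
  if (length(control_fcs) == 0) stop("no control fold changes supplied")
  stopifnot(band > 0)
  ctr <- if (identical(center, "median")) stats::median(control_fcs)
         else as.numeric(center)
  mean(abs(control_fcs / ctr - 1) <= band)
}

#' Pearson correlation between replicate z-score vectors
#'
#' @param z_rep1,z_rep2 paired numeric vectors, length >= 3, nonconstant.
#' @return Pearson product-moment correlation coefficient.
#' @export
replicate_correlation <- function(z_rep1, z_rep2) {
  stopifnot(length(z_rep1) == length(z_rep2), length(z_rep1) >= 3)
  if (anyNA(z_rep1) || anyNA(z_rep2))
    stop("z-score vectors contain NA; supply complete cases")
  if (stats::sd(z_rep1) == 0 || stats::sd(z_rep2) == 0)
    stop("replicate z-score vector is constant; correlation undefined")
  stats::cor(z_rep1, z_rep2)
}
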