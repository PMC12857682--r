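.layout3 <- function() {
  data.frame(plate = 1L, well = c("A01", "A02", "A03"),
             gene = c("G1", "G2", "NTC"), sirna_id = c("s1", "s2", "ntc"),
             condition = c("assay", "assay", "control"), replicate = 1L)
}

test_that("well medians aggregate per-nucleus scores exactly", {
  lay <- .layout3()
  scores <- data.frame(plate = 1L,
                       well = c("A01", "A01", "A01", "A02"),
                       score = c(1, 2, 3, 7))
  wm <- well_medians(scores, lay)
  expect_equal(wm$median_score, c(2, 7, NA))
  expect_equal(wm$n_nuclei, c(3L, 1L, 0L))
  bad <- data.frame(plate = 1L, well = "Z99", score = 1)
  expect_error(well_medians(bad, lay), "Z99")
})

test_that("well medians agree with a sort-based oracle on a full plate", {
  sim <- simulate_screen_tables(screen_sim_config(n_genes = 280L, seed = 1L))
  lay <- sim$wells[sim$wells$replicate == 1, ]
  set.seed(2)
  scores <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    data.frame(plate = lay$plate[i], well = lay$well[i],
               score = rnorm(7, mean = lay$median_score[i]))
  }))
  wm <- well_medians(scores, lay)
  expect_equal(nrow(wm), 384)
  oracle_med <- vapply(seq_len(nrow(lay)), function(i) {
    v <- sort(scores$score[scores$well == lay$well[i]])
    (v[4])                       # middle of 7 sorted values
  }, numeric(1))
  expect_equal(wm$median_score, oracle_med)
})

test_that("well retention thresholds and planted dropout rates work", {
  w <- data.frame(n_nuclei = c(150L, 250L))
  r <- retain_wells(w, 200L)
  expect_equal(r$retained$n_nuclei, 250L)
  expect_equal(r$dropped$n_nuclei, 150L)
  expect_match(r$dropped$drop_reason, "150 < 200")
  expect_equal(nrow(retain_wells(w, 0L)$dropped), 0)

  sim <- simulate_screen_tables(screen_sim_config(
    n_genes = 280L, low_count_fraction = 0.12, seed = 5L))
  kept <- retain_wells(sim$wells, 200L)
  frac <- nrow(kept$retained) / nrow(sim$wells)
  expect_lt(abs(frac - 0.88), 0.03)
})

test_that("plate z-scores normalize the assay population exactly", {
  w <- data.frame(plate = 1L, replicate = 1L,
                  condition = c("assay", "assay", "assay", "control"),
                  median_score = c(1, 2, 3, 10))
  z <- plate_zscores(w)
  expect_equal(z$z[1:3], c(-1, 0, 1))           # sample SD of {1,2,3} is 1
  expect_equal(z$z[4], (10 - 2) / 1)            # control scored, not in pop
  expect_equal(mean(z$z[1:3]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[1:3]), 1, tolerance = 1e-12)
  w0 <- w; w0$median_score <- c(2, 2, 2, 5)
  expect_error(plate_zscores(w0), "zero spread")
  expect_error(plate_zscores(w[3:4, ]), "fewer than 2")
})

test_that("replicate z-scores show the screen's replicate concordance", {
  # under the study conditions (2% + 2% planted hits at 0.5x / 1.5x, 5%
  # well noise) the between-replicate correlation is set by the ratio of
  # planted-effect variance to well noise, which lands at ~0.8 - the
  # concordance the screen design reports
  res <- run_pipeline(screen_sim_config(n_genes = 500L, seed = 7L),
                      min_nuclei = 0L)
  ok <- stats::complete.cases(res$z_table[, c("z_rep1", "z_rep2")])
  r <- replicate_correlation(res$z_table$z_rep1[ok], res$z_table$z_rep2[ok])
  expect_lt(abs(r - 0.80), 0.06)
})

test_that("primary hit calls reproduce the published z-gate examples", {
  zt <- data.frame(
    gene = c("a", "b", "c", "d", "e", "f"),
    z_rep1 = c(-2.2, -2.5, 3.0, 2.5, -5, NA),
    z_rep2 = c(-2.2, -1.0, 0.0, 2.4, -5, 1))
  hits <- call_primary_hits(zt, exclusion_genes = "e")
  expect_equal(hits$class,
               c("NIPBL-like",      # below -2.1 in both replicates
                 "NIPBL-like",      # below -2.45 in one replicate
                 "WAPL/PDS5-like",  # above 2.9 in one replicate
                 "none",            # 2.5/2.4 passes neither gate
                 "none",            # excluded degron-machinery gene
                 "none"))           # missing replicate: not called
  expect_true(hits$excluded[5])
  expect_true(hits$insufficient[6])
  # boundary values fail (strict inequalities)
  zb <- data.frame(gene = "x", z_rep1 = -2.1, z_rep2 = -2.1)
  expect_equal(call_primary_hits(zb)$class, "none")
})

test_that("more extreme z-scores never remove a primary call", {
  set.seed(9)
  for (i in 1:50) {
    z <- data.frame(gene = "g", z_rep1 = rnorm(1, 0, 3), z_rep2 = rnorm(1, 0, 3))
    cls <- call_primary_hits(z)$class
    if (cls == "NIPBL-like") {
      z2 <- z; z2$z_rep1 <- z$z_rep1 - runif(1, 0, 5)
      expect_equal(call_primary_hits(z2)$class, "NIPBL-like")
    } else if (cls == "WAPL/PDS5-like") {
      z2 <- z; z2$z_rep2 <- z$z_rep2 + runif(1, 0, 5)
      expect_equal(call_primary_hits(z2)$class, "WAPL/PDS5-like")
    }
  }
})

test_that("fold changes are exact against the plate control median", {
  w <- data.frame(plate = 1L, replicate = 1L,
                  condition = c("control", "control", "control", "assay"),
                  median_score = c(90, 100, 110, 80))
  fc <- fold_changes(w)
  expect_equal(fc$fc[4], 0.8)
  expect_equal(fc$fc[2], 1.0)
  sim <- simulate_screen_tables(screen_sim_config(
    n_genes = 50L, wells_per_plate = 96L, n_control_wells = 16L,
    well_noise_sd = 0, planted_suppressor_fraction = 0.1,
    planted_enhancer_fraction = 0, suppressor_effect = 0.5, seed = 8L))
  fc2 <- fold_changes(sim$wells[sim$wells$replicate == 1, ])
  sup <- sim$truth$gene[sim$truth$class == "suppressor"]
  expect_true(all(fc2$fc[fc2$gene %in% sup] == 0.5))
  w_noctl <- w[w$condition == "assay", , drop = FALSE]
  expect_error(fold_changes(w_noctl), "no control")
})

test_that("de-pooled prioritization applies the two-best siRNA rule strictly", {
  expect_true(prioritize_depooled(c(0.75, 0.85, 0.95, 1.02), "suppressor")$pass)
  expect_true(prioritize_depooled(c(1.35, 1.12, 1.00, 0.96), "enhancer")$pass)
  # boundaries are not strict passes
  expect_false(prioritize_depooled(c(0.80, 0.85, 1, 1), "suppressor")$pass)
  expect_false(prioritize_depooled(c(1.30, 1.12, 1, 1), "enhancer")$pass)
  expect_false(prioritize_depooled(c(0.75, 0.90, 1, 1), "suppressor")$pass)
  r <- prioritize_depooled(c(0.7, NA, 0.85, 0.99), "suppressor")
  expect_true(r$pass)
  expect_true(r$incomplete)
  expect_false(prioritize_depooled(c(0.5, NA, NA, NA), "suppressor")$pass)
})

test_that("secondary calls gate each assay against the degron fold change", {
  # suppressor: one siRNA crossing both halves of the KO gate suffices
  s <- call_secondary("g1", data.frame(sirna_id = "s1", degron = 0.88,
                                       ko = 0.85), "suppressor")
  expect_equal(s$class, "NIPBL-like")
  s2 <- call_secondary("g2", data.frame(sirna_id = "s1", degron = 0.91,
                                        ko = 0.85), "suppressor")
  expect_equal(s2$class, "none")    # degron half fails
  s3 <- call_secondary("g3", data.frame(sirna_id = "s1", degron = 0.88,
                                        ko = 0.87), "suppressor")
  expect_equal(s3$class, "none")    # boundary 0.87 is not < 0.87

  # enhancer: two of three assays passing makes a hit
  fc <- data.frame(sirna_id = c("s1", "s2"),
                   degron = c(1.11, 1.12),
                   ko = c(1.12, 1.05),
                   siwapl = c(1.20, 1.0),
                   alone = c(1.05, 1.0))
  e <- call_secondary("g4", fc, "enhancer")
  expect_equal(e$class, "WAPL/PDS5-like")
  expect_equal(e$n_assays_passed, 2L)
  expect_true(e$pass_ko && e$pass_siwapl && !e$pass_alone)
  # only one assay passing is no hit
  fc1 <- data.frame(sirna_id = "s1", degron = 1.15, ko = 1.0,
                    siwapl = 1.3, alone = 1.0)
  expect_equal(call_secondary("g5", fc1, "enhancer")$class, "none")
  expect_error(call_secondary("g6", data.frame(sirna_id = "s", degron = 1.2),
                              "enhancer"), "no assay data")
})

test_that("CTCF stratification splits enhancers at the band edge", {
  expect_equal(stratify_ctcf("t", 1.3, 0.85)$class, "PDS5-like")
  expect_equal(stratify_ctcf("w", 1.3, 1.15)$class, "WAPL-like")
  expect_equal(stratify_ctcf("n", 1.3, 1.00)$class, "WAPL-like")
  expect_equal(stratify_ctcf("b", 1.3, 0.93)$class, "WAPL-like")  # boundary
  expect_error(stratify_ctcf("x", 0.9, 0.8), "enhancers only")
})

test_that("control band fraction counts and matches the normal model", {
  expect_equal(control_band_fraction(rep(1, 10)), 1)
  # band centred at 1 when the fold changes are already normalized ...
  expect_equal(control_band_fraction(c(0.95, 1.05, 1.20), 0.07, center = 1),
               2 / 3)
  # ... and at the control median by default
  expect_equal(control_band_fraction(c(0.95, 1.05, 1.20), 0.07), 1 / 3)
  expect_error(control_band_fraction(numeric(0)), "no control")
  set.seed(4)
  frac <- control_band_fraction(rnorm(20000, 1, 0.03), 0.07)
  want <- pnorm(7 / 3) - pnorm(-7 / 3)       # 0.9804
  expect_lt(abs(frac - want), 0.01)
})

test_that("replicate correlation is exact on degenerate cases and calibrated", {
  x <- c(1, 2, 5, 3)
  expect_equal(replicate_correlation(x, x), 1.0)
  expect_equal(replicate_correlation(x, -x), -1.0)
  expect_error(replicate_correlation(x, rep(1, 4)), "constant")
  set.seed(12)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(n)
  expect_lt(abs(replicate_correlation(z1, z2) - 0.8), 0.02)
})

test_that("hit lists narrow monotonically across screening rounds", {
  set.seed(30)
  genes <- sprintf("g%02d", 1:40)
  zt <- data.frame(gene = genes, z_rep1 = rnorm(40, 0, 2),
                   z_rep2 = rnorm(40, 0, 2))
  primary <- call_primary_hits(zt)
  prim_hits <- primary$gene[primary$class != "none"]
  # de-pooled round evaluates primary hits only
  dep_hits <- Filter(function(g) {
    dir <- if (primary$class[primary$gene == g] == "NIPBL-like")
      "suppressor" else "enhancer"
    set.seed(match(g, genes))
    prioritize_depooled(runif(4, 0.6, 1.5), dir)$pass
  }, prim_hits)
  # secondary round evaluates de-pooled survivors only
  final_hits <- Filter(function(g) {
    dir <- if (primary$class[primary$gene == g] == "NIPBL-like")
      "suppressor" else "enhancer"
    set.seed(1000 + match(g, genes))
    fc <- data.frame(sirna_id = paste0("s", 1:4), degron = runif(4, 0.7, 1.4),
                     ko = runif(4, 0.7, 1.4), siwapl = runif(4, 0.7, 1.4),
                     alone = runif(4, 0.7, 1.4))
    call_secondary(g, fc, dir)$class != "none"
  }, dep_hits)
  expect_lte(length(final_hits), length(dep_hits))
  expect_lte(length(dep_hits), length(prim_hits))
  expect_true(all(final_hits %in% dep_hits))
  expect_true(all(dep_hits %in% prim_hits))
})
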