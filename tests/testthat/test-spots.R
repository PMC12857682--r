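# one circular nucleus label raster centred in an n x n field
.one_nucleus <- function(n = 64, radius = 24) {
  rr <- matrix(seq_len(n), n, n) - (n + 1) / 2
  lab <- matrix(0L, n, n)
  lab[rr^2 + t(rr)^2 <= radius^2] <- 1L
  lab
}

.gauss_at <- function(n, r, c, amp = 3000, sigma = 1.5) {
  rr <- matrix(seq_len(n), n, n) - r
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - c
  amp * exp(-(rr^2 + cc^2) / (2 * sigma^2))
}

test_that("a single planted spot is found at its centroid; outside spots are not", {
  lab <- .one_nucleus()
  set.seed(1)
  noise <- matrix(abs(rnorm(64 * 64, 100, 10)), 64)
  sp <- detect_spots(noise + .gauss_at(64, 30.3, 36.7), lab)
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$row - 30.3)^2 + (sp$col - 36.7)^2), 1)
  # same spot placed outside the nucleus: nothing reported
  sp2 <- detect_spots(noise + .gauss_at(64, 4, 4), lab)
  expect_equal(nrow(sp2), 0)
  # tiny nuclei are skipped with a warning
  lab_tiny <- matrix(0L, 16, 16); lab_tiny[8, 8] <- 1L
  expect_warning(detect_spots(matrix(1, 16, 16) + diag(16), lab_tiny),
                 "skipped")
})

test_that("detection on simulated FISH fields has high recall and precision", {
  ff <- simulate_fish_field(fish_sim_config(n_nuclei = 25L, seed = 0L))
  seg <- segment_nuclei(ff$dapi)
  for (chan in c("A", "B")) {
    found <- detect_spots(if (chan == "A") ff$channel_a else ff$channel_b,
                          seg$labels)
    truth <- ff$truth$spots[ff$truth$spots$channel == chan, ]
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      any(sqrt((found$row - truth$row[i])^2 +
                 (found$col - truth$col[i])^2) < 3)
    }, logical(1))
    matched <- vapply(seq_len(nrow(found)), function(i) {
      any(sqrt((truth$row - found$row[i])^2 +
                 (truth$col - found$col[i])^2) < 3)
    }, logical(1))
    expect_gte(mean(hit), 0.95)      # recall
    expect_gte(mean(matched), 0.95)  # precision
  }
})

test_that("pairing reproduces exact small cases and the distance cutoff", {
  a <- data.frame(nucleus = 1L, row = 0, col = 0)
  b <- data.frame(nucleus = 1L, row = 3, col = 4)
  pr <- pair_spots(a, b, cutoff_um = 10, pixel_size = 1)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$ccd_um, 5)         # 3-4-5 triangle
  b_far <- data.frame(nucleus = 1L, row = 30, col = 40)
  expect_equal(nrow(pair_spots(a, b_far, 10, 1)), 0)
  expect_equal(nrow(pair_spots(a[0, ], b, 10, 1)), 0)
})

test_that("greedy pairing equals the sorted-exhaustive-consumption oracle", {
  for (s in 1:100) {
    set.seed(s)
    for (k in c(3, 4)) {
      ax <- runif(k, 0, 50); ay <- runif(k, 0, 50)
      bx <- runif(k, 0, 50); by <- runif(k, 0, 50)
      cutoff <- runif(1, 10, 60)
      want <- oracle_greedy_pairs(ax, ay, bx, by, cutoff)
      got <- pair_spots(data.frame(nucleus = 1L, row = ax, col = ay),
                        data.frame(nucleus = 1L, row = bx, col = by),
                        cutoff_um = cutoff, pixel_size = 1)
      expect_equal(got$spot_a, want$ia)
      expect_equal(got$spot_b, want$ib)
      expect_equal(got$ccd_px, want$d)
    }
  }
})

test_that("pairings are valid matchings and deterministic", {
  for (s in 1:20) {
    set.seed(200 + s)
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- data.frame(nucleus = 1L, row = runif(na, 0, 40), col = runif(na, 0, 40))
    b <- data.frame(nucleus = 1L, row = runif(nb, 0, 40), col = runif(nb, 0, 40))
    pr <- pair_spots(a, b, cutoff_um = 25, pixel_size = 1)
    expect_lte(nrow(pr), min(na, nb))
    expect_false(any(duplicated(pr$spot_a)))
    expect_false(any(duplicated(pr$spot_b)))
    expect_true(all(pr$ccd_um <= 25))
    expect_identical(pr, pair_spots(a, b, 25, 1))
    # the optimal assignment never pairs fewer spots than greedy
    po <- pair_spots(a, b, 25, 1, method = "optimal")
    expect_gte(nrow(po), nrow(pr))
  }
})

test_that("CCD summaries compute exact means and fold changes", {
  pairs <- data.frame(ccd_um = rep(1.0, 6),
                      well = rep(c("A01", "B02"), each = 3),
                      gene = rep(c("NTC", "G1"), each = 3),
                      condition = rep(c("control", "assay"), each = 3))
  s <- summarize_ccd(pairs)
  expect_equal(s$wells$mean_ccd_um, c(1, 1))
  expect_equal(s$wells$fc, c(1, 1))   # identical to control: fc 1
  pairs$ccd_um[pairs$gene == "G1"] <- 0.8
  s2 <- summarize_ccd(pairs)
  expect_equal(s2$wells$fc[s2$wells$gene == "G1"], 0.8)
  expect_error(summarize_ccd(pairs[pairs$condition == "assay", ]), "control")
})

test_that("planted CCD shifts are recovered through the full FISH pipeline", {
  run_cond <- function(mean_um, seeds) {
    ccd <- c()
    for (s in seeds) {
      ff <- simulate_fish_field(fish_sim_config(n_nuclei = 25L,
                                                true_ccd_mean = mean_um,
                                                seed = s))
      seg <- segment_nuclei(ff$dapi)
      pr <- pair_spots(detect_spots(ff$channel_a, seg$labels),
                       detect_spots(ff$channel_b, seg$labels),
                       cutoff_um = 2, pixel_size = 0.108)
      ccd <- c(ccd, pr$ccd_um)
    }
    ccd
  }
  truth_mean <- function(mean_um, seeds) {
    mean(unlist(lapply(seeds, function(s)
      simulate_fish_field(fish_sim_config(n_nuclei = 25L,
                                          true_ccd_mean = mean_um,
                                          seed = s))$truth$pairs$ccd_um)))
  }
  ctl <- run_cond(1.0, 31:32)
  trt <- run_cond(0.8, 33:34)
  # measured means recover the generated truth means within 5%
  expect_lt(abs(mean(ctl) - truth_mean(1.0, 31:32)) / 1.0, 0.05)
  expect_lt(abs(mean(trt) - truth_mean(0.8, 33:34)) / 0.8, 0.05)
  fc <- mean(trt) / mean(ctl)
  expect_lt(abs(fc - 0.8), 0.08)                # fold-change recovery
})
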