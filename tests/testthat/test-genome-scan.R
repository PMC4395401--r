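# Genome scans: recombination-rate profile, distortion scan, BH control,
# collinearity, bin polymorphism.

linear_map <- function(n = 60, slope = 3, lg = 1L) {
  structure(
    tibble::tibble(
      linkage_group = lg,
      marker_id = sprintf("m%03d", seq_len(n)),
      bin = seq_len(n),
      pos_mb = seq(0, 20, length.out = n),
      cm = slope * seq(0, 20, length.out = n),
      chrom = 1L
    ),
    class = c("linkage_map", class(tibble::tibble()))
  )
}

test_that("a linear map yields a constant recombination-rate profile", {
  prof <- local_recomb_rate(linear_map(slope = 3))
  expect_true(all(abs(prof$rate_cm_mb - 3) < 1e-6))
  expect_equal(prof$log10_rate, log10(prof$rate_cm_mb))
  expect_true(all(diff(prof$mid_mb) > 0))
})

test_that("mean window rate agrees with the global slope on simulated maps", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_cM = 100, chrom_length_Mb = 30,
                    n_markers = 200, n_rils = 150, seed = 5)
  sim <- simulate_ril_population(cfg)
  map <- build_linkage_map(sim$calls)
  prof <- local_recomb_rate(map)
  global <- attr(map, "groups")$length_cm / diff(range(map$pos_mb))
  expect_lt(abs(mean(prof$rate_cm_mb) - global) / global, 0.1)
})

test_that("a recombination hotspot appears as the profile maximum", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_cM = 100, chrom_length_Mb = 30,
                    n_markers = 250, n_rils = 150, seed = 5,
                    hotspots = list(list(chrom = 1, start_mb = 10,
                                         end_mb = 18, fold = 5)))
  sim <- simulate_ril_population(cfg)
  map <- build_linkage_map(sim$calls)
  prof <- local_recomb_rate(map)
  peak <- prof$mid_mb[which.max(prof$rate_cm_mb)]
  expect_gte(peak, 10)
  expect_lte(peak, 18)
})

test_that("groups too small for a window warn and yield empty profiles", {
  small <- linear_map(n = 3)
  expect_warning(prof <- local_recomb_rate(small), "fewer than")
  expect_equal(nrow(prof), 0)
})

test_that("Benjamini-Hochberg matches a brute-force step-up evaluation", {
  brute <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= alpha * seq_len(m) / m)
    reject <- rep(FALSE, m)
    if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
    q <- rev(cummin(rev(ps * m / seq_len(m))))
    q_full <- numeric(m)
    q_full[o] <- pmin(q, 1)
    list(reject = reject, q = q_full)
  }
  expect_true(all(benjamini_hochberg(c(0.01, 0.02, 0.04), 0.05)$reject))
  expect_false(any(benjamini_hochberg(rep(1, 10), 0.05)$reject))
  withr::with_seed(8, {
    for (i in 1:1000) {
      m <- sample(1:40, 1)
      p <- round(runif(m), 3)
      alpha <- sample(c(0.01, 0.05, 0.1), 1)
      got <- benjamini_hochberg(p, alpha)
      want <- brute(p, alpha)
      expect_identical(got$reject, want$reject)
      expect_equal(got$q_values, want$q, tolerance = 1e-12)
      # the q-value formulation is equivalent to the step-up rule
      expect_identical(got$q_values <= alpha, want$reject)
    }
  })
})

test_that("the distortion chi-square matches the hand computation", {
  gt <- matrix(c(rep("AA", 80), rep("BB", 30)), 1,
               dimnames = list("m1", sprintf("s%d", 1:110)))
  scan <- segregation_scan(calls_from_matrix(gt))
  rec <- scan$records
  expect_equal(rec$chi2, 2 * 25^2 / 55, tolerance = 1e-12)
  expect_lt(rec$chi2_p, 1e-5)
  expect_equal(rec$delta, 50 / 110)
  expect_gt(rec$delta, 0)  # sign tracks the over-represented allele
})

test_that("SDR intervals require a run of same-direction significant markers", {
  sim <- tiny_sim(seed = 60, n_chromosomes = 2, n_markers = 120, n_rils = 150,
                  sdr_spec = list(chrom = 1, start_mb = 8, end_mb = 12, weight = 3))
  scan <- segregation_scan(sim$calls)
  expect_gt(nrow(scan$intervals), 0)
  hit <- scan$intervals[scan$intervals$chrom == 1, ]
  expect_true(any(hit$start_mb <= 12 & hit$end_mb >= 8))
  expect_true(all(hit$favored_allele == "A"))
  expect_true(all(scan$records$delta[scan$records$significant &
                                       scan$records$chrom == 1 &
                                       scan$records$pos_mb >= 8 &
                                       scan$records$pos_mb <= 12] > 0))
})

test_that("a distortion-free population rarely produces SDR intervals", {
  # under the global null BH rejects anything in at most ~5% of
  # replicates, so false intervals should be correspondingly rare; test
  # the rate with a calibrated binomial bound (99th percentile at p=0.05)
  hits <- vapply(1:40, function(s) {
    cfg <- sim_config(n_chromosomes = 1, n_markers = 80, chrom_length_cM = 90,
                      chrom_length_Mb = 25, n_rils = 100, seed = 200 + s)
    sim <- simulate_ril_population(cfg)
    nrow(segregation_scan(sim$calls, smooth = FALSE)$intervals)
  }, 0)
  expect_lte(sum(hits > 0), qbinom(0.99, 40, 0.05))
})

test_that("collinearity is perfect for linear maps in either orientation", {
  map <- linear_map()
  # an exactly linear map triggers R's perfect-fit warning; that is the point
  expect_equal(suppressWarnings(collinearity(map)$r_squared), 1,
               tolerance = 1e-12)
  rev_map <- map
  rev_map$cm <- max(map$cm) - map$cm
  expect_equal(suppressWarnings(collinearity(rev_map)$r_squared), 1,
               tolerance = 1e-12)
  # permuted positions give near-zero correlation
  perm <- map
  perm$pos_mb <- withr::with_seed(3, sample(map$pos_mb))
  expect_lt(collinearity(perm)$r_squared, 0.2)
  expect_equal(suppressWarnings(collinearity(map)$frac_chrom_match), 1)
})

test_that("bin polymorphism counts covered bins and replaceable markers", {
  map <- linear_map(n = 10)
  map$bin <- rep(1:5, each = 2)
  acc <- matrix("AA", 10, 3,
                dimnames = list(map$marker_id, sprintf("ACC_%d", 1:3)))
  # bins 1-4 get one polymorphic member each; bin 5 stays monomorphic
  acc[c(1, 3, 5, 7), 2] <- "BB"
  bp <- bin_polymorphism(map, calls_from_matrix(acc))
  expect_equal(bp$coverage, 0.8)
  # markers 2,4,6,8 are non-polymorphic but share a covered bin; 9,10 do not
  expect_equal(bp$replaceable, 4 / 6)
  # fully monomorphic panel
  acc0 <- matrix("AA", 10, 3, dimnames = dimnames(acc))
  expect_equal(bin_polymorphism(map, calls_from_matrix(acc0))$coverage, 0)
  # accession panel generator is reproducible with spatial structure
  sim <- tiny_sim(seed = 3, n_markers = 200)
  p1 <- simulate_accession_panel(sim, seed = 4)
  p2 <- simulate_accession_panel(sim, seed = 4)
  expect_identical(p1, p2)
})
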