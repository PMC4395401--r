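# Marker/sample filtering: selfing expectations, Bhattacharyya distance,
# redundancy dedup, low-confidence and segregation filters, sample QC.

test_that("selfing expectations follow the transition exactly", {
  expect_equal(expected_ril_probs(2), c(pAA = 1/4, pAB = 1/2, pBB = 1/4))
  expect_identical(unname(expected_ril_probs(7)), c(63, 2, 63) / 128)
  # heterozygote share halves every generation
  for (t in 2:12) {
    expect_identical(expected_ril_probs(t)[["pAB"]], 0.5^(t - 1))
  }
  big <- expected_ril_probs(60)
  expect_equal(unname(big), c(0.5, 0, 0.5), tolerance = 1e-12)
  expect_error(expected_ril_probs(1), ">= 2")
})

test_that("Bhattacharyya distance matches its closed forms", {
  expect_equal(bhattacharyya_distance(c(1, 2), diag(2), c(1, 2), diag(2)), 0)
  # identity covariances: D = delta^2 / 8
  for (delta in c(0.5, 2, 5)) {
    expect_equal(
      bhattacharyya_distance(c(0, 0), diag(2), c(delta, 0), diag(2)),
      delta^2 / 8, tolerance = 1e-12
    )
  }
  seps <- vapply(seq(0.2, 4, by = 0.2), function(d) {
    bhattacharyya_distance(c(0, 0), diag(c(1, 2)), c(d, d), diag(c(2, 1)))
  }, 0)
  expect_true(all(diff(seps) > 0))
  expect_error(
    bhattacharyya_distance(c(0, 0), matrix(0, 2, 2), c(1, 1), matrix(0, 2, 2)),
    "singular"
  )
})

test_that("redundant markers collapse to the best-separated representative", {
  gt <- rbind(
    m1 = c("AA", "BB", "AA", "BB"),
    m2 = c("AA", "BB", "AA", "BB"),
    m3 = c("BB", "AA", "BB", "AA")
  )
  colnames(gt) <- sprintf("s%d", 1:4)
  calls <- calls_from_matrix(gt)
  sep_model <- function(d) {
    manual_model(list(c(0, 0), c(d, 0), c(2 * d, 0)))
  }
  # min pairwise separations: m1 -> 1.2, m2 -> 3.4 (identity covariances,
  # D = d^2/8, so d = sqrt(8 * D))
  models <- tibble::tibble(
    snp_id = c("m1", "m2", "m3"),
    gts_status = "GTS_perfect",
    model = list(sep_model(sqrt(8 * 1.2)), sep_model(sqrt(8 * 3.4)),
                 sep_model(sqrt(8 * 1)))
  )
  out <- dedup_redundant(calls, models)
  expect_setequal(out$marker_id, c("m2", "m3"))
  groups <- attr(out, "dedup_groups")
  expect_equal(groups$representative[groups$member == "m1"], "m2")
  # all-distinct input passes through
  out2 <- dedup_redundant(calls[c(1, 3), ], models)
  expect_equal(nrow(out2), 2)
  # tie in separation: lower marker id kept, invariant to row order
  models_tie <- models
  models_tie$model[[2]] <- models_tie$model[[1]]
  a <- dedup_redundant(calls, models_tie)
  b <- dedup_redundant(calls[c(3, 2, 1), ], models_tie)
  expect_true("m1" %in% a$marker_id)
  expect_setequal(a$marker_id, b$marker_id)
})

test_that("the low-confidence filter applies the median + 1 MAD rule", {
  build <- function(counts, n_samples = 12) {
    k <- length(counts)
    cf <- matrix(1, k, n_samples,
                 dimnames = list(sprintf("m%d", seq_len(k)), NULL))
    for (i in seq_len(k)) if (counts[i] > 0) cf[i, seq_len(counts[i])] <- 0.5
    colnames(cf) <- sprintf("s%d", 1:n_samples)
    gt <- matrix("AA", k, n_samples, dimnames = dimnames(cf))
    list(calls = calls_from_matrix(gt), conf = calls_from_matrix(cf))
  }
  # counts (0,0,0,0,10): median 0, MAD 0 -> only the heavy marker removed
  b1 <- build(c(0, 0, 0, 0, 10))
  out1 <- filter_low_confidence(b1$calls, b1$conf)
  expect_setequal(attr(out1, "removed"), "m5")
  # equal counts: nothing removed
  b2 <- build(c(3, 3, 3, 3))
  expect_length(attr(filter_low_confidence(b2$calls, b2$conf), "removed"), 0)
  # counts (1,2,3,4,5): median 3, MAD 1 -> count-5 marker removed
  b3 <- build(c(1, 2, 3, 4, 5))
  expect_setequal(attr(filter_low_confidence(b3$calls, b3$conf), "removed"), "m5")
})

test_that("segregation filtering matches hand-computed chi-square outcomes", {
  build_counts <- function(n_aa, n_ab, n_bb) {
    v <- c(rep("AA", n_aa), rep("AB", n_ab), rep("BB", n_bb))
    m <- matrix(v, 1, dimnames = list("m1", sprintf("s%d", seq_along(v))))
    calls_from_matrix(m)
  }
  # (60, 2, 58) at the F7 expectation: retained
  ok <- filter_segregation(build_counts(60, 2, 58), t = 7)
  expect_equal(nrow(ok), 1)
  # (110, 2, 8): AA-vs-BB chi2 ~ 88, removed at any cutoff
  bad <- filter_segregation(build_counts(110, 2, 8), t = 7)
  expect_equal(nrow(bad), 0)
  st <- attr(bad, "seg_tests")
  expect_lt(st$p_value, 1e-15)
  # single marker, p just below alpha: removed (Bonferroni with m = 1)
  single <- build_counts(71, 0, 49)
  p_hand <- pchisq(2 * (71 - 60)^2 / 60, df = 1, lower.tail = FALSE)
  expect_lt(p_hand, 0.05)
  expect_equal(nrow(filter_segregation(single, t = 7, alpha = 0.05)), 0)
})

test_that("family-wise error of the segregation filter is controlled under the null", {
  withr::with_seed(77, {
    reps <- 60
    m <- 800
    n <- 120
    p <- expected_ril_probs(7)
    hits <- 0
    for (r in seq_len(reps)) {
      counts <- rmultinom(m, n, p)
      pv <- rilmap:::segregation_pvalues(counts[1, ], counts[2, ], counts[3, ], 7)
      if (any(pv < 0.05 / m)) hits <- hits + 1
    }
    expect_lte(hits / reps, 0.07)
  })
})

test_that("sample QC drops heterozygous-excess, uninformative and fragmented samples", {
  gt <- cbind(
    good = c(rep("AA", 45), rep("BB", 45), rep("AB", 2), rep("NC", 8)),
    high_het = c(rep("AA", 35), rep("BB", 35), rep("AB", 25), rep("NC", 5)),
    uninformative = c(rep("AA", 5), rep("BB", 5), rep("AB", 5), rep("NC", 85))
  )
  rownames(gt) <- sprintf("m%03d", seq_len(nrow(gt)))
  calls <- calls_from_matrix(gt)
  out <- sample_qc(calls)
  expect_setequal(sample_cols(out), "good")
  rep_tbl <- attr(out, "sample_report")
  expect_true(rep_tbl$removed[rep_tbl$sample == "high_het"])
  expect_true(rep_tbl$removed[rep_tbl$sample == "uninformative"])
  # refined no-call region rule: more than 10 regions drops a sample
  nc_regions <- c(good = 2L, high_het = 0L, uninformative = 0L)
  nc_regions["good"] <- 11L
  out2 <- sample_qc(calls, het_max = 1, hom_min = 0, nc_regions = nc_regions)
  expect_false("good" %in% sample_cols(out2))
})

test_that("the filter chain reports counts per stage", {
  sim <- tiny_sim(seed = 30, n_markers = 50, n_rils = 60)
  sig <- simulate_array_signals(sim)
  proc <- process_signals(sig, spatial_filter = FALSE)
  mods <- fit_training_models(proc)
  gc0 <- call_genotypes(proc, mods, markers = sim$markers)
  filt <- filter_markers(gc0, t = 7)
  rep_tbl <- attr(filt, "filter_report")
  expect_equal(rep_tbl$stage,
               c("input", "dedup_redundant", "low_confidence", "segregation",
                 "sample_qc"))
  expect_true(all(diff(rep_tbl$markers) <= 0))
  expect_s3_class(attr(filt, "dedup_groups"), "data.frame")
})
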