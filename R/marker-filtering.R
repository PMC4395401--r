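# Marker and sample filtering ahead of map construction: redundancy
# deduplication (keeping the member with the most distinct signal
# clusters), low-confidence-call filtering (median + 1 MAD rule),
# segregation goodness-of-fit against the F_t selfing expectation, and
# sample-level quality control.

#' Expected genotype proportions in a selfed F_t RIL population
#'
#' Iterates the per-locus selfing transition (AB -> 1/4 AA, 1/2 AB,
#' 1/4 BB; homozygotes breed true) t - 1 times from a pure heterozygote,
#' so the heterozygote share is (1/2)^(t-1). At t = 7 this gives the
#' familiar 63/128, 2/128, 63/128.
#'
#' @param t Selfing-generation index (F1 is t = 1); must be >= 2.
#' @return Named numeric vector (pAA, pAB, pBB) summing to 1.
#' @examples
#' expected_ril_probs(7) * 128
#' @export
expected_ril_probs <- function(t) {
  if (t < 2) abort("generation t must be >= 2")
  p <- c(pAA = 0, pAB = 1, pBB = 0)
  for (i in seq_len(t - 1)) {
    p <- c(
      pAA = p[["pAA"]] + p[["pAB"]] / 4,
      pAB = p[["pAB"]] / 2,
      pBB = p[["pBB"]] + p[["pAB"]] / 4
    )
  }
  p
}

#' Bhattacharyya distance between two Gaussian clusters
#'
#' `D = 1/8 (mu1-mu2)' S^-1 (mu1-mu2) + 1/2 ln(det S / sqrt(det S1 det S2))`
#' with `S = (S1 + S2)/2`.
#'
#' @param mean1,mean2 Cluster mean vectors.
#' @param cov1,cov2 Positive-definite covariance matrices.
#' @return Nonnegative distance (0 for identical Gaussians).
#' @export
bhattacharyya_distance <- function(mean1, cov1, mean2, cov2) {
  s <- (cov1 + cov2) / 2
  ds <- det(s)
  if (!is.finite(ds) || ds <= 0) abort("singular pooled covariance; regularize upstream")
  delta <- mean1 - mean2
  as.numeric(
    t(delta) %*% solve(s, delta) / 8 +
      log(ds / sqrt(det(cov1) * det(cov2))) / 2
  )
}

# smallest pairwise Bhattacharyya distance among a model's three clusters
min_cluster_separation <- function(model) {
  if (is.null(model$clusters)) return(-Inf)
  cl <- model$clusters
  pairs <- utils::combn(3, 2)
  min(apply(pairs, 2, function(p) {
    bhattacharyya_distance(cl[[p[1]]]$mean, cl[[p[1]]]$cov,
                           cl[[p[2]]]$mean, cl[[p[2]]]$cov)
  }))
}

#' Collapse markers with identical genotype-call vectors
#'
#' Markers whose calls agree exactly across all samples (including the NC
#' pattern) form a redundancy group; the member whose training clusters
#' are best separated (largest minimum pairwise Bhattacharyya distance)
#' represents the group, ties broken by lower marker id.
#'
#' @param calls A calls table.
#' @param models A `training_models` tibble supplying cluster geometry;
#'   markers without a model get separation -Inf.
#' @return The reduced calls table, with a `dedup_groups` attribute
#'   (tibble representative / member) for later bin expansion.
#' @export
dedup_redundant <- function(calls, models = NULL) {
  assert_calls(calls)
  gt <- calls_matrix(calls)
  key <- apply(gt, 1, paste, collapse = "\r")
  sep <- rep(-Inf, nrow(gt))
  if (!is.null(models)) {
    idx <- match(rownames(gt), models$snp_id)
    sep[!is.na(idx)] <- vapply(models$model[idx[!is.na(idx)]],
                               min_cluster_separation, 0)
  }
  d <- tibble(marker_id = rownames(gt), key = key, sep = sep) |>
    group_by(.data$key) |>
    mutate(representative = .data$marker_id[order(-.data$sep, .data$marker_id)][1]) |>
    ungroup()
  out <- calls[calls$marker_id %in% unique(d$representative), ]
  attr(out, "dedup_groups") <- d |>
    select("representative", member = "marker_id") |>
    arrange(.data$representative, .data$member)
  out
}

#' Filter markers with an excess of low-confidence calls
#'
#' A call with confidence <= `conf_cutoff` is low-confidence. Markers
#' whose low-confidence count exceeds the across-marker median by more
#' than one (unscaled) median absolute deviation are removed.
#'
#' @param calls,confidence Aligned calls and confidence tables.
#' @param conf_cutoff Low-confidence threshold.
#' @return Filtered calls table; removed ids in attribute `removed`.
#' @export
filter_low_confidence <- function(calls, confidence, conf_cutoff = 0.6) {
  assert_calls(calls)
  cf <- calls_matrix(confidence)
  cf <- cf[match(calls$marker_id, rownames(cf)), , drop = FALSE]
  n_low <- rowSums(cf <= conf_cutoff, na.rm = TRUE)
  med <- median(n_low)
  mad_raw <- median(abs(n_low - med))
  drop <- n_low > med + mad_raw
  out <- calls[!drop, ]
  attr(out, "removed") <- calls$marker_id[drop]
  out
}

# chi-square goodness-of-fit p-values against the F_t expectation.
# The AB category enters the test only when its expected count is at least
# 5 (Cochran validity rule); below that the test compares the two
# homozygote classes against equal frequencies, conditioning on
# homozygous calls.
segregation_pvalues <- function(n_aa, n_ab, n_bb, t) {
  p <- expected_ril_probs(t)
  n <- n_aa + n_ab + n_bb
  p_three <- function(i) {
    e <- n[i] * p
    obs <- c(n_aa[i], n_ab[i], n_bb[i])
    pchisq(sum((obs - e)^2 / e), df = 2, lower.tail = FALSE)
  }
  p_two <- function(i) {
    nh <- n_aa[i] + n_bb[i]
    if (nh == 0) return(NA_real_)
    stat <- (n_aa[i] - nh / 2)^2 / (nh / 2) + (n_bb[i] - nh / 2)^2 / (nh / 2)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(NA_real_)
    if (n[i] * p[["pAB"]] >= 5) p_three(i) else p_two(i)
  }, 0)
}

#' Filter markers deviating from the expected segregation ratio
#'
#' Chi-square goodness-of-fit of each marker's (AA, AB, BB) counts against
#' the F_t selfing expectation, with Bonferroni correction over the tested
#' markers; NC calls are excluded from the counts. When the expected AB
#' count is below 5 the heterozygote class is dropped and the test
#' compares AA against BB.
#'
#' @param calls A calls table.
#' @param t Selfing-generation index.
#' @param alpha Family-wise significance level before Bonferroni division.
#' @return Filtered calls table; attribute `seg_tests` holds the per-marker
#'   counts and p-values.
#' @export
filter_segregation <- function(calls, t = 7, alpha = 0.05) {
  assert_calls(calls)
  gt <- calls_matrix(calls)
  n_aa <- rowSums(gt == "AA")
  n_ab <- rowSums(gt == "AB")
  n_bb <- rowSums(gt == "BB")
  testable <- (n_aa + n_ab + n_bb) >= 2
  pv <- rep(NA_real_, nrow(gt))
  pv[testable] <- segregation_pvalues(n_aa[testable], n_ab[testable],
                                      n_bb[testable], t)
  m <- sum(testable)
  drop <- !is.na(pv) & pv < alpha / m
  out <- calls[!drop, ]
  attr(out, "seg_tests") <- tibble(
    marker_id = calls$marker_id, n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
    p_value = pv, removed = drop
  )
  out
}

#' Sample-level quality control
#'
#' Drops samples whose heterozygous-call proportion exceeds `het_max`,
#' whose homozygous-call proportion falls below `hom_min` (uninformative),
#' or - when refined no-call region counts are supplied - with more than
#' `max_nc_regions` no-call regions. NC calls are excluded from proportion
#' denominators.
#'
#' @param calls A calls table.
#' @param het_max Maximum tolerated heterozygous proportion.
#' @param hom_min Minimum required homozygous proportion (of all calls).
#' @param nc_regions Optional named integer vector of no-call region
#'   counts per sample (see [count_nc_regions()]).
#' @param max_nc_regions Region-count cutoff.
#' @return Calls table restricted to retained samples; attribute
#'   `sample_report` details every sample's metrics and fate.
#' @export
sample_qc <- function(calls, het_max = 0.2, hom_min = 0.15,
                      nc_regions = NULL, max_nc_regions = 10) {
  assert_calls(calls)
  gt <- calls_matrix(calls)
  n_called <- colSums(gt != "NC")
  het <- colSums(gt == "AB") / pmax(n_called, 1)
  hom <- colSums(gt == "AA" | gt == "BB") / nrow(gt)
  regions <- if (is.null(nc_regions)) rep(NA_integer_, ncol(gt)) else
    nc_regions[colnames(gt)]
  drop <- het > het_max | hom < hom_min |
    (!is.na(regions) & regions > max_nc_regions)
  report <- tibble(
    sample = colnames(gt), het_prop = het, hom_prop = hom,
    nc_regions = as.integer(regions), removed = unname(drop)
  )
  keep_cols <- c(marker_meta_cols(calls), colnames(gt)[!drop])
  out <- calls[, keep_cols]
  attr(out, "sample_report") <- report
  out
}

#' Run the full pre-map marker/sample filter chain
#'
#' Order: redundancy dedup, low-confidence filter, segregation filter,
#' sample QC - the narrative order of a linkage-map build.
#'
#' @param genotypes A `genotype_calls` object (or a calls table, in which
#'   case `confidence`/`models` may be supplied separately).
#' @param confidence,models See [filter_low_confidence()],
#'   [dedup_redundant()].
#' @param t,alpha,conf_cutoff,het_max,hom_min Stage parameters.
#' @return Filtered calls table with attributes `dedup_groups`,
#'   `seg_tests`, `sample_report` and a `filter_report` tibble of
#'   per-stage marker/sample counts.
#' @export
filter_markers <- function(genotypes, confidence = NULL, models = NULL,
                           t = 7, alpha = 0.05, conf_cutoff = 0.6,
                           het_max = 0.2, hom_min = 0.15) {
  if (inherits(genotypes, "genotype_calls")) {
    confidence <- confidence %||% genotypes$confidence
    models <- models %||% genotypes$models
    calls <- genotypes$calls
  } else {
    calls <- genotypes
  }
  n0 <- nrow(calls)
  s0 <- length(sample_cols(calls))
  dd <- dedup_redundant(calls, models)
  lc <- if (!is.null(confidence)) {
    filter_low_confidence(dd, confidence, conf_cutoff = conf_cutoff)
  } else dd
  sg <- filter_segregation(lc, t = t, alpha = alpha)
  qc <- sample_qc(sg, het_max = het_max, hom_min = hom_min)
  report <- tibble(
    stage = c("input", "dedup_redundant", "low_confidence", "segregation",
              "sample_qc"),
    markers = c(n0, nrow(dd), nrow(lc), nrow(sg), nrow(qc)),
    samples = c(s0, s0, s0, s0, length(sample_cols(qc)))
  )
  attr(qc, "dedup_groups") <- attr(dd, "dedup_groups")
  attr(qc, "seg_tests") <- attr(sg, "seg_tests")
  attr(qc, "filter_report") <- report
  qc
}
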