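# Training-set based genotype calling.
#
# Per SNP, the 16 parent/F1 hybridizations (6 expected AA, 5 AB, 5 BB) are
# partitioned by k-means into three clusters; clusters inherit the expected
# label of the majority of their members. A SNP whose training points all
# land in the cluster of their expected label has a perfect training set
# (GTS); exactly one disagreement is tolerated (GTS one-off); anything else
# is rejected. Test samples are assigned by Mahalanobis distance with
# confidence d1/(d1+d0).

#' Fit the three-cluster training model for one SNP
#'
#' K-means (k = 3) with deterministic initialization from the
#' expected-label group means, followed by per-cluster mean/covariance
#' estimation with shrinkage toward the pooled diagonal covariance
#' (needed because clusters hold only 5-6 points).
#'
#' @param points Numeric matrix (n x 2) of (signal_a, signal_b) training
#'   coordinates; rows with NA are treated as masked.
#' @param expected Character vector of expected labels (AA/AB/BB) parallel
#'   to `points`.
#' @param lambda Shrinkage weight toward the pooled diagonal covariance.
#' @return A list of class `training_model`: cluster means/covariances and
#'   labels, per-point assignments, `gts_status` (GTS_perfect /
#'   GTS_one_off / rejected), `miscluster_count`, and a `reason` when
#'   rejected.
#' @export
fit_training_model <- function(points, expected, lambda = 0.5) {
  stopifnot(ncol(points) == 2, nrow(points) == length(expected))
  ok <- complete.cases(points)
  pts <- points[ok, , drop = FALSE]
  exp_ok <- expected[ok]
  reject <- function(reason) {
    structure(
      list(clusters = NULL, assigned = NULL, expected = expected,
           gts_status = "rejected", miscluster_count = NA_integer_,
           reason = reason),
      class = "training_model"
    )
  }
  counts <- table(factor(exp_ok, levels = c("AA", "AB", "BB")))
  if (any(counts < 3)) return(reject("fewer than 3 points for an expected label"))

  init <- do.call(rbind, lapply(c("AA", "AB", "BB"), function(l) {
    colMeans(pts[exp_ok == l, , drop = FALSE])
  }))
  if (anyDuplicated(init) > 0) return(reject("degenerate initial centers"))
  km <- tryCatch(
    kmeans(pts, centers = init, iter.max = 100L),
    error = function(e) NULL
  )
  if (is.null(km)) return(reject("k-means failed"))

  # clusters take the majority expected label of their members
  lab <- character(3)
  for (c_i in 1:3) {
    members <- exp_ok[km$cluster == c_i]
    if (length(members) == 0) return(reject("empty cluster"))
    tab <- sort(table(members), decreasing = TRUE)
    lab[c_i] <- names(tab)[1]
  }
  if (anyDuplicated(lab) > 0) return(reject("two clusters share a majority label"))

  # pooled diagonal covariance for shrinkage
  centered <- pts - km$centers[km$cluster, , drop = FALSE]
  pool <- diag(apply(centered, 2, function(x) sum(x^2) / max(1, length(x) - 3)), 2)
  clusters <- lapply(1:3, function(c_i) {
    m <- pts[km$cluster == c_i, , drop = FALSE]
    s <- if (nrow(m) >= 2) cov(m) else pool
    sigma <- (1 - lambda) * s + lambda * pool
    sigma <- sigma + diag(1e-6 * max(mean(diag(sigma)), 1e-6), 2)
    list(label = lab[c_i], mean = km$centers[c_i, ], cov = sigma)
  })
  names(clusters) <- lab

  assigned <- rep(NA_character_, length(expected))
  assigned[ok] <- lab[km$cluster]
  mis <- sum(assigned[ok] != exp_ok)
  structure(
    list(clusters = clusters, assigned = assigned, expected = expected,
         gts_status = if (mis == 0) "GTS_perfect" else if (mis == 1) "GTS_one_off" else "rejected",
         miscluster_count = as.integer(mis),
         reason = if (mis > 1) "more than one misclustered training signal" else NA_character_),
    class = "training_model"
  )
}

#' Training-set status of a fitted model
#'
#' `GTS_perfect` when every training point clusters with its expected
#' label, `GTS_one_off` when exactly one disagrees, `rejected` otherwise.
#'
#' @param model A `training_model`.
#' @return One of "GTS_perfect", "GTS_one_off", "rejected".
#' @export
classify_gts <- function(model) {
  stopifnot(inherits(model, "training_model"))
  model$gts_status
}

#' Fit training models for every SNP of a summarized signal table
#'
#' @param summarized A `summarized_signals` tibble from
#'   [process_signals()].
#' @param training Training design (sample, expected_call); defaults to
#'   the table's attribute.
#' @param lambda Shrinkage weight, see [fit_training_model()].
#' @return Tibble (snp_id, gts_status, miscluster_count, reason, model)
#'   with the fitted `training_model` objects in the `model` list-column;
#'   class `training_models`.
#' @export
fit_training_models <- function(summarized, training = attr(summarized, "training"),
                                lambda = 0.5) {
  if (is.null(training)) abort("no training design found; pass `training`")
  tr <- summarized |>
    inner_join(training, by = "sample") |>
    arrange(match(.data$sample, training$sample))
  by_snp <- split(tr, tr$snp_id)
  out <- purrr::map_dfr(by_snp, function(d) {
    m <- fit_training_model(cbind(d$signal_a, d$signal_b), d$expected_call,
                            lambda = lambda)
    tibble(
      snp_id = d$snp_id[1],
      gts_status = m$gts_status,
      miscluster_count = m$miscluster_count,
      reason = m$reason,
      model = list(m)
    )
  })
  out <- out[match(unique(summarized$snp_id), out$snp_id), ]
  class(out) <- c("training_models", class(out))
  out
}

mahal_distances <- function(pts, model) {
  matrix(vapply(model$clusters, function(cl) {
    sqrt(stats::mahalanobis(pts, cl$mean, cl$cov))
  }, numeric(nrow(pts))), nrow = nrow(pts))
}

#' Call the genotype of a single signal point
#'
#' `d0` is the Mahalanobis distance to the nearest cluster (the tentative
#' call), `d1` the distance to the nearest remaining cluster; the call's
#' confidence is `d1 / (d1 + d0)` and falls back to no-call (NC) when it
#' does not exceed `nc_threshold`.
#'
#' @param point Numeric length-2 vector (signal_a, signal_b).
#' @param model A non-rejected `training_model`.
#' @param nc_threshold Confidence cutoff for no-calls.
#' @return Tibble (call, confidence, d0, d1).
#' @export
call_genotype <- function(point, model, nc_threshold = 0.6) {
  stopifnot(inherits(model, "training_model"))
  if (model$gts_status == "rejected") abort("cannot call from a rejected model")
  if (anyNA(point)) {
    return(tibble(call = "NC", confidence = 0, d0 = NA_real_, d1 = NA_real_))
  }
  d <- setNames(mahal_distances(matrix(point, 1), model)[1, ],
                names(model$clusters))
  o <- order(d)
  d0 <- d[o[1]]
  d1 <- d[o[2]]
  conf <- unname(if (d0 + d1 > 0) d1 / (d0 + d1) else 0.5)
  tibble(
    call = if (conf > nc_threshold) names(model$clusters)[o[1]] else "NC",
    confidence = conf, d0 = unname(d0), d1 = unname(d1)
  )
}

#' Call genotypes for all samples from fitted training models
#'
#' Applies [call_genotype()] per SNP to every non-training sample;
#' rejected SNPs are dropped.
#'
#' @param summarized A `summarized_signals` tibble.
#' @param models A `training_models` tibble from [fit_training_models()].
#' @param markers Optional marker metadata (marker_id, chrom, pos_mb, cm)
#'   joined onto the output; `marker_id` must match `snp_id`.
#' @param nc_threshold Confidence cutoff for no-calls.
#' @return List of class `genotype_calls` with elements `calls` and
#'   `confidence` (calls tables: marker metadata + one column per sample)
#'   and `models`.
#' @export
call_genotypes <- function(summarized, models, markers = NULL,
                           nc_threshold = 0.6) {
  training <- attr(summarized, "training")
  test <- summarized
  if (!is.null(training)) test <- filter(test, !.data$sample %in% training$sample)
  keep <- models$snp_id[models$gts_status != "rejected"]
  test <- filter(test, .data$snp_id %in% keep)
  samples <- unique(test$sample)

  by_snp <- split(test, factor(test$snp_id, levels = unique(test$snp_id)))
  model_of <- setNames(models$model, models$snp_id)
  res <- purrr::map(by_snp, function(d) {
    m <- model_of[[d$snp_id[1]]]
    pts <- cbind(d$signal_a, d$signal_b)
    call <- rep("NC", nrow(d))
    conf <- rep(0, nrow(d))
    ok <- complete.cases(pts)
    if (any(ok)) {
      dm <- mahal_distances(pts[ok, , drop = FALSE], m)
      o1 <- max.col(-dm, ties.method = "first")
      d0 <- dm[cbind(seq_len(nrow(dm)), o1)]
      dm[cbind(seq_len(nrow(dm)), o1)] <- Inf
      o2 <- max.col(-dm, ties.method = "first")
      d1 <- dm[cbind(seq_len(nrow(dm)), o2)]
      cf <- ifelse(d0 + d1 > 0, d1 / (d0 + d1), 0.5)
      call[ok] <- ifelse(cf > nc_threshold, names(m$clusters)[o1], "NC")
      conf[ok] <- cf
    }
    list(call = setNames(call, d$sample), conf = setNames(conf, d$sample))
  })

  gt <- t(vapply(res, function(x) x$call[samples], character(length(samples))))
  cf <- t(vapply(res, function(x) x$conf[samples], numeric(length(samples))))
  colnames(gt) <- colnames(cf) <- samples
  meta <- tibble(marker_id = names(res))
  if (!is.null(markers)) {
    meta <- left_join(meta, markers, by = "marker_id")
  }
  out <- list(
    calls = calls_table(meta, gt),
    confidence = calls_table(meta, cf),
    models = models
  )
  class(out) <- "genotype_calls"
  out
}

#' @export
print.genotype_calls <- function(x, ...) {
  gt <- calls_matrix(x$calls)
  cat(sprintf("<genotype_calls> %d markers x %d samples (%.2f%% NC)\n",
              nrow(gt), ncol(gt), 100 * mean(gt == "NC")))
  invisible(x)
}
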