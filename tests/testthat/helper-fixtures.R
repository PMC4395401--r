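# Shared fixture builders; everything is generated in code at test time.

tiny_sim <- function(seed = 1, n_markers = 40, n_rils = 30, n_chromosomes = 1,
                     chrom_length_cM = 80, chrom_length_Mb = 20, ...) {
  simulate_ril_population(sim_config(
    n_chromosomes = n_chromosomes, n_markers = n_markers,
    chrom_length_cM = chrom_length_cM, chrom_length_Mb = chrom_length_Mb,
    n_rils = n_rils, seed = seed, ...
  ))
}

# calls table from a character matrix
calls_from_matrix <- function(mat, chrom = 1L, pos_mb = seq_len(nrow(mat))) {
  meta <- tibble::tibble(
    marker_id = rownames(mat) %||% sprintf("mk%03d", seq_len(nrow(mat))),
    chrom = chrom, pos_mb = pos_mb
  )
  rownames(mat) <- meta$marker_id
  dplyr::bind_cols(meta, tibble::as_tibble(mat, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built training model with given cluster means/covariances
manual_model <- function(means, covs = NULL, labels = c("AA", "AB", "BB")) {
  covs <- covs %||% replicate(3, diag(2), simplify = FALSE)
  clusters <- lapply(1:3, function(i) {
    list(label = labels[i], mean = means[[i]], cov = covs[[i]])
  })
  names(clusters) <- labels
  structure(
    list(clusters = clusters, assigned = labels, expected = labels,
         gts_status = "GTS_perfect", miscluster_count = 0L, reason = NA_character_),
    class = "training_model"
  )
}

# three Gaussian blobs in the 6/5/5 training design
training_blobs <- function(centers, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- c(6, 5, 5)
    pts <- do.call(rbind, lapply(1:3, function(i) {
      cbind(rnorm(n[i], centers[i, 1], sd), rnorm(n[i], centers[i, 2], sd))
    }))
    list(points = pts, expected = rep(c("AA", "AB", "BB"), n))
  })
}
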