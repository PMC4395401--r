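# Two-channel hybridization signal simulator.
#
# Each SNP is interrogated by four probes: two per allele (A and B), one
# detecting the forward and one the reverse strand. A sample's pair of
# channel intensities is centered on the cluster center of its genotype
# (rows AA/AB/BB of config$cluster_centers): allele-A probes emit around
# the A-signal coordinate, allele-B probes around the B-signal coordinate.
# Noise is multiplicative (Gaussian on log2 scale), plus a per-probe
# affinity offset shared across arrays and a per-array brightness offset -
# the artifacts the preprocessing stages are designed to remove.

training_design <- function() {
  tibble(
    sample = c(
      sprintf("P1_rep%d", 1:6),
      sprintf("F1_rep%d", 1:5),
      sprintf("P2_rep%d", 1:5)
    ),
    expected_call = c(rep("AA", 6), rep("AB", 5), rep("BB", 5))
  )
}

#' Simulate array intensities for a RIL population plus its training set
#'
#' Emits the long-format signal tensor for every probe x sample
#' combination: the 16 training hybridizations (6 parent-A arrays expected
#' AA, 5 F1 arrays expected AB, 5 parent-B arrays expected BB) followed by
#' the RIL arrays. A fraction `miscluster_rate` of training signals is
#' drawn from a wrong cluster; `missing_rate` intensities are NA; with
#' probability `spatial_defect_rate` an array carries one 3x3 blob of
#' 5x-inflated intensities on the probe grid.
#'
#' @param sim A `ril_sim` object (or a calls table with no NC).
#' @param config A [sim_config()]; defaults to the simulation's own.
#' @return A tibble (snp_id, allele, strand, sample, intensity) of class
#'   `signal_tensor`, with attributes:
#'   * `layout`: probe grid coordinates (probe_id, row, col),
#'   * `training`: the training design (sample, expected_call),
#'   * `truth`: list of injected artifacts (misclustered training points,
#'     defect-affected probes).
#' @export
simulate_array_signals <- function(sim, config = NULL) {
  if (inherits(sim, "ril_sim")) {
    config <- config %||% sim$config
    calls <- sim$calls
  } else {
    calls <- assert_calls(sim)
    if (is.null(config)) abort("config must be supplied with a bare calls table")
  }
  gt <- calls_matrix(calls)
  snp_ids <- rownames(gt)
  n_snp <- nrow(gt)
  tr <- training_design()
  samples <- c(tr$sample, colnames(gt))
  n_s <- length(samples)

  with_seed(child_seed(config$seed, "signals"), {
    # genotype index per (snp, sample): training expectation then RIL calls
    g <- cbind(
      matrix(rep(match(tr$expected_call, GT_LEVELS), each = n_snp), n_snp),
      matrix(match(gt, GT_LEVELS), n_snp)
    )
    nc_truth <- which(g == 4L, arr.ind = TRUE)
    if (nrow(nc_truth) > 0) {
      # NC inputs carry no genotype: draw from a random cluster, flag in truth
      g[g == 4L] <- sample.int(3L, nrow(nc_truth), replace = TRUE)
    }
    # miscluster training signals
    tr_block <- g[, seq_len(nrow(tr)), drop = FALSE]
    flip <- which(matrix(runif(length(tr_block)) < config$miscluster_rate,
                         nrow(tr_block)), arr.ind = TRUE)
    if (nrow(flip) > 0) {
      for (i in seq_len(nrow(flip))) {
        old <- tr_block[flip[i, 1], flip[i, 2]]
        tr_block[flip[i, 1], flip[i, 2]] <- sample(setdiff(1:3, old), 1L)
      }
      g[, seq_len(nrow(tr))] <- tr_block
    }

    l2c <- log2(config$cluster_centers)
    # probe rows per SNP: (A,F), (A,R), (B,F), (B,R)
    probe_allele <- rep(c("A", "A", "B", "B"), times = n_snp)
    probe_strand <- rep(c("F", "R", "F", "R"), times = n_snp)
    probe_snp <- rep(snp_ids, each = 4L)
    probe_id <- paste(probe_snp, probe_allele, probe_strand, sep = "|")
    n_p <- length(probe_id)

    base_a <- matrix(l2c[g, 1], n_snp, n_s)  # log2 A-channel center
    base_b <- matrix(l2c[g, 2], n_snp, n_s)
    idx <- rep(seq_len(n_snp), each = 4L)
    base <- matrix(0, n_p, n_s)
    a_rows <- probe_allele == "A"
    base[a_rows, ] <- base_a[idx[a_rows], ]
    base[!a_rows, ] <- base_b[idx[!a_rows], ]

    probe_eff <- rnorm(n_p, 0, config$probe_effect_sd)
    array_eff <- rnorm(n_s, 0, config$array_effect_sd)
    noise <- matrix(rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s)
    l2 <- base + probe_eff + rep(array_eff, each = n_p) + noise

    # probe grid layout (randomized placement, as on a physical slide)
    nr <- ceiling(sqrt(n_p))
    ncg <- ceiling(n_p / nr)
    slot <- sample.int(nr * ncg, n_p)
    layout <- tibble(
      probe_id = probe_id,
      row = ((slot - 1L) %% nr) + 1L,
      col = ((slot - 1L) %/% nr) + 1L
    )

    defects <- tibble(sample = character(), probe_id = character())
    if (config$spatial_defect_rate > 0) {
      hit <- runif(n_s) < config$spatial_defect_rate
      for (j in which(hit)) {
        r0 <- sample.int(nr - 2L, 1L) + 1L
        c0 <- sample.int(ncg - 2L, 1L) + 1L
        in_blob <- abs(layout$row - r0) <= 1L & abs(layout$col - c0) <= 1L
        l2[in_blob, j] <- l2[in_blob, j] + log2(5)
        defects <- bind_rows(defects,
                             tibble(sample = samples[j], probe_id = probe_id[in_blob]))
      }
    }

    intensity <- 2^l2
    if (config$missing_rate > 0) {
      intensity[runif(n_p * n_s) < config$missing_rate] <- NA_real_
    }

    out <- tibble(
      snp_id = rep(probe_snp, times = n_s),
      allele = rep(probe_allele, times = n_s),
      strand = rep(probe_strand, times = n_s),
      sample = rep(samples, each = n_p),
      intensity = as.vector(intensity)
    )
    attr(out, "layout") <- layout
    attr(out, "training") <- tr
    attr(out, "truth") <- list(
      miscluster = if (nrow(flip) > 0) {
        tibble(snp_id = snp_ids[flip[, 1]], sample = tr$sample[flip[, 2]])
      } else {
        tibble(snp_id = character(), sample = character())
      },
      nc_inputs = if (nrow(nc_truth) > 0) {
        tibble(snp_id = snp_ids[nc_truth[, 1]], sample = samples[nc_truth[, 2]])
      } else {
        tibble(snp_id = character(), sample = character())
      },
      defects = defects
    )
    class(out) <- c("signal_tensor", class(out))
    out
  })
}
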