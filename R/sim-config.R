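#' Simulation configuration for a RIL genotyping-array study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the cucumber 9930 x Gy14 study design that motivates the
#' package: seven chromosomes with the real linkage-group genetic lengths,
#' physical lengths close to the assembled chromosome sizes, roughly 2,000
#' markers genome-wide, 120 RILs at selfing generation t = 7 (so the
#' expected genotype proportions are 63/128 AA, 2/128 AB, 63/128 BB), and a
#' parents/F1 training design of 6 + 5 + 5 hybridizations.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cM Genetic length per chromosome (cM); recycled.
#' @param chrom_length_Mb Physical length per chromosome (Mb); recycled.
#' @param n_markers Markers per chromosome; recycled. The default places
#'   about 2,000 markers proportionally to physical length.
#' @param n_rils Number of RIL samples.
#' @param generations Selfing-generation index t; the F1 is t = 1, so t = 7
#'   corresponds to an F7 RIL (F7:8 seed).
#' @param cluster_centers 3 x 2 numeric matrix of linear-scale hybridization
#'   intensities, rows AA/AB/BB, columns (A-signal, B-signal). Signals are
#'   generated on the positive linear scale and log2-transformed by the
#'   preprocessing stage.
#' @param noise_sd Gaussian standard deviation of the per-axis signal noise
#'   on the log2 scale (multiplicative noise on the linear scale).
#' @param probe_effect_sd SD of a per-probe affinity offset (log2 scale),
#'   shared across arrays; removed by per-probe centering. The default is
#'   large relative to the allele contrast, as on real hybridization
#'   arrays, which keeps whole-array intensity distributions comparable
#'   between genotype-homogeneous (parent/F1) and segregating arrays and
#'   so makes between-array quantile normalization safe.
#' @param array_effect_sd SD of a per-array brightness offset (log2 scale);
#'   removed by quantile normalization / median polish.
#' @param miscluster_rate Probability that a training hybridization signal
#'   for a SNP is drawn from a wrong cluster. The default 0.0067 makes the
#'   expected share of one-misclustered training sets among accepted SNPs
#'   about 9.8%, the share observed on the real array.
#' @param missing_rate Probability that an individual probe intensity is
#'   missing.
#' @param spatial_defect_rate Probability that an array carries one 3 x 3
#'   high-intensity defect blob (scratch/bubble surrogate).
#' @param sdr_spec Optional segregation-distortion specification:
#'   `list(chrom =, start_mb =, end_mb =, weight =)` with viability weight
#'   > 1 favoring the A allele at the interval's central marker.
#' @param hotspots Optional recombination hotspot list; each element
#'   `list(chrom =, start_mb =, end_mb =, fold =)` multiplies the local
#'   cM/Mb rate (total chromosome genetic length is preserved).
#' @param seed Integer seed driving every random draw.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, n_markers = 50, n_rils = 20, seed = 1)
#' cfg$generations
#' @export
sim_config <- function(n_chromosomes = 7,
                       chrom_length_cM = c(72.5, 87.1, 96.9, 104.7, 88.7, 87.0, 61.8),
                       chrom_length_Mb = c(28.6, 23.3, 39.7, 23.6, 28.1, 29.0, 19.2),
                       n_markers = NULL,
                       n_rils = 120,
                       generations = 7,
                       cluster_centers = rbind(
                         AA = c(2048, 128),
                         AB = c(724, 724),
                         BB = c(128, 2048)
                       ),
                       noise_sd = 0.35,
                       probe_effect_sd = 3,
                       array_effect_sd = 0.2,
                       miscluster_rate = 0.0067,
                       missing_rate = 0.001,
                       spatial_defect_rate = 0,
                       sdr_spec = NULL,
                       hotspots = NULL,
                       seed = 1L) {
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  chrom_length_Mb <- rep_len(chrom_length_Mb, n_chromosomes)
  if (is.null(n_markers)) {
    n_markers <- pmax(2L, round(2000 * chrom_length_Mb / sum(chrom_length_Mb)))
  }
  n_markers <- rep_len(as.integer(n_markers), n_chromosomes)

  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = chrom_length_cM,
    chrom_length_Mb = chrom_length_Mb,
    n_markers = n_markers,
    n_rils = as.integer(n_rils),
    generations = as.integer(generations),
    cluster_centers = cluster_centers,
    noise_sd = noise_sd,
    probe_effect_sd = probe_effect_sd,
    array_effect_sd = array_effect_sd,
    miscluster_rate = miscluster_rate,
    missing_rate = missing_rate,
    spatial_defect_rate = spatial_defect_rate,
    sdr_spec = sdr_spec,
    hotspots = hotspots,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1) abort("n_chromosomes must be >= 1")
  if (any(cfg$n_markers < 1)) abort("n_markers must be positive")
  if (cfg$n_rils < 1) abort("n_rils must be positive")
  if (cfg$generations < 2) abort("generations (t) must be >= 2")
  if (any(cfg$chrom_length_cM < 0) || any(cfg$chrom_length_Mb <= 0)) {
    abort("chromosome lengths must be positive (genetic length may be 0)")
  }
  rates <- c(cfg$miscluster_rate, cfg$missing_rate, cfg$spatial_defect_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  cc <- cfg$cluster_centers
  if (!is.matrix(cc) || nrow(cc) != 3 || ncol(cc) != 2) {
    abort("cluster_centers must be a 3 x 2 matrix (rows AA/AB/BB)")
  }
  if (any(cc <= 0)) abort("cluster_centers must be positive intensities")
  d <- as.matrix(stats::dist(cc))
  if (any(d[upper.tri(d)] == 0)) abort("cluster centers must be pairwise distinct")
  if (!is.null(cfg$sdr_spec)) {
    s <- cfg$sdr_spec
    if (is.null(s$weight) || s$weight <= 0) abort("sdr_spec weight must be > 0")
    if (is.null(s$chrom) || s$chrom > cfg$n_chromosomes) {
      abort("sdr_spec interval must lie on a simulated chromosome")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d chromosome(s), %d markers, %d RILs at generation t=%d (seed %d)\n",
    x$n_chromosomes, sum(x$n_markers), x$n_rils, x$generations, x$seed
  ))
  cat(sprintf(
    "  noise_sd %.3g, miscluster %.3g, missing %.3g, defects %.3g\n",
    x$noise_sd, x$miscluster_rate, x$missing_rate, x$spatial_defect_rate
  ))
  if (!is.null(x$sdr_spec)) {
    cat(sprintf(
      "  SDR: chrom %s %.3g-%.3g Mb, weight %.3g\n",
      x$sdr_spec$chrom, x$sdr_spec$start_mb, x$sdr_spec$end_mb, x$sdr_spec$weight
    ))
  }
  invisible(x)
}
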