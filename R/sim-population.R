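# RIL population simulator.
#
# Lines are represented as pairs of haplotypes per chromosome (0 = parent-A
# allele, 1 = parent-B allele). Meiosis follows the Haldane model: the
# crossover count on a chromosome is Poisson with mean equal to its genetic
# length in Morgans and crossover positions are uniform on the cM scale
# (no interference). Selfing starts from a single fully heterozygous F1
# (t = 1) and iterates t - 1 times, so heterozygosity decays as (1/2)^(t-1).

#' Marker scaffold for a simulation configuration
#'
#' Draws marker physical positions uniformly per chromosome and converts
#' them to genetic positions by integrating the (possibly hotspot-modified)
#' local recombination rate, scaled so each chromosome attains its
#' configured genetic length.
#'
#' @param config A [sim_config()].
#' @return Tibble with marker_id, chrom, pos_mb, cm (physical positions
#'   strictly increasing, genetic positions nondecreasing per chromosome).
#' @export
simulate_markers <- function(config) {
  with_seed(child_seed(config$seed, "markers"), {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
      m <- config$n_markers[ch]
      L_mb <- config$chrom_length_Mb[ch]
      pos <- sort(runif(m, 0, L_mb))
      while (anyDuplicated(pos) > 0) pos <- sort(runif(m, 0, L_mb))
      tibble(
        marker_id = sprintf("m%02d_%04d", ch, seq_len(m)),
        chrom = ch,
        pos_mb = pos,
        cm = genetic_position(pos, ch, config)
      )
    })
  })
}

# integrate a piecewise-constant rate landscape; total length preserved
genetic_position <- function(pos_mb, chrom, config) {
  L_mb <- config$chrom_length_Mb[chrom]
  L_cm <- config$chrom_length_cM[chrom]
  hs <- purrr::keep(config$hotspots %||% list(), ~ .x$chrom == chrom)
  rate <- function(x) {
    r <- rep(1, length(x))
    for (h in hs) r <- r * ifelse(x >= h$start_mb & x < h$end_mb, h$fold, 1)
    r
  }
  # cumulative integral on a fine grid
  grid <- sort(unique(c(seq(0, L_mb, length.out = 2048), pos_mb, L_mb)))
  seg <- diff(grid) * rate(head(grid, -1))
  cum <- c(0, cumsum(seg))
  w <- cum[match(pos_mb, grid)] / cum[length(cum)]
  w * L_cm
}

# one gamete from a pair of haplotypes; cm = marker genetic positions
meiosis_gamete <- function(h1, h2, cm, L_cm) {
  n_co <- rpois(1L, L_cm / 100)
  strand <- rep(sample.int(2L, 1L) - 1L, length(cm))
  if (n_co > 0L) {
    breaks <- sort(runif(n_co, 0, L_cm))
    strand <- (strand + findInterval(cm, breaks)) %% 2L
  }
  ifelse(strand == 0L, h1, h2)
}

# simulate n independent RIL lines on a fixed marker scaffold; returns list
# of haplotype pair matrices (markers x n) per chromosome combined into
# a dosage matrix (markers x n) with values 0/1/2 = count of B alleles
simulate_lines_dosage <- function(markers, config, n) {
  chroms <- split(markers, markers$chrom)
  t_gen <- config$generations
  single <- vapply(chroms, nrow, 0L) == 1L
  dosages <- vector("list", length(chroms))
  names(dosages) <- names(chroms)
  if (any(single)) {
    # single-locus chromosomes segregate by a fair coin per gamete;
    # no crossover machinery needed, so the whole block vectorizes
    m1 <- sum(single)
    h1 <- matrix(0L, m1, n)
    h2 <- matrix(1L, m1, n)
    for (g in seq_len(t_gen - 1L)) {
      c1 <- matrix(runif(m1 * n) < 0.5, m1, n)
      c2 <- matrix(runif(m1 * n) < 0.5, m1, n)
      g1 <- ifelse(c1, h1, h2)
      g2 <- ifelse(c2, h1, h2)
      h1 <- g1
      h2 <- g2
    }
    dos1 <- h1 + h2
    for (k in seq_len(m1)) {
      dosages[[which(single)[k]]] <- dos1[k, , drop = FALSE]
    }
  }
  for (ci in which(!single)) {
    mk <- chroms[[ci]]
    m <- nrow(mk)
    L_cm <- config$chrom_length_cM[mk$chrom[1]]
    out <- matrix(0L, m, n)
    for (j in seq_len(n)) {
      h1 <- rep(0L, m)  # F1: one haplotype per parent
      h2 <- rep(1L, m)
      for (g in seq_len(t_gen - 1L)) {
        g1 <- meiosis_gamete(h1, h2, mk$cm, L_cm)
        g2 <- meiosis_gamete(h1, h2, mk$cm, L_cm)
        h1 <- g1
        h2 <- g2
      }
      out[, j] <- h1 + h2
    }
    dosages[[ci]] <- out
  }
  do.call(rbind, dosages)
}

dosage_to_call <- function(d) c("AA", "AB", "BB")[d + 1L]

#' Simulate an F_t RIL population
#'
#' Produces genotypes for `config$n_rils` lines obtained by selfing a single
#' F1 for `config$generations - 1` rounds, with crossovers under the
#' Haldane no-interference model. If `config$sdr_spec` is set, viability
#' selection is applied afterwards via [apply_segregation_distortion()].
#'
#' @param config A [sim_config()].
#' @return An object of class `ril_sim`: a list with elements `calls` (a
#'   calls table, markers x RILs, values AA/AB/BB), `markers` (the scaffold
#'   from [simulate_markers()]) and `config`. The simulation ground truth
#'   is available through [truth_set()].
#' @examples
#' sim <- simulate_ril_population(sim_config(n_chromosomes = 1,
#'   n_markers = 30, n_rils = 15, seed = 42))
#' table(calls_matrix(sim$calls))
#' @export
simulate_ril_population <- function(config) {
  validate_sim_config(config)
  markers <- simulate_markers(config)
  dos <- with_seed(child_seed(config$seed, "population"), {
    simulate_lines_dosage(markers, config, config$n_rils)
  })
  gt <- matrix(dosage_to_call(dos), nrow(dos), ncol(dos))
  colnames(gt) <- sprintf("RIL_%03d", seq_len(config$n_rils))
  sim <- structure(
    list(calls = calls_table(markers, gt), markers = markers, config = config),
    class = "ril_sim"
  )
  if (!is.null(config$sdr_spec)) {
    sim <- apply_segregation_distortion(sim, config$sdr_spec)
  }
  sim
}

#' @export
print.ril_sim <- function(x, ...) {
  cat(sprintf(
    "<ril_sim> %d markers x %d RILs, t=%d, %d chromosome(s)\n",
    nrow(x$calls), length(sample_cols(x$calls)),
    x$config$generations, x$config$n_chromosomes
  ))
  invisible(x)
}

#' Ground truth of a simulated population
#'
#' @param sim A `ril_sim` object.
#' @return List with `genotypes` (calls table without NC), `order` (marker
#'   ids in true order per chromosome), `cm` and `mb` (named position
#'   vectors).
#' @export
truth_set <- function(sim) {
  stopifnot(inherits(sim, "ril_sim"))
  list(
    genotypes = sim$calls,
    order = split(sim$markers$marker_id, sim$markers$chrom),
    cm = setNames(sim$markers$cm, sim$markers$marker_id),
    mb = setNames(sim$markers$pos_mb, sim$markers$marker_id)
  )
}

#' Apply viability-based segregation distortion to a RIL population
#'
#' Models a segregation-distortion region (SDR) as zygote viability
#' weighting at the marker closest to the midpoint of the specified
#' interval: a line carrying genotype AA there survives with relative
#' weight `weight^2`, AB with `weight`, BB with 1 (weights normalized by
#' their maximum). Rejected lines are replaced by freshly simulated lines
#' subjected to the same selection, so the population size is preserved and
#' linked markers are distorted through hitchhiking only.
#'
#' @param sim A `ril_sim` object.
#' @param sdr_spec `list(chrom =, start_mb =, end_mb =, weight =)`;
#'   `weight > 1` favors the A allele.
#' @return A `ril_sim` with the same markers and (possibly) replaced lines.
#'   `weight = 1` returns the input unchanged.
#' @export
apply_segregation_distortion <- function(sim, sdr_spec) {
  stopifnot(inherits(sim, "ril_sim"))
  w <- sdr_spec$weight
  if (is.null(w) || w <= 0) abort("sdr_spec weight must be > 0")
  if (sdr_spec$chrom > sim$config$n_chromosomes) {
    abort("sdr_spec interval must lie on a simulated chromosome")
  }
  if (w == 1) return(sim)

  mk <- sim$markers
  on_chrom <- mk$chrom == sdr_spec$chrom
  if (!any(on_chrom)) abort("no markers on the SDR chromosome")
  mid <- (sdr_spec$start_mb + sdr_spec$end_mb) / 2
  anchor <- mk$marker_id[on_chrom][which.min(abs(mk$pos_mb[on_chrom] - mid))]

  gt <- calls_matrix(sim$calls)
  # survival probability by genotype at the anchor locus
  wts <- c(AA = w^2, AB = w, BB = 1)
  surv <- wts / max(wts)

  with_seed(child_seed(sim$config$seed, "sdr"), {
    keep <- runif(ncol(gt)) < surv[gt[anchor, ]]
    n_replace <- sum(!keep)
    if (n_replace > 0) {
      replacements <- matrix(NA_character_, nrow(gt), 0)
      while (ncol(replacements) < n_replace) {
        batch <- max(n_replace - ncol(replacements), 8L)
        dos <- simulate_lines_dosage(mk, sim$config, batch)
        cand <- matrix(dosage_to_call(dos), nrow(dos))
        rownames(cand) <- mk$marker_id
        ok <- runif(batch) < surv[cand[anchor, ]]
        replacements <- cbind(replacements, cand[, ok, drop = FALSE])
      }
      gt[, !keep] <- replacements[, seq_len(n_replace)]
    }
  })
  sim$calls <- calls_table(mk, gt)
  sim
}
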