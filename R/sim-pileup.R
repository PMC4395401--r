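# Read-pileup, flank-sequence and toy-annotation generators for the
# probe-design stage. These summarize sequencing evidence directly (no
# read-level simulation): each candidate SNP site carries per-allele
# depths, a minimum base quality and a mapping-uniqueness flag.

#' Simulate a read-pileup table of candidate SNP sites
#'
#' Site total depths are log-normal, parameterized so that a configured
#' central probability mass falls inside a configured depth range
#' (default: 90% of sites between 8 and 39 reads, the coverage profile of
#' a typical resequencing experiment at this scale).
#'
#' @param config A [sim_config()].
#' @param sites_per_chrom Candidate sites per chromosome; default three per
#'   2-Kb selection window so windows usually hold competing candidates.
#' @param depth_range Two integers: the central depth range.
#' @param central_mass Probability mass assigned to `depth_range`.
#' @param prop_unique Probability a site is uniquely mapped.
#' @param window_bp Window size used to pick the default site density.
#' @return Tibble (chrom, pos, ref, alt, depth_ref, depth_alt, min_qual,
#'   unique), sorted by (chrom, pos); positions 1-based.
#' @export
simulate_read_pileup <- function(config,
                                 sites_per_chrom = NULL,
                                 depth_range = c(8, 39),
                                 central_mass = 0.9,
                                 prop_unique = 0.95,
                                 window_bp = 2000) {
  n_windows <- pmax(1, floor(config$chrom_length_Mb * 1e6 / window_bp))
  if (is.null(sites_per_chrom)) {
    # cap so toy configurations stay small
    sites_per_chrom <- pmin(3L * n_windows, 3L * config$n_markers)
  }
  sites_per_chrom <- rep_len(as.integer(sites_per_chrom), config$n_chromosomes)

  meanlog <- mean(log(depth_range))
  sdlog <- (log(depth_range[2]) - meanlog) / stats::qnorm(0.5 + central_mass / 2)

  with_seed(child_seed(config$seed, "pileup"), {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
      n <- sites_per_chrom[ch]
      len_bp <- round(config$chrom_length_Mb[ch] * 1e6)
      pos <- sort(sample.int(len_bp, n))
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      depth <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
      depth_alt <- rbinom(n, depth, 0.5)
      tibble(
        chrom = sprintf("chr%d", ch),
        pos = pos,
        ref = ref,
        alt = unname(alt),
        depth_ref = depth - depth_alt,
        depth_alt = depth_alt,
        min_qual = pmin(41L, pmax(2L, as.integer(round(rnorm(n, 33, 5))))),
        unique = runif(n) < prop_unique
      )
    })
  })
}

# parameters of the depth sampling distribution, used by tests as oracle
pileup_depth_params <- function(depth_range = c(8, 39), central_mass = 0.9) {
  meanlog <- mean(log(depth_range))
  list(
    meanlog = meanlog,
    sdlog = (log(depth_range[2]) - meanlog) / stats::qnorm(0.5 + central_mass / 2)
  )
}

#' Simulate flanking sequence around SNP sites
#'
#' Random ACGT context for probe design; each entry is an odd-length
#' string with the site's reference base at the central position.
#'
#' @param snps Tibble with at least chrom, pos, ref (e.g. rows of a pileup).
#' @param flank Bases on each side of the SNP (>= 17 for probe design).
#' @param seed Integer seed.
#' @return Named character vector, one sequence per row of `snps`, named
#'   `chrom:pos`.
#' @export
simulate_flanks <- function(snps, flank = 35, seed = 1L) {
  with_seed(seed, {
    vapply(seq_len(nrow(snps)), function(i) {
      side <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      paste0(side(flank), snps$ref[i], side(flank))
    }, "") |>
      setNames(sprintf("%s:%d", snps$chrom, snps$pos))
  })
}

#' Simulate a toy genome annotation
#'
#' Generates non-overlapping gene models per chromosome, each with an mRNA
#' spanning the gene and two CDS exons inside it, for SNP genomic-context
#' classification.
#'
#' @param config A [sim_config()].
#' @param genes_per_chrom Number of genes per chromosome.
#' @return Tibble (chrom, start, end, type, id) with 1-based inclusive
#'   coordinates and type in gene/mRNA/CDS.
#' @export
simulate_annotation <- function(config, genes_per_chrom = 40) {
  with_seed(child_seed(config$seed, "annotation"), {
    purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
      len_bp <- round(config$chrom_length_Mb[ch] * 1e6)
      n <- genes_per_chrom
      starts <- sort(sample.int(max(len_bp - 6000L, n), n))
      purrr::map_dfr(seq_len(n), function(i) {
        g_start <- starts[i]
        g_end <- min(g_start + 2999L + sample.int(2000L, 1L), len_bp)
        id <- sprintf("gene_%d_%03d", ch, i)
        exon1 <- c(g_start + 100L, g_start + 800L)
        exon2 <- c(min(g_start + 1500L, g_end), min(g_start + 2200L, g_end))
        tibble(
          chrom = sprintf("chr%d", ch),
          start = c(g_start, g_start, exon1[1], exon2[1]),
          end = c(g_end, g_end, exon1[2], exon2[2]),
          type = c("gene", "mRNA", "CDS", "CDS"),
          id = c(id, paste0(id, ".1"), paste0(id, ".1.c1"), paste0(id, ".1.c2"))
        )
      })
    })
  })
}

#' Write an annotation table as GFF3
#'
#' @param anno Annotation tibble from [simulate_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(anno, path) {
  gr <- GenomicRanges::makeGRangesFromDataFrame(
    data.frame(
      seqnames = anno$chrom, start = anno$start, end = anno$end,
      strand = "+", type = anno$type, ID = anno$id
    ),
    keep.extra.columns = TRUE
  )
  # toy CDS features carry no phase; rtracklayer notes this on export
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}
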