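# Probe design: one best SNP per 2-Kb window, four Tm-optimized probes per
# SNP (two alleles x two strands), genomic-context classification.

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' top-strand stacks.
.nn_dh <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9
)
.nn_ds <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2
)
# duplex initiation with a terminal G/C vs terminal A/T
.nn_init_dh <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.nn_init_ds <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor thermodynamic parameters
#'
#' SantaLucia unified dinucleotide-stack enthalpies and entropies with
#' duplex initiation terms, plus the gas constant and effective strand
#' concentration used in the melting-temperature formula.
#'
#' @param ctx Effective strand concentration term (mol/L).
#' @param gas_constant Gas constant R in cal/(mol K).
#' @return List of class `thermo_params` with elements dh_table, ds_table,
#'   init_dh, init_ds, gas_constant, ctx.
#' @export
thermo_params <- function(ctx = 1e-7, gas_constant = 1.9872) {
  stopifnot(ctx > 0)
  structure(
    list(
      dh_table = .nn_dh, ds_table = .nn_ds,
      init_dh = .nn_init_dh, init_ds = .nn_init_ds,
      gas_constant = gas_constant, ctx = ctx
    ),
    class = "thermo_params"
  )
}

#' Melting temperature from enthalpy/entropy totals
#'
#' The nearest-neighbor two-state formula
#' `Tm = dH * 1000 / (dS + R * ln(Ctx)) - 273.15` with dH in kcal/mol and
#' dS in cal/(mol K).
#'
#' @param dh Total enthalpy (kcal/mol).
#' @param ds Total entropy (cal/(mol K)).
#' @param ctx Effective strand concentration term.
#' @param gas_constant Gas constant (cal/(mol K)).
#' @return Temperature in degrees Celsius.
#' @export
tm_from_totals <- function(dh, ds, ctx, gas_constant = 1.9872) {
  dh * 1000 / (ds + gas_constant * log(ctx)) - 273.15
}

#' Probe melting temperature by the nearest-neighbor model
#'
#' Sums stack enthalpies/entropies over consecutive dinucleotides plus the
#' two terminal initiation contributions, then applies [tm_from_totals()].
#'
#' @param sequence Character string over ACGT, length >= 2.
#' @param params A [thermo_params()].
#' @return Temperature in degrees Celsius.
#' @examples
#' compute_tm("ACGTACGTACGTACGTACGT")
#' @export
compute_tm <- function(sequence, params = thermo_params()) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2) abort("sequence must have length >= 2")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("sequence contains non-ACGT characters")
  }
  stacks <- paste0(head(bases, -1), tail(bases, -1))
  dh <- sum(params$dh_table[stacks]) +
    params$init_dh[bases[1]] + params$init_dh[bases[length(bases)]]
  ds <- sum(params$ds_table[stacks]) +
    params$init_ds[bases[1]] + params$init_ds[bases[length(bases)]]
  unname(tm_from_totals(dh, ds, params$ctx, params$gas_constant))
}

#' Select the best SNP per genomic window
#'
#' Scans non-overlapping windows (anchored at position 1 of each
#' chromosome, half-open) and keeps, per window, the uniquely-mapped
#' candidate with base quality at least `min_qual` and the highest
#' minor-allele read depth. Ties break by higher quality, then lower
#' position.
#'
#' @param pileup Pileup tibble as from [simulate_read_pileup()], sorted by
#'   (chrom, pos).
#' @param window_bp Window width in bp.
#' @param min_qual Minimum PHRED base quality.
#' @return Tibble of selected pileup rows with an added `window` column.
#' @export
select_window_snps <- function(pileup, window_bp = 2000, min_qual = 25) {
  ord <- order(pileup$chrom, pileup$pos)
  if (!identical(ord, seq_len(nrow(pileup)))) {
    abort("pileup must be sorted by (chrom, pos); use arrange(chrom, pos)")
  }
  pileup |>
    filter(.data$unique, .data$min_qual >= !!min_qual) |>
    mutate(
      window = (.data$pos - 1L) %/% window_bp,
      minor_depth = pmin(.data$depth_ref, .data$depth_alt)
    ) |>
    group_by(.data$chrom, .data$window) |>
    arrange(desc(.data$minor_depth), desc(.data$min_qual), .data$pos,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos) |>
    select(-"minor_depth")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Design the four allele-specific probes for one SNP
#'
#' For each allele, builds probes centered on the SNP at every length from
#' 20 to 35 and keeps the length whose melting temperature is closest to
#' `target_tm`; the second replicate probe is the reverse complement
#' (detecting the opposite strand) and shares the same Tm.
#'
#' @param snp One-row data frame (or list) with chrom, pos, ref, alt.
#' @param flank Odd-length ACGT string centered on the SNP site, providing
#'   at least 17 bases each side.
#' @param params A [thermo_params()].
#' @param target_tm Target melting temperature (deg C).
#' @return Tibble of 4 probes (snp_id, chrom, pos, allele, strand,
#'   probe_seq, length, tm).
#' @export
design_probes <- function(snp, flank, params = thermo_params(), target_tm = 80) {
  nchar_f <- nchar(flank)
  if (nchar_f %% 2 != 1) abort("flank must have odd length (SNP at center)")
  center <- (nchar_f + 1L) %/% 2L
  if (center - 1L < 17L || nchar_f - center < 17L) {
    abort("flank must provide >= 17 bases on each side of the SNP")
  }
  snp_id <- sprintf("%s:%d", snp$chrom, snp$pos)
  purrr::map_dfr(c(A = snp$ref, B = snp$alt), function(base) {
    lens <- 20:35
    cand <- vapply(lens, function(l) {
      left <- (l - 1L) %/% 2L
      right <- l - 1L - left
      seq <- paste0(
        substr(flank, center - left, center - 1L),
        base,
        substr(flank, center + 1L, center + right)
      )
      seq
    }, "")
    tms <- vapply(cand, compute_tm, 0, params = params)
    best <- which.min(abs(tms - target_tm))
    fwd <- cand[best]
    tibble(
      snp_id = snp_id, chrom = snp$chrom, pos = snp$pos,
      strand = c("F", "R"),
      probe_seq = c(fwd, revcomp(fwd)),
      length = lens[best],
      tm = tms[best]
    )
  }, .id = "allele") |>
    select("snp_id", "chrom", "pos", "allele", "strand", "probe_seq",
           "length", "tm")
}

#' Classify SNP genomic context from an annotation
#'
#' Labels each SNP `CDS` if it falls inside any CDS feature, else `mRNA`
#' if inside any mRNA feature, else `intergenic`.
#'
#' @param snps Tibble with chrom and pos columns.
#' @param annotation Annotation tibble (chrom, start, end, type; 1-based
#'   inclusive) or the path to a GFF3 file.
#' @return `snps` with an added `context` column.
#' @export
annotate_snp_context <- function(snps, annotation) {
  if (is.character(annotation)) {
    gr <- tryCatch(
      rtracklayer::import(annotation, format = "gff3"),
      error = function(e) abort(paste("malformed GFF3:", conditionMessage(e)))
    )
    annotation <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      type = as.character(gr$type)
    )
  }
  in_type <- function(chrom, pos, type) {
    feats <- annotation[annotation$type == type, ]
    vapply(seq_along(pos), function(i) {
      any(feats$chrom == chrom[i] & feats$start <= pos[i] & feats$end >= pos[i])
    }, NA)
  }
  snps |>
    mutate(context = case_when(
      in_type(.data$chrom, .data$pos, "CDS") ~ "CDS",
      in_type(.data$chrom, .data$pos, "mRNA") ~ "mRNA",
      .default = "intergenic"
    ))
}

#' Design an array from a pileup
#'
#' End-to-end probe-design stage: window-based SNP selection, four probes
#' per selected SNP, optional genomic-context classification.
#'
#' @inheritParams select_window_snps
#' @param flanks Named character vector of flank sequences (names
#'   `chrom:pos`), e.g. from [simulate_flanks()]; missing SNPs are dropped
#'   with a warning.
#' @param annotation Optional annotation (see [annotate_snp_context()]).
#' @inheritParams design_probes
#' @return Probe tibble as from [design_probes()], with a `context` column
#'   when annotation is given.
#' @export
design_array <- function(pileup, flanks, window_bp = 2000, min_qual = 25,
                         params = thermo_params(), target_tm = 80,
                         annotation = NULL) {
  sel <- select_window_snps(pileup, window_bp = window_bp, min_qual = min_qual)
  keys <- sprintf("%s:%d", sel$chrom, sel$pos)
  have <- keys %in% names(flanks)
  if (!all(have)) {
    warn(sprintf("dropping %d selected SNPs without flank sequence", sum(!have)))
    sel <- sel[have, ]
    keys <- keys[have]
  }
  probes <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    design_probes(sel[i, ], flanks[[keys[i]]], params = params,
                  target_tm = target_tm)
  })
  if (!is.null(annotation)) {
    ctx <- annotate_snp_context(distinct(probes, .data$snp_id, .data$chrom, .data$pos),
                                annotation)
    probes <- left_join(probes, select(ctx, "snp_id", "context"), by = "snp_id")
  }
  probes
}
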