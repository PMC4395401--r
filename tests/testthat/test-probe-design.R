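# Probe design: melting temperature, window selection, probe layout,
# genomic-context classification.

test_that("the melting-temperature closed form evaluates correctly", {
  # dH = -80 kcal/mol, dS = -220 cal/(mol K), R ln(Ctx) = -32.03
  ctx <- exp(-32.03 / 1.9872)
  expect_equal(tm_from_totals(-80, -220, ctx), -80000 / -252.03 - 273.15,
               tolerance = 1e-12)
  expect_equal(tm_from_totals(-80, -220, ctx), 44.27, tolerance = 0.01)
})

test_that("Tm increases with strand concentration for stabilizing duplexes", {
  grid <- 10^seq(-9, -4, length.out = 60)
  tms <- vapply(grid, function(ct) tm_from_totals(-80, -220, ct), 0)
  expect_true(all(diff(tms) > 0))
})

test_that("compute_tm agrees with an independent re-evaluation of the formula", {
  # oracle coded from scratch: explicit dinucleotide walk + closed form
  params <- thermo_params(ctx = 3e-7)
  oracle <- function(seq) {
    b <- strsplit(seq, "")[[1]]
    dh <- rilmap:::.nn_init_dh[[b[1]]] + rilmap:::.nn_init_dh[[b[length(b)]]]
    ds <- rilmap:::.nn_init_ds[[b[1]]] + rilmap:::.nn_init_ds[[b[length(b)]]]
    for (i in seq_len(length(b) - 1)) {
      st <- paste0(b[i], b[i + 1])
      dh <- dh + rilmap:::.nn_dh[[st]]
      ds <- ds + rilmap:::.nn_ds[[st]]
    }
    dh * 1000 / (ds + 1.9872 * log(3e-7)) - 273.15
  }
  withr::with_seed(31, {
    for (i in 1:100) {
      seq <- paste(sample(c("A", "C", "G", "T"), sample(20:35, 1), TRUE),
                   collapse = "")
      expect_equal(compute_tm(seq, params), oracle(seq), tolerance = 1e-9)
    }
  })
  expect_error(compute_tm("ACGTN"), "non-ACGT")
  expect_error(compute_tm("A"), "length")
})

test_that("Tm of a long uniform-stack sequence approaches the stack ratio limit", {
  seqs <- vapply(c(50, 200, 1000), function(n) strrep("G", n), "")
  tms <- vapply(seqs, compute_tm, 0)
  limit <- rilmap:::.nn_dh[["GG"]] * 1000 / rilmap:::.nn_ds[["GG"]] - 273.15
  expect_lt(abs(tms[3] - limit), abs(tms[1] - limit))
  expect_lt(abs(tms[3] - limit), 2)
})

make_pileup <- function(...) {
  d <- tibble::tribble(...)
  d
}

test_that("window selection keeps the best qualifying SNP per window", {
  pu <- tibble::tibble(
    chrom = "chr1",
    pos = c(100L, 500L, 1500L, 2500L, 4100L),
    ref = "A", alt = "C",
    depth_ref = c(20L, 12L, 15L, 30L, 9L),
    depth_alt = c(10L, 5L, 3L, 2L, 9L),
    min_qual = c(30L, 30L, 30L, 30L, 24L),
    unique = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  sel <- select_window_snps(pu)
  # window [1, 2000): minor depths 10 vs 5 vs 3 -> the depth-10 SNP wins
  expect_equal(sel$pos[sel$window == 0], 100L)
  # window [2000, 4000): single candidate
  expect_true(2500 %in% sel$pos)
  # window [4000, 6000): only SNP fails the quality threshold
  expect_false(4100 %in% sel$pos)
  # non-unique mapping is never selected
  pu2 <- pu
  pu2$unique[1] <- FALSE
  sel2 <- select_window_snps(pu2)
  expect_false(100 %in% sel2$pos)
  # unsorted input is rejected with advice
  expect_error(select_window_snps(pu[c(2, 1, 3, 4, 5), ]), "sort")
})

test_that("window-selection ties break by quality then position", {
  pu <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
    depth_ref = c(10L, 10L, 10L), depth_alt = c(10L, 10L, 10L),
    min_qual = c(30L, 35L, 35L), unique = TRUE
  )
  expect_equal(select_window_snps(pu)$pos, 20L)
})

test_that("four probes are designed per SNP with optimal centered lengths", {
  snp <- list(chrom = "chr1", pos = 1000L, ref = "A", alt = "G")
  flank <- withr::with_seed(7, paste(c(
    sample(c("A", "C", "G", "T"), 35, TRUE), "A",
    sample(c("A", "C", "G", "T"), 35, TRUE)
  ), collapse = ""))
  params <- thermo_params()
  des <- design_probes(snp, flank, params, target_tm = 80)
  expect_equal(nrow(des), 4)
  expect_equal(sort(unique(des$allele)), c("A", "B"))
  expect_equal(as.integer(table(des$allele)), c(2L, 2L))
  expect_true(all(des$length >= 20 & des$length <= 35))
  # forward and reverse probes of an allele are reverse complements with
  # identical Tm
  for (al in c("A", "B")) {
    pair <- des[des$allele == al, ]
    expect_equal(rilmap:::revcomp(pair$probe_seq[pair$strand == "F"]),
                 pair$probe_seq[pair$strand == "R"])
    expect_equal(pair$tm[1], pair$tm[2])
  }
  # chosen length is the brute-force argmin of |Tm - target| over 20:35
  center <- 36L
  for (al in c(A = snp$ref, B = snp$alt)) {
    tms <- vapply(20:35, function(l) {
      left <- (l - 1L) %/% 2L
      right <- l - 1L - left
      compute_tm(paste0(substr(flank, center - left, center - 1L), al,
                        substr(flank, center + 1L, center + right)), params)
    }, 0)
    best_len <- (20:35)[which.min(abs(tms - 80))]
    expect_equal(unique(des$length[des$allele == names(which(c(A = snp$ref, B = snp$alt) == al))]),
                 best_len)
  }
  # all candidates below target: with a GC-only context Tm rises with
  # length, so the boundary length 35 is closest
  gc_flank <- paste0(strrep("G", 35), "A", strrep("C", 35))
  des_hot <- design_probes(snp, gc_flank, params, target_tm = 200)
  expect_true(all(des_hot$length == 35))
  expect_error(design_probes(snp, substr(flank, 20, 50), params), "17")
})

test_that("SNP context classification follows CDS > mRNA > intergenic", {
  anno <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 150L),
    end = c(1000L, 1000L, 300L),
    type = c("gene", "mRNA", "CDS"),
    id = c("g1", "g1.1", "g1.1.c1")
  )
  snps <- tibble::tibble(chrom = "chr1", pos = c(200L, 500L, 5000L))
  ctx <- annotate_snp_context(snps, anno)
  expect_equal(ctx$context, c("CDS", "mRNA", "intergenic"))
  # GFF3 round trip through rtracklayer
  gff <- tempfile(fileext = ".gff3")
  write_annotation_gff3(tibble::tibble(
    chrom = anno$chrom, start = anno$start, end = anno$end,
    type = anno$type, id = anno$id
  ), gff)
  ctx2 <- annotate_snp_context(snps, gff)
  expect_equal(ctx2$context, ctx$context)
})

test_that("median spacing of selected SNPs on a dense pileup is about one window", {
  cfg <- sim_config(n_chromosomes = 1, n_markers = 600, chrom_length_cM = 90,
                    chrom_length_Mb = 2, n_rils = 10, seed = 23)
  pu <- simulate_read_pileup(cfg)
  sel <- select_window_snps(pu)
  n_windows <- ceiling(2e6 / 2000)
  expect_lte(nrow(sel), n_windows)
  spacing <- diff(sel$pos)
  expect_lt(abs(median(spacing) - 2000), 600)
})
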