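# Signal preprocessing: log2 transform, between-array quantile
# normalization, per-probe centering, spatial-defect masking, and
# median-polish summarization of the four probe replicates into one
# (A-signal, B-signal) pair per SNP per sample.

#' Quantile normalization between arrays
#'
#' Replaces each array's empirical distribution by the mean of order
#' statistics across arrays (mid-rank handling of ties), so sorted values
#' are identical across arrays afterwards. Missing entries are excluded
#' from rank computation and restored as missing.
#'
#' @param mat Numeric matrix, one column per array.
#' @return Normalized matrix of the same shape.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (any(colSums(!is.na(mat)) == 0)) {
    abort("quantile normalization undefined for an entirely missing array")
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  out[is.na(mat)] <- NA_real_
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-probe centering across arrays
#'
#' Subtracts each probe's median over arrays, so every probe row has
#' median zero; removes probe affinity effects.
#'
#' @param mat Numeric matrix, probes x arrays.
#' @return Centered matrix.
#' @export
center_probes <- function(mat) {
  mat <- as.matrix(mat)
  sweep(mat, 1, row_medians_cpp(mat, TRUE))
}

#' Mask spatial slide defects on one array
#'
#' Reconstructs the slide grid from the probe layout and masks probes
#' whose intensity deviates from the local spatial median surface by more
#' than `k` local MADs - a simplified scratch/bubble filter.
#'
#' @param values Named numeric vector of one array's probe intensities
#'   (names = probe ids).
#' @param layout Tibble (probe_id, row, col) giving grid coordinates.
#' @param radius Chebyshev neighborhood radius in grid cells.
#' @param k Robust multiplier on the local MAD.
#' @return Logical vector parallel to `values`; TRUE = masked. Probes with
#'   an entirely missing neighborhood are left unmasked with a warning.
#' @export
mask_spatial_defects <- function(values, layout, radius = 3, k = 5) {
  idx <- match(names(values), layout$probe_id)
  if (anyNA(idx)) abort("layout must cover all probes")
  nr <- max(layout$row)
  nc <- max(layout$col)
  grid <- matrix(NA_real_, nr, nc)
  grid[cbind(layout$row[idx], layout$col[idx])] <- values
  code <- spatial_outlier_mask_cpp(grid, as.integer(radius), k)
  cell <- code[cbind(layout$row[idx], layout$col[idx])]
  if (any(cell == 2L)) {
    warn(sprintf("%d probes had an entirely missing neighborhood; left unmasked",
                 sum(cell == 2L)))
  }
  setNames(cell == 1L, names(values))
}

#' Summarize probe replicates by median polish
#'
#' For each (SNP, allele), runs median polish on the replicates x arrays
#' matrix (forward/reverse strand probes as rows) and reports, per array,
#' the overall effect plus the array column effect - the replicate summary
#' with the array effect removed from residual structure.
#'
#' @param mat Numeric matrix, probes x arrays, with rownames of the form
#'   `snp|allele|strand` (as produced inside [process_signals()]), already
#'   on the processed (log2) scale; masked entries NA.
#' @param max_iter,tol Median-polish iteration cap and convergence
#'   tolerance (total absolute change).
#' @return Tibble (snp_id, allele, sample, signal); `signal` is NA where
#'   every replicate was masked.
#' @export
summarize_replicates <- function(mat, max_iter = 10L, tol = 1e-8) {
  parts <- do.call(rbind, strsplit(rownames(mat), "|", fixed = TRUE))
  key <- paste(parts[, 1], parts[, 2], sep = "|")
  groups <- split(seq_len(nrow(mat)), factor(key, levels = unique(key)))
  samples <- colnames(mat)
  n_s <- length(mat[1, ])
  summary <- matrix(NA_real_, length(groups), n_s,
                    dimnames = list(names(groups), samples))

  two_row <- vapply(groups, length, 0L) == 2L
  idx2 <- groups[two_row]
  if (length(idx2) > 0) {
    z1 <- mat[vapply(idx2, `[`, 0L, 1L), , drop = FALSE]
    z2 <- mat[vapply(idx2, `[`, 0L, 2L), , drop = FALSE]
    summary[names(idx2), ] <- medpolish_two_row(z1, z2, max_iter, tol)
  }
  # groups with unusual replicate counts take the generic path
  for (g in names(groups)[!two_row]) {
    sub <- mat[groups[[g]], , drop = FALSE]
    ok_col <- colSums(!is.na(sub)) > 0
    if (!any(ok_col)) next
    mp <- suppressWarnings(
      medpolish(sub[, ok_col, drop = FALSE], eps = tol, maxiter = max_iter,
                trace.iter = FALSE, na.rm = TRUE)
    )
    summary[g, ok_col] <- mp$overall + mp$col
  }

  ids <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  tibble(
    snp_id = rep(ids[, 1], times = n_s),
    allele = rep(ids[, 2], times = n_s),
    sample = rep(samples, each = length(groups)),
    signal = as.vector(summary)
  )
}

# vectorized median polish for stacks of 2 x n matrices (NA = masked, as
# with median(..., na.rm = TRUE)): z1/z2 hold the first/second row of
# every group (groups x samples)
medpolish_two_row <- function(z1, z2, max_iter, tol) {
  g <- nrow(z1)
  both_na <- is.na(z1) & is.na(z2)
  re1 <- re2 <- tt <- numeric(g)
  ce <- matrix(0, g, ncol(z1))
  pair_med <- function(a, b) {
    # elementwise median of two values with NA removal
    out <- (a + b) / 2
    out[is.na(a)] <- b[is.na(a)]
    out[is.na(b)] <- a[is.na(b)]
    out[is.na(out)] <- 0
    out
  }
  zero_na <- function(x) { x[is.na(x)] <- 0; x }
  for (iter in seq_len(max_iter)) {
    old <- tt + 0
    rd1 <- zero_na(row_medians_cpp(z1, TRUE))
    rd2 <- zero_na(row_medians_cpp(z2, TRUE))
    z1 <- z1 - rd1; z2 <- z2 - rd2
    re1 <- re1 + rd1; re2 <- re2 + rd2
    cd <- row_medians_cpp(ce, TRUE)
    ce <- ce - cd; tt <- tt + cd
    cdel <- pair_med(z1, z2)       # column median of two values
    z1 <- z1 - cdel; z2 <- z2 - cdel
    ce <- ce + cdel
    rdel <- (re1 + re2) / 2        # median of the two row effects
    re1 <- re1 - rdel; re2 <- re2 - rdel
    tt <- tt + rdel
    if (max(abs(tt - old)) < tol && iter > 1) break
  }
  out <- tt + ce
  out[both_na] <- NA_real_
  out
}

#' Preprocess a signal tensor into per-SNP A/B signals
#'
#' The full preprocessing chain: log2 transform, quantile normalization
#' between arrays, per-probe median centering, optional spatial-defect
#' masking, then median-polish summarization of the strand replicates,
#' yielding one (signal_a, signal_b) pair per SNP per sample.
#'
#' @param signals A `signal_tensor` tibble from [simulate_array_signals()]
#'   or any tibble with columns snp_id, allele, strand, sample, intensity.
#' @param layout Probe grid layout; defaults to the tensor's own attribute.
#' @param spatial_filter Apply the spatial defect mask?
#' @param radius,k Parameters of [mask_spatial_defects()].
#' @return Tibble (snp_id, sample, signal_a, signal_b, masked) of class
#'   `summarized_signals`; the training design attribute, if present on
#'   the input, is carried through.
#' @export
process_signals <- function(signals, layout = attr(signals, "layout"),
                            spatial_filter = TRUE, radius = 3, k = 5) {
  probe_id <- paste(signals$snp_id, signals$allele, signals$strand, sep = "|")
  probes <- unique(probe_id)
  samples <- unique(signals$sample)
  mat <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
  mat[cbind(match(probe_id, probes), match(signals$sample, samples))] <-
    signals$intensity

  mat <- log2(mat)
  mat[!is.finite(mat)] <- NA_real_
  mat <- quantile_normalize(mat)
  mat <- center_probes(mat)

  if (spatial_filter && !is.null(layout)) {
    for (j in seq_len(ncol(mat))) {
      masked <- mask_spatial_defects(setNames(mat[, j], rownames(mat)),
                                     layout, radius = radius, k = k)
      mat[masked, j] <- NA_real_
    }
  }

  long <- summarize_replicates(mat)
  out <- long |>
    tidyr::pivot_wider(names_from = "allele", values_from = "signal",
                       names_prefix = "signal_") |>
    rename(signal_a = "signal_A", signal_b = "signal_B") |>
    mutate(masked = is.na(.data$signal_a) | is.na(.data$signal_b)) |>
    arrange(match(.data$snp_id, unique(signals$snp_id)),
            match(.data$sample, samples))
  attr(out, "training") <- attr(signals, "training")
  class(out) <- c("summarized_signals", class(out))
  out
}
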