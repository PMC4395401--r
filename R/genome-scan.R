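# Downstream genome scans on the refined map: local recombination-rate
# profile (lowess-smoothed cM vs Mb, sliding 5-marker slope), the
# segregation-distortion scan (p(AA) - p(BB), chi-square, BH), map-genome
# collinearity, and bin-polymorphism coverage for non-parental accessions.

#' Local recombination-rate profile
#'
#' Per linkage group, smooths genetic position against physical position
#' with lowess (span 0.1 by default) and reports the least-squares slope
#' of each sliding window of `window` markers, in cM/Mb and log10(cM/Mb).
#' Markers whose genetic order contradicts the physical order are removed
#' first (longest nondecreasing subsequence after orientation).
#'
#' @param map A `linkage_map` (needs cm and pos_mb columns).
#' @param span Lowess span.
#' @param window Markers per sliding window.
#' @param rate_floor Clamp for nonpositive smoothed slopes before the log
#'   transform.
#' @return Tibble (linkage_group, mid_mb, mid_cm, rate_cm_mb, log10_rate);
#'   groups with fewer than `window` usable markers yield no rows (with a
#'   warning).
#' @export
local_recomb_rate <- function(map, span = 0.1, window = 5, rate_floor = 1e-6) {
  stopifnot(all(c("cm", "pos_mb") %in% names(map)))
  purrr::map_dfr(split(as_tibble(map), map$linkage_group), function(d) {
    d <- d |>
      filter(!is.na(.data$pos_mb)) |>
      distinct(.data$pos_mb, .keep_all = TRUE) |>
      arrange(.data$cm, .data$pos_mb)
    # orient so physical position increases along the map, then drop
    # order-inconsistent markers
    if (nrow(d) >= 2 && cor(d$cm, d$pos_mb, method = "spearman") < 0) {
      d$pos_mb <- -d$pos_mb
    }
    d <- d[lis_indices(d$pos_mb), ]
    d$pos_mb <- abs(d$pos_mb)
    if (nrow(d) < window) {
      warn(sprintf("linkage group %s has fewer than %d usable markers",
                   as.character(d$linkage_group[1]), window))
      return(tibble())
    }
    sm <- lowess(d$pos_mb, d$cm, f = span)
    n <- length(sm$x)
    idx <- seq_len(n - window + 1)
    rates <- vapply(idx, function(i) {
      xs <- sm$x[i:(i + window - 1)]
      ys <- sm$y[i:(i + window - 1)]
      if (max(xs) - min(xs) < 1e-9) return(NA_real_)
      sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
    }, 0)
    tibble(
      linkage_group = d$linkage_group[1],
      mid_mb = vapply(idx, function(i) mean(sm$x[i:(i + window - 1)]), 0),
      mid_cm = vapply(idx, function(i) mean(sm$y[i:(i + window - 1)]), 0),
      rate_cm_mb = pmax(rates, rate_floor),
      log10_rate = log10(pmax(rates, rate_floor))
    )
  })
}

#' Benjamini-Hochberg step-up control
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha Target false-discovery rate.
#' @return List with `q_values` (monotone BH-adjusted values) and
#'   `reject` (logical).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= alpha)
}

#' Segregation-distortion scan
#'
#' Per marker, tests the homozygous call counts nAA vs nBB against equal
#' frequencies (chi-square, heterozygotes excluded), controls the FDR by
#' Benjamini-Hochberg, and reports distortion delta = p(AA) - p(BB). A
#' segregation-distortion region (SDR) is a maximal run of at least
#' `min_run` consecutive significant markers favoring the same allele. A
#' cross-validated cubic smoothing spline of delta vs position is fitted
#' per chromosome for reporting.
#'
#' @param calls A calls table with chrom and pos_mb.
#' @param alpha FDR level.
#' @param min_run Minimum run of consecutive significant markers forming
#'   an SDR.
#' @param smooth Fit the reporting spline? (It never feeds the test;
#'   disable in tight simulation loops.)
#' @return List of class `distortion_scan`: `records` (marker tibble with
#'   n_aa, n_bb, delta, chi2_p, bh_q, significant, delta_smooth) and
#'   `intervals` (SDR tibble: chrom, start_mb, end_mb, start_marker,
#'   end_marker, n_markers, favored_allele).
#' @export
segregation_scan <- function(calls, alpha = 0.05, min_run = 3, smooth = TRUE) {
  assert_calls(calls)
  gt <- calls_matrix(calls)
  rec <- tibble(
    marker_id = calls$marker_id,
    chrom = calls$chrom %||% 1L,
    pos_mb = calls$pos_mb %||% seq_len(nrow(calls)),
    n_aa = unname(rowSums(gt == "AA")),
    n_bb = unname(rowSums(gt == "BB"))
  ) |>
    filter(.data$n_aa + .data$n_bb > 0) |>
    arrange(.data$chrom, .data$pos_mb) |>
    mutate(
      delta = (.data$n_aa - .data$n_bb) / (.data$n_aa + .data$n_bb),
      chi2 = (.data$n_aa - (.data$n_aa + .data$n_bb) / 2)^2 /
        ((.data$n_aa + .data$n_bb) / 2) * 2,
      chi2_p = pchisq(.data$chi2, df = 1, lower.tail = FALSE)
    )
  bh <- benjamini_hochberg(rec$chi2_p, alpha = alpha)
  rec$bh_q <- bh$q_values
  rec$significant <- bh$reject

  rec <- if (smooth) {
    rec |>
      group_by(.data$chrom) |>
      mutate(delta_smooth = smooth_delta(.data$pos_mb, .data$delta)) |>
      ungroup()
  } else {
    mutate(rec, delta_smooth = NA_real_)
  }

  intervals <- purrr::map_dfr(split(rec, rec$chrom), function(d) {
    state <- ifelse(d$significant, sign(d$delta), 0)
    runs <- call_runs(as.character(state))
    runs <- runs[runs$value %in% c("1", "-1") & runs$length >= min_run, ]
    if (nrow(runs) == 0) return(tibble())
    tibble(
      chrom = d$chrom[1],
      start_mb = d$pos_mb[runs$start],
      end_mb = d$pos_mb[runs$end],
      start_marker = d$marker_id[runs$start],
      end_marker = d$marker_id[runs$end],
      n_markers = runs$length,
      favored_allele = ifelse(runs$value == "1", "A", "B")
    )
  })
  out <- list(records = rec, intervals = intervals, alpha = alpha,
              min_run = min_run)
  class(out) <- "distortion_scan"
  out
}

smooth_delta <- function(pos, delta) {
  if (length(unique(pos)) < 8) return(delta)
  fit <- tryCatch(smooth.spline(pos, delta, cv = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) return(delta)
  predict(fit, pos)$y
}

#' @export
print.distortion_scan <- function(x, ...) {
  cat(sprintf("<distortion_scan> %d markers tested, %d significant, %d SDR interval(s)\n",
              nrow(x$records), sum(x$records$significant), nrow(x$intervals)))
  invisible(x)
}

#' Map-genome collinearity
#'
#' Per linkage group, the R-squared of regressing map position (cM) on
#' genome position (Mb) after resolving orientation by the sign of the
#' rank correlation, plus the fraction of markers whose linkage group
#' matches the majority chromosome.
#'
#' @param map A `linkage_map` whose markers carry genome coordinates
#'   (chrom, pos_mb).
#' @return Tibble (linkage_group, chrom, n_markers, frac_chrom_match,
#'   r_squared).
#' @export
collinearity <- function(map) {
  stopifnot(all(c("chrom", "pos_mb") %in% names(map)))
  purrr::map_dfr(split(as_tibble(map), map$linkage_group), function(d) {
    d <- filter(d, !is.na(.data$chrom), !is.na(.data$pos_mb))
    maj <- names(sort(table(d$chrom), decreasing = TRUE))[1]
    dm <- filter(d, .data$chrom == maj)
    r2 <- if (nrow(dm) >= 3 && sd(dm$cm) > 0 && sd(dm$pos_mb) > 0) {
      orient <- sign(cor(dm$cm, dm$pos_mb, method = "spearman"))
      if (orient == 0) orient <- 1
      summary(lm(cm ~ I(orient * pos_mb), data = dm))$r.squared
    } else NA_real_
    tibble(
      linkage_group = d$linkage_group[1],
      chrom = maj,
      n_markers = nrow(d),
      frac_chrom_match = nrow(dm) / nrow(d),
      r_squared = r2
    )
  })
}

#' Bin-polymorphism coverage in additional accessions
#'
#' A marker is polymorphic when the accession panel shows at least two
#' distinct non-NC genotype calls; a bin is covered when at least one
#' member marker is polymorphic. Reports per-bin coverage and, for every
#' non-polymorphic marker, whether its bin offers a polymorphic
#' replacement.
#'
#' @param map A `linkage_map`.
#' @param accession_calls Calls table for the accession panel (marker_id +
#'   one column per accession).
#' @return List of class `bin_polymorphism`: `bins` (per-bin tibble),
#'   `coverage` (fraction of polymorphic bins), `replaceable` (fraction of
#'   non-polymorphic markers whose bin contains a polymorphic marker).
#' @export
bin_polymorphism <- function(map, accession_calls) {
  assert_calls(accession_calls)
  acc <- calls_matrix(accession_calls)
  poly <- apply(acc, 1, function(v) {
    v <- v[v != "NC" & !is.na(v)]
    length(unique(v)) >= 2
  })
  d <- as_tibble(map) |>
    mutate(polymorphic = unname(poly[match(.data$marker_id,
                                           rownames(acc))])) |>
    mutate(polymorphic = ifelse(is.na(.data$polymorphic), FALSE,
                                .data$polymorphic))
  bins <- d |>
    group_by(.data$linkage_group, .data$bin) |>
    summarise(
      n_markers = n(),
      n_polymorphic = sum(.data$polymorphic),
      covered = any(.data$polymorphic),
      .groups = "drop"
    )
  nonpoly <- filter(d, !.data$polymorphic)
  covered_bins <- bins |> filter(.data$covered)
  replaceable <- if (nrow(nonpoly) == 0) NA_real_ else {
    mean(paste(nonpoly$linkage_group, nonpoly$bin) %in%
           paste(covered_bins$linkage_group, covered_bins$bin))
  }
  structure(
    list(bins = bins, coverage = mean(bins$covered), replaceable = replaceable),
    class = "bin_polymorphism"
  )
}

#' Simulate genotype calls of a non-parental accession panel
#'
#' Emulates genotyping additional inbred lines on the array: each line is
#' homozygous everywhere, and polymorphism (disagreement among panel
#' members) arises in haplotype stretches - polymorphism status is
#' spatially autocorrelated along each chromosome via a two-state Markov
#' chain with stationary polymorphic share `p_poly`.
#'
#' @param sim A `ril_sim` (for the marker scaffold) or markers tibble.
#' @param n_accessions Panel size.
#' @param p_poly Stationary probability that a marker is polymorphic in
#'   the panel.
#' @param persistence Probability of staying in the current polymorphism
#'   state from one marker to the next.
#' @param seed Integer seed.
#' @return Calls table (marker_id, chrom, pos_mb + accession columns).
#' @export
simulate_accession_panel <- function(sim, n_accessions = 4, p_poly = 0.53,
                                     persistence = 0.9, seed = 1L) {
  markers <- if (inherits(sim, "ril_sim")) sim$markers else sim
  with_seed(seed, {
    poly <- unlist(lapply(split(seq_len(nrow(markers)), markers$chrom), function(rows) {
      n <- length(rows)
      st <- logical(n)
      st[1] <- runif(1) < p_poly
      for (i in seq_len(n - 1)) {
        keep <- runif(1) < persistence
        st[i + 1] <- if (keep) st[i] else runif(1) < p_poly
      }
      st
    }))
    gt <- matrix("AA", nrow(markers), n_accessions,
                 dimnames = list(markers$marker_id,
                                 sprintf("ACC_%02d", seq_len(n_accessions))))
    flip <- which(poly)
    for (i in flip) {
      # at least one accession carries the alternative allele
      k <- sample.int(n_accessions - 1, 1)
      gt[i, sample.int(n_accessions, k)] <- "BB"
    }
    calls_table(markers[, marker_meta_cols(markers)], gt)
  })
}
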