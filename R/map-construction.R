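# Binned genetic-map construction from filtered RIL genotype calls:
# pairwise recombination fractions over homozygous calls (with the
# Haldane-Waddington RIL correction), single-linkage grouping on a
# two-locus independence test, greedy + 2-opt marker ordering, and
# zero-recombinant binning with cumulative Haldane cM positions.

#' Haldane mapping function and its inverse
#'
#' `haldane_cm(r) = -50 ln(1 - 2r)` converts a per-meiosis recombination
#' fraction into additive map distance (cM) under no interference;
#' `haldane_r()` inverts it. `r >= 0.5` maps to `Inf`.
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @param d Distance in cM.
#' @return Distance in cM / recombination fraction.
#' @examples
#' haldane_cm(0.25)
#' haldane_r(haldane_cm(0.25))
#' @export
haldane_cm <- function(r) {
  ifelse(r >= 0.5, Inf, -50 * log(1 - 2 * pmax(r, 0)))
}

#' @rdname haldane_cm
#' @export
haldane_r <- function(d) {
  (1 - exp(-d / 50)) / 2
}

#' Observed and meiotic recombination fraction between two markers
#'
#' Counts discordant homozygous call pairs (AA/BB vs BB/AA) over samples
#' where both markers are homozygous. In a selfed RIL the observed
#' recombinant fraction R relates to the per-meiosis fraction r by
#' R = 2r/(1+2r) (Haldane-Waddington), inverted here when
#' `ril_correction` is on.
#'
#' @param m1,m2 Character vectors of genotype calls (AA/AB/BB/NC).
#' @param ril_correction Apply the RIL correction?
#' @param min_informative Minimum number of doubly-homozygous samples; a
#'   pair below it is flagged unlinked.
#' @return Tibble (R_observed, r_meiotic, n_informative, unlinked).
#' @export
pairwise_recfrac <- function(m1, m2, ril_correction = TRUE, min_informative = 10) {
  hom <- m1 %in% c("AA", "BB") & m2 %in% c("AA", "BB")
  n <- sum(hom)
  if (n < min_informative) {
    return(tibble(R_observed = NA_real_, r_meiotic = NA_real_,
                  n_informative = n, unlinked = TRUE))
  }
  disc <- sum(m1[hom] != m2[hom])
  R <- disc / n
  r <- if (ril_correction) pmin(R / (2 * (1 - R)), 0.4999) else R
  tibble(R_observed = R, r_meiotic = pmin(r, 0.4999),
         n_informative = n, unlinked = FALSE)
}

# all-pairs recombination statistics from a calls matrix; returns list of
# matrices (R observed, r corrected, n informative, chi2 p-value of the
# two-locus independence test on the 2x2 homozygote table)
recfrac_matrices <- function(gt, ril_correction = TRUE, min_informative = 10) {
  a <- (gt == "AA") * 1
  b <- (gt == "BB") * 1
  n11 <- a %*% t(a)
  n12 <- a %*% t(b)
  n21 <- b %*% t(a)
  n22 <- b %*% t(b)
  n <- n11 + n12 + n21 + n22
  disc <- n12 + n21
  R <- ifelse(n > 0, disc / n, NA_real_)
  r <- if (ril_correction) pmin(R / (2 * (1 - R)), 0.4999) else R
  # chi-square independence on the 2x2 table
  r1 <- n11 + n12
  r2 <- n21 + n22
  c1 <- n11 + n21
  c2 <- n12 + n22
  stat <- ifelse(r1 * r2 * c1 * c2 > 0,
                 n * (n11 * n22 - n12 * n21)^2 / (r1 * r2 * c1 * c2), 0)
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  min_exp <- ifelse(n > 0, pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / pmax(n, 1), 0)
  too_few <- n < min_informative
  pv[too_few] <- 1
  R[too_few] <- NA_real_
  r[too_few] <- NA_real_
  list(R = R, r = r, n = n, p = pv, min_expected = min_exp)
}

#' Group markers into linkage groups
#'
#' Single-linkage clustering: two markers connect when the two-locus
#' independence test on their 2x2 homozygous-call table rejects at
#' `p_cutoff` (chi-square, with Fisher's exact fallback when an expected
#' cell is below 5) and their recombination fraction is below 0.5.
#' Markers missing more than `missing_threshold` of their calls are set
#' aside first; connected components smaller than `min_group_size` are
#' reported as unmapped.
#'
#' @param calls A calls table.
#' @param p_cutoff Linkage p-value cutoff.
#' @param missing_threshold Maximum tolerated NC fraction per marker.
#' @param min_group_size Groups below this size are left unmapped.
#' @param ril_correction Passed to the recombination estimator.
#' @return Tibble (marker_id, linkage_group); unmapped/excluded markers
#'   have NA linkage_group. The pairwise matrices are kept in attribute
#'   `recfrac` for downstream ordering.
#' @export
group_markers <- function(calls, p_cutoff = 1e-10, missing_threshold = 0.15,
                          min_group_size = 2, ril_correction = TRUE) {
  assert_calls(calls)
  gt <- calls_matrix(calls)
  miss <- rowMeans(gt == "NC")
  use <- miss <= missing_threshold
  gtu <- gt[use, , drop = FALSE]
  rf <- recfrac_matrices(gtu, ril_correction = ril_correction)
  pv <- rf$p
  # Fisher fallback where the chi-square approximation is doubtful
  low <- which(rf$min_expected < 5 & rf$n >= 10 & upper.tri(pv), arr.ind = TRUE)
  for (k in seq_len(nrow(low))) {
    i <- low[k, 1]; j <- low[k, 2]
    tab <- table(factor(gtu[i, ], levels = c("AA", "BB")),
                 factor(gtu[j, ], levels = c("AA", "BB")))
    if (all(dim(tab) == c(2, 2)) && sum(tab) >= 10) {
      pv[i, j] <- pv[j, i] <- fisher.test(tab)$p.value
    }
  }
  linked <- pv < p_cutoff & !is.na(rf$R) & rf$R < 0.5
  diag(linked) <- TRUE
  comp <- connected_components(linked)
  sizes <- table(comp)
  comp_ids <- names(sizes)[sizes >= min_group_size]
  # stable group numbering by first marker occurrence
  lg <- rep(NA_integer_, nrow(gt))
  keep_comp <- comp %in% as.integer(comp_ids)
  renumber <- match(comp, unique(comp[keep_comp]))
  lg[use][keep_comp] <- renumber[keep_comp]
  out <- tibble(marker_id = rownames(gt), linkage_group = lg)
  attr(out, "recfrac") <- list(
    marker_id = rownames(gtu),
    R = rf$R, r = rf$r, n = rf$n
  )
  out
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# objective: sum of adjacent recombination fractions along a path
path_cost <- function(order, r) {
  sum(r[cbind(order[-length(order)], order[-1])])
}

#' Order the markers of one linkage group
#'
#' Minimizes the sum of adjacent recombination fractions along the
#' chain. Groups of up to 10 markers are solved exactly by dynamic
#' programming over subsets (Held-Karp); larger groups use greedy chain
#' construction (start from the closest pair, repeatedly append the
#' marker nearest to either end) followed by 2-opt segment reversals
#' until no improvement. Output orientation is canonicalized so the
#' first marker id sorts before the last.
#'
#' @param marker_ids Markers of the group.
#' @param r Recombination-fraction matrix with dimnames covering
#'   `marker_ids` (NA entries treated as 0.5).
#' @param exact_max Largest group size solved exactly.
#' @return Character vector: the ordered marker ids.
#' @export
order_markers <- function(marker_ids, r, exact_max = 10) {
  marker_ids <- sort(marker_ids)
  m <- length(marker_ids)
  if (m <= 2) return(marker_ids)
  rr <- r[marker_ids, marker_ids]
  rr[is.na(rr)] <- 0.5
  diag(rr) <- Inf

  if (m <= exact_max) {
    ids <- marker_ids[held_karp_path(rr)]
    if (ids[1] > ids[length(ids)]) ids <- rev(ids)
    return(ids)
  }

  # greedy chain: seed with the globally closest pair
  seed <- which(rr == min(rr), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
  chain <- as.integer(seed)
  remaining <- setdiff(seq_len(m), chain)
  while (length(remaining) > 0) {
    head_d <- rr[chain[1], remaining]
    tail_d <- rr[chain[length(chain)], remaining]
    if (min(head_d) <= min(tail_d)) {
      pick <- remaining[which.min(head_d)]
      chain <- c(pick, chain)
    } else {
      pick <- remaining[which.min(tail_d)]
      chain <- c(chain, pick)
    }
    remaining <- setdiff(remaining, pick)
  }

  # 2-opt: reverse any segment that lowers the adjacent-r sum; reversing
  # chain[i..j] only swaps the two boundary edges, so the gain is O(1)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (i == 1 && j == m) next
        old <- 0
        new <- 0
        if (i > 1) {
          old <- old + rr[chain[i - 1], chain[i]]
          new <- new + rr[chain[i - 1], chain[j]]
        }
        if (j < m) {
          old <- old + rr[chain[j], chain[j + 1]]
          new <- new + rr[chain[i], chain[j + 1]]
        }
        if (new < old - 1e-12) {
          chain[i:j] <- rev(chain[i:j])
          improved <- TRUE
        }
      }
    }
  }

  ids <- marker_ids[chain]
  if (ids[1] > ids[length(ids)]) ids <- rev(ids)
  ids
}

# exact minimum-cost Hamiltonian path by subset dynamic programming
held_karp_path <- function(rr) {
  m <- nrow(rr)
  full <- bitwShiftL(1L, m) - 1L
  dp <- matrix(Inf, full, m)       # dp[S, j]: best path over set S ending at j
  parent <- matrix(0L, full, m)
  for (j in seq_len(m)) dp[bitwShiftL(1L, j - 1L), j] <- 0
  for (S in seq_len(full)) {
    for (j in seq_len(m)) {
      if (!bitwAnd(S, bitwShiftL(1L, j - 1L))) next
      base <- dp[S, j]
      if (!is.finite(base)) next
      for (k in seq_len(m)) {
        if (bitwAnd(S, bitwShiftL(1L, k - 1L))) next
        S2 <- bitwOr(S, bitwShiftL(1L, k - 1L))
        cand <- base + rr[j, k]
        if (cand < dp[S2, k]) {
          dp[S2, k] <- cand
          parent[S2, k] <- j
        }
      }
    }
  }
  end <- which.min(dp[full, ])
  path <- integer(m)
  S <- full
  j <- end
  for (i in rev(seq_len(m))) {
    path[i] <- j
    pj <- parent[S, j]
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  path
}

#' Collapse an ordered group into map bins
#'
#' Adjacent markers with zero observed recombinants share a bin; bin cM
#' positions are cumulative Haldane distances (from the corrected r of
#' the markers straddling each bin boundary), starting at 0.
#'
#' @param ordered_ids Ordered marker ids of one group.
#' @param R,r Observed / corrected recombination-fraction matrices.
#' @return Tibble (marker_id, bin, cm).
#' @export
bin_markers <- function(ordered_ids, R, r) {
  m <- length(ordered_ids)
  if (m == 1) return(tibble(marker_id = ordered_ids, bin = 1L, cm = 0))
  adj_R <- R[cbind(ordered_ids[-m], ordered_ids[-1])]
  adj_r <- r[cbind(ordered_ids[-m], ordered_ids[-1])]
  adj_R[is.na(adj_R)] <- 0.5
  adj_r[is.na(adj_r)] <- 0.4999
  new_bin <- adj_R > 0
  bin <- cumsum(c(TRUE, new_bin))
  d <- haldane_cm(adj_r)
  d[!new_bin] <- 0
  cm_marker <- cumsum(c(0, d))
  tibble(marker_id = ordered_ids, bin = as.integer(bin),
         cm = cm_marker)
}

#' Build a binned linkage map from filtered genotype calls
#'
#' Runs grouping, per-group ordering and binning, and re-attaches
#' redundancy-group members (from [dedup_redundant()]) to their
#' representative's bin.
#'
#' @param calls A filtered calls table (e.g. from [filter_markers()]).
#' @param p_cutoff,missing_threshold,min_group_size,ril_correction See
#'   [group_markers()].
#' @return A `linkage_map`: tibble (marker_id, linkage_group, bin, cm,
#'   chrom, pos_mb when available), ordered by group and position, with a
#'   `groups` attribute summarizing each linkage group.
#' @export
build_linkage_map <- function(calls, p_cutoff = 1e-10, missing_threshold = 0.15,
                              min_group_size = 2, ril_correction = TRUE) {
  assert_calls(calls)
  grouping <- group_markers(calls, p_cutoff = p_cutoff,
                            missing_threshold = missing_threshold,
                            min_group_size = min_group_size,
                            ril_correction = ril_correction)
  rf <- attr(grouping, "recfrac")
  dimnames(rf$R) <- dimnames(rf$r) <- list(rf$marker_id, rf$marker_id)
  groups <- grouping |> filter(!is.na(.data$linkage_group))
  if (nrow(groups) == 0) {
    warn("no linkage groups formed at this p cutoff / sample size")
    map <- tibble(linkage_group = integer(), marker_id = character(),
                  bin = integer(), cm = numeric())
  } else {
    map <- purrr::map_dfr(split(groups$marker_id, groups$linkage_group),
                          function(ids) {
      ord <- order_markers(ids, rf$r)
      bin_markers(ord, rf$R, rf$r)
    }, .id = "linkage_group") |>
      mutate(linkage_group = as.integer(.data$linkage_group))
  }

  dd <- attr(calls, "dedup_groups")
  if (!is.null(dd)) {
    extra <- dd |>
      filter(.data$member != .data$representative,
             .data$representative %in% map$marker_id) |>
      inner_join(map, by = c(representative = "marker_id")) |>
      select(marker_id = "member", "linkage_group", "bin", "cm")
    map <- bind_rows(map, extra)
  }
  meta <- calls[, intersect(c("marker_id", "chrom", "pos_mb"), names(calls))]
  if (ncol(meta) > 1) {
    map <- left_join(map, meta, by = "marker_id")
  }
  map <- arrange(map, .data$linkage_group, .data$cm, .data$bin, .data$marker_id)
  attr(map, "groups") <- map |>
    group_by(.data$linkage_group) |>
    summarise(
      n_markers = n(),
      n_bins = dplyr::n_distinct(.data$bin),
      length_cm = max(.data$cm),
      .groups = "drop"
    )
  class(map) <- c("linkage_map", class(map))
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("<linkage_map> %d markers in %d group(s), %d bins, %.1f cM total\n",
              nrow(x), nrow(g), sum(g$n_bins), sum(g$length_cm)))
  NextMethod()
}
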