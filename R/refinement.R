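# Rule-based refinement of genotype calls along the map order. Two rules,
# applied per sample per linkage group:
#   * region rule: a mosaic stretch of 12 or more loci (bounded by uniform
#     blocks, internally switching among two or more call values in short
#     runs) is set entirely to no-call;
#   * locus rule: a single locus differing from both immediate neighbors
#     is overwritten by the common call of six uniform flanking loci on
#     each side, or set to no-call when the flanks are not uniform.
# Loci within one flank width of a chromosome end are never modified.

#' Refine isolated locus calls from their flanking loci
#'
#' @param seq_calls Character vector of calls (AA/AB/BB/NC) along one
#'   linkage group for one sample, in map order.
#' @param flank Required number of uniform consecutive loci on each side.
#' @return The refined call vector.
#' @export
refine_locus <- function(seq_calls, flank = 6) {
  n <- length(seq_calls)
  if (n < 2 * flank + 1) return(seq_calls)
  out <- seq_calls
  for (i in seq(flank + 1, n - flank)) {
    x <- seq_calls[i]
    if (x == seq_calls[i - 1] || x == seq_calls[i + 1]) next
    left <- seq_calls[(i - flank):(i - 1)]
    right <- seq_calls[(i + 1):(i + flank)]
    left_u <- length(unique(left)) == 1 && left[1] != "NC"
    right_u <- length(unique(right)) == 1 && right[1] != "NC"
    if (left_u && right_u && left[1] == right[1]) {
      out[i] <- left[1]
    } else {
      out[i] <- "NC"
    }
  }
  out
}

#' Blank out long mosaic regions
#'
#' A maximal stretch of consecutive short runs (each shorter than
#' `min_block`) containing at least two distinct call values and spanning
#' `region_len` or more loci is considered an unresolvable mosaic and set
#' entirely to no-call.
#'
#' @inheritParams refine_locus
#' @param region_len Minimum mosaic length (loci) triggering the rule.
#' @param min_block Run length from which a block counts as uniform
#'   (bounding the mosaic) rather than part of it.
#' @return The refined call vector.
#' @export
refine_region <- function(seq_calls, region_len = 12, min_block = 3) {
  runs <- call_runs(seq_calls)
  mosaic <- runs$length < min_block
  if (!any(mosaic)) return(seq_calls)
  out <- seq_calls
  rr <- rle(mosaic)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1
  for (k in seq_along(rr$values)) {
    if (!rr$values[k]) next
    seg_runs <- runs[starts[k]:ends[k], ]
    loci <- sum(seg_runs$length)
    if (loci >= region_len && length(unique(seg_runs$value)) >= 2) {
      out[seg_runs$start[1]:seg_runs$end[nrow(seg_runs)]] <- "NC"
    }
  }
  out
}

#' Count no-call regions
#'
#' @inheritParams refine_locus
#' @return Number of maximal runs of consecutive NC.
#' @export
count_nc_regions <- function(seq_calls) {
  runs <- call_runs(seq_calls)
  sum(runs$value == "NC")
}

#' Refine a calls table along the map order
#'
#' Applies [refine_region()] then [refine_locus()] to every sample within
#' every linkage group (regions are the larger pathology, so they are
#' cleaned first). The input must already be ordered along the map; pass
#' a `linkage_map` to order and split by group.
#'
#' @param calls A calls table.
#' @param map Optional `linkage_map`; when given, markers are restricted
#'   and reordered to the map and grouped by linkage group, otherwise the
#'   table's own `chrom` column (in row order) defines the groups.
#' @param flank,region_len,min_block Rule parameters.
#' @return List of class `refined_calls`: `calls` (refined table), `diff`
#'   (tibble sample/marker_id/old/new) and `nc_regions` (named count per
#'   sample, summed over groups).
#' @export
refine_genotypes <- function(calls, map = NULL, flank = 6, region_len = 12,
                             min_block = 3) {
  assert_calls(calls)
  if (!is.null(map)) {
    ord <- map$marker_id[map$marker_id %in% calls$marker_id]
    calls <- calls[match(ord, calls$marker_id), ]
    group <- map$linkage_group[match(ord, map$marker_id)]
  } else if ("chrom" %in% names(calls)) {
    group <- calls$chrom
  } else {
    group <- rep(1L, nrow(calls))
  }
  gt <- calls_matrix(calls)
  refined <- gt
  nc_regions <- setNames(integer(ncol(gt)), colnames(gt))
  for (g in unique(group)) {
    rows <- which(group == g)
    for (j in seq_len(ncol(gt))) {
      v <- refine_region(gt[rows, j], region_len = region_len,
                         min_block = min_block)
      v <- refine_locus(v, flank = flank)
      refined[rows, j] <- v
      nc_regions[j] <- nc_regions[j] + count_nc_regions(v)
    }
  }
  changed <- which(refined != gt, arr.ind = TRUE)
  diff <- tibble(
    sample = colnames(gt)[changed[, 2]],
    marker_id = rownames(gt)[changed[, 1]],
    old = gt[changed],
    new = refined[changed]
  )
  out <- list(
    calls = calls_table(calls[, marker_meta_cols(calls)], refined),
    diff = diff,
    nc_regions = nc_regions
  )
  class(out) <- "refined_calls"
  out
}

#' @export
print.refined_calls <- function(x, ...) {
  cat(sprintf("<refined_calls> %d calls modified across %d samples\n",
              nrow(x$diff), length(x$nc_regions)))
  invisible(x)
}
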