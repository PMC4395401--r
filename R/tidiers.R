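# broom-style methods so fitted objects drop into tidy workflows.

#' Tidy a linkage map
#'
#' @param x A `linkage_map`.
#' @param ... Unused.
#' @return One row per marker (marker_id, linkage_group, bin, cm, and
#'   genome coordinates when carried).
#' @export
tidy.linkage_map <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.linkage_map
#' @return `glance()`: one row per linkage group (n_markers, n_bins,
#'   length_cm, median bin interval).
#' @export
glance.linkage_map <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$linkage_group) |>
    summarise(
      n_markers = n(),
      n_bins = dplyr::n_distinct(.data$bin),
      length_cm = max(.data$cm),
      median_bin_interval_cm = {
        pos <- sort(unique(.data$cm[!duplicated(.data$bin)]))
        if (length(pos) > 1) median(diff(pos)) else NA_real_
      },
      .groups = "drop"
    )
}

#' Tidy genotype calls
#'
#' @param x A `genotype_calls` object.
#' @param ... Unused.
#' @return Long tibble (marker_id, sample, call, confidence).
#' @export
tidy.genotype_calls <- function(x, ...) {
  calls <- x$calls |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols(x$calls)),
                        names_to = "sample", values_to = "call")
  conf <- x$confidence |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols(x$confidence)),
                        names_to = "sample", values_to = "confidence")
  left_join(
    select(calls, "marker_id", "sample", "call"),
    select(conf, "marker_id", "sample", "confidence"),
    by = c("marker_id", "sample")
  )
}

#' @rdname tidy.genotype_calls
#' @return `glance()`: one-row summary (markers, samples, call-rate, GTS
#'   composition).
#' @export
glance.genotype_calls <- function(x, ...) {
  gt <- calls_matrix(x$calls)
  tibble(
    n_markers = nrow(gt),
    n_samples = ncol(gt),
    call_rate = mean(gt != "NC"),
    het_rate = mean(gt == "AB"),
    gts_perfect = sum(x$models$gts_status == "GTS_perfect"),
    gts_one_off = sum(x$models$gts_status == "GTS_one_off"),
    rejected = sum(x$models$gts_status == "rejected")
  )
}

#' Tidy a distortion scan
#'
#' @param x A `distortion_scan`.
#' @param ... Unused.
#' @return The per-marker records tibble.
#' @export
tidy.distortion_scan <- function(x, ...) {
  x$records
}

#' @rdname tidy.distortion_scan
#' @export
glance.distortion_scan <- function(x, ...) {
  tibble(
    n_markers = nrow(x$records),
    n_significant = sum(x$records$significant),
    n_intervals = nrow(x$intervals),
    alpha = x$alpha
  )
}
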