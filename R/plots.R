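# ggplot2 views of the main result types.

#' Plot training clusters and calls for one SNP
#'
#' @param summarized A `summarized_signals` tibble.
#' @param snp SNP id to plot.
#' @param training Training design; defaults to the table's attribute.
#' @return A ggplot.
#' @export
plot_signal_clusters <- function(summarized, snp,
                                 training = attr(summarized, "training")) {
  d <- summarized |>
    filter(.data$snp_id == snp) |>
    left_join(training, by = "sample") |>
    mutate(set = ifelse(is.na(.data$expected_call), "test",
                        paste("training", .data$expected_call)))
  ggplot2::ggplot(d, ggplot2::aes(.data$signal_a, .data$signal_b,
                                  colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "A signal (log2)", y = "B signal (log2)", title = snp,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn build_linkage_map Plot marker map positions per linkage
#'   group (cM vs physical Mb when available).
#' @param object A `linkage_map`.
#' @param ... Unused.
#' @export
autoplot.linkage_map <- function(object, ...) {
  d <- as_tibble(object)
  if ("pos_mb" %in% names(d) && any(!is.na(d$pos_mb))) {
    ggplot2::ggplot(d, ggplot2::aes(.data$pos_mb, .data$cm)) +
      ggplot2::geom_point(size = 0.5, alpha = 0.6) +
      ggplot2::facet_wrap(~linkage_group, scales = "free") +
      ggplot2::labs(x = "physical position (Mb)", y = "map position (cM)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(factor(.data$linkage_group), .data$cm)) +
      ggplot2::geom_point(shape = 95, size = 4) +
      ggplot2::labs(x = "linkage group", y = "map position (cM)") +
      ggplot2::theme_minimal()
  }
}

#' Plot a local recombination-rate profile
#'
#' @param profile Tibble from [local_recomb_rate()].
#' @param log_scale Plot log10 rate?
#' @return A ggplot.
#' @export
plot_recomb_profile <- function(profile, log_scale = TRUE) {
  y <- if (log_scale) "log10_rate" else "rate_cm_mb"
  ggplot2::ggplot(profile, ggplot2::aes(.data$mid_mb, .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~linkage_group, scales = "free_x") +
    ggplot2::labs(x = "physical position (Mb)",
                  y = if (log_scale) "log10 recombination rate (cM/Mb)"
                      else "recombination rate (cM/Mb)") +
    ggplot2::theme_minimal()
}

#' @describeIn segregation_scan Plot the distortion scan: per-marker
#'   delta = p(AA) - p(BB) with the spline smooth and SDR intervals shaded.
#' @param object A `distortion_scan`.
#' @param ... Unused.
#' @export
autoplot.distortion_scan <- function(object, ...) {
  r <- object$records
  p <- ggplot2::ggplot(r, ggplot2::aes(.data$pos_mb, .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$delta_smooth), linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "physical position (Mb)", y = "p(AA) - p(BB)") +
    ggplot2::theme_minimal()
  if (nrow(object$intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$start_mb, xmax = .data$end_mb,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p
}
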