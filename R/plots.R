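#' Virtual-4C contact profile for one bait
#'
#' Normalized (or raw) contact counts along the bait chromosome, with
#' significant fragments highlighted and the bait position marked; the
#' package's analogue of a per-bait virtual-4C track.
#'
#' @param calls A `sig_calls` object from [call_interactions()].
#' @param bait Bait name to plot.
#' @return A ggplot object.
#' @export
plot_contact_profile <- function(calls, bait) {
  tab <- calls$table[calls$table$bait == bait, ]
  if (!nrow(tab)) abort(paste0("no calls for bait ", bait))
  ggplot2::ggplot(tab, ggplot2::aes(x = (start + end) / 2, y = count,
                                    fill = significant)) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = "read count",
                  title = paste0("Contact profile: ", bait)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sig_calls <- function(object, bait = NULL, ...) {
  plot_contact_profile(object, bait %||% object$table$bait[1])
}

#' Bait-by-fragment contact heatmap
#'
#' Normalized counts per (bait, fragment) cell on one chromosome; masked
#' bait-proximal cells are blank.
#'
#' @param masked_contacts Normalized contacts with a `masked` column.
#' @param chrom Chromosome to display.
#' @return A ggplot object.
#' @export
plot_contact_heatmap <- function(masked_contacts, chrom) {
  cc <- masked_contacts[masked_contacts$chrom == chrom, ]
  val <- if ("norm_count" %in% names(cc)) "norm_count" else "count"
  cc$value <- ifelse(cc$masked, NA_real_, cc[[val]])
  ggplot2::ggplot(cc, ggplot2::aes(x = (start + end) / 2, y = bait,
                                   fill = log10(value + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  fill = "log10(count + 1)") +
    ggplot2::theme_minimal()
}

#' Ligation-frequency distance-decay plot
#'
#' @param decay Result of [fit_decay()].
#' @return A ggplot object.
#' @export
plot_decay <- function(decay) {
  ggplot2::ggplot(decay$profile, ggplot2::aes(distance, density)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "ligation density (per bp)",
                  subtitle = sprintf("fitted slope %.2f", decay$slope)) +
    ggplot2::theme_minimal()
}
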