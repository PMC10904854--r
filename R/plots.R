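#' Overlaid normalized R_g distributions
#'
#' The canonical reference-vs-perturbed view: normalized frequency
#' distributions of per-frame R_g, reference in black and perturbed in
#' red.
#'
#' @param reference,perturbed `rg` tibbles or numeric vectors
#'   (`perturbed` optional).
#' @param bin_width Histogram bin width in Angstrom.
#' @return A ggplot object.
#' @export
plot_rg_distribution <- function(reference, perturbed = NULL,
                                 bin_width = 1) {
  hist_df <- function(x, cond) {
    dplyr::mutate(rg_histogram(x, bin_width = bin_width), condition = cond)
  }
  df <- hist_df(reference, "reference")
  if (!is.null(perturbed)) {
    df <- dplyr::bind_rows(df, hist_df(perturbed, "perturbed"))
  }
  df$condition <- factor(df$condition, c("reference", "perturbed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$frequency,
    colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(reference = "black", perturbed = "red")) +
    ggplot2::labs(x = expression(R[g] ~ "(Å)"),
      y = "Normalized frequency", colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot an R_g-energy landscape
#'
#' Scatter of R_g against min-max normalized energy, colored by condition
#' (reference black, perturbed red).
#'
#' @param landscape A tibble from [rg_landscape()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  cols <- c("black", "red", "grey40", "orange")
  conds <- unique(landscape$condition)
  ggplot2::ggplot(landscape, ggplot2::aes(.data$rg, .data$energy_norm,
    colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(cols[seq_along(conds)], conds)) +
    ggplot2::labs(x = expression(R[g] ~ "(Å)"),
      y = "Normalized energy", colour = NULL) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a switch report
#'
#' Per-tile switch components: spread reduction, tail depletion and KS
#' distance as grouped bars, flagged tiles marked.
#'
#' @param object A `switch_report` from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot switch_report
#' @export
autoplot.switch_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "tile", "spread_reduction",
      "tail_depletion", "ks_D", "flagged"),
    cols = c("spread_reduction", "tail_depletion", "ks_D"),
    names_to = "component", values_to = "value"
  )
  df$tile <- factor(df$tile, unique(df$tile))
  ggplot2::ggplot(df, ggplot2::aes(.data$tile, .data$value,
    fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = dplyr::filter(dplyr::distinct(df, .data$tile, .data$flagged),
        .data$flagged),
      ggplot2::aes(.data$tile, y = 1.05), inherit.aes = FALSE, shape = 25,
      fill = "red", size = 2
    ) +
    ggplot2::labs(x = NULL, y = "Component value", fill = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}

#' Plot a per-residue binding decomposition
#'
#' Mean per-residue binding-energy contributions with SD error bars,
#' highlighting residues at or below the reporting threshold.
#'
#' @param object A `binding_result` from [binding_energy()].
#' @param threshold Highlight threshold in kcal/mol (default -2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_result
#' @export
autoplot.binding_result <- function(object, threshold = -2, ...) {
  df <- dplyr::mutate(object$per_residue,
    label = paste0(.data$chain, .data$residue_id),
    significant = .data$mean <= threshold)
  df$label <- factor(df$label, df$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$mean,
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
      ymax = .data$mean + .data$sd), width = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "goldenrod",
      `FALSE` = "grey70"), guide = "none") +
    ggplot2::labs(x = NULL, y = "Binding energy (kcal/mol)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}

#' Export a tidy table as TSV
#'
#' Convenience writer used for profile, tile, series and report tables.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
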