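#' Kurtosis ranking plot
#'
#' Bar chart of each composed sub-band's |excess kurtosis|, ordered by
#' selection rank, with the selected bands highlighted. Useful to see which
#' levels/orientations drive the estimate.
#'
#' @param fit a `stain_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stain_fit <- function(fit, ...) {
  tb <- fit$subbands
  tb$band <- paste0("L", tb$level, tb$orientation)
  tb$selected <- !is.na(tb$rank) & tb$rank <= fit$params$n_subbands
  tb <- tb[order(tb$rank), ]
  tb$band <- factor(tb$band, levels = tb$band)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$band, y = .data$abs_k,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               name = "selected") +
    ggplot2::labs(x = "sub-band (level, orientation)", y = "|excess kurtosis|",
                  title = "Sub-band non-Gaussianity ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Density map heat plot
#'
#' @param fit a `stain_fit`.
#' @param stain_index which density map (default 1 = haematoxylin-like).
#' @param clip clip negative densities for display (default TRUE).
#' @return A ggplot object (raster heat map).
#' @export
plot_density_map <- function(fit, stain_index = 1, clip = TRUE) {
  plane <- density_plane(fit$densities, stain_index, clip = clip)
  df <- expand.grid(col = seq_len(ncol(plane)), row = seq_len(nrow(plane)))
  df$density <- as.vector(t(plane))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Density:", fit$densities$labels[stain_index]),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement plot
#'
#' Scatter of per-pixel differences against means with the bias and 95%
#' limits of agreement drawn as horizontal lines.
#'
#' @param ba a `bland_altman` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(ba, ...) {
  df <- data.frame(mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "#2166ac") +
    ggplot2::labs(x = "mean density (estimate, truth)",
                  y = "difference (estimate - truth)",
                  title = sprintf("Bland-Altman: bias %.3f, limits [%.3f, %.3f]",
                                  ba$bias, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}
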