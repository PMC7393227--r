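#' @import ggplot2
NULL

#' Volcano plot of one or more DE contrasts
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot: -log10 adjusted p against log2 fold change, coloured
#'   by DE status, faceted by contrast.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(contrast = paste0(.data$condition, " t", .data$time_h))
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                 colour = .data$status)) +
    geom_point(size = 0.4, alpha = 0.6) +
    scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                   ns = "grey70")) +
    facet_wrap(~contrast) +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         colour = "status") +
    theme_bw()
}

#' Bar chart of DE gene counts per contrast
#'
#' The classic induced/repressed bar summary across conditions and time
#' points.
#'
#' @param de A `de_result` or the output of [de_summary()].
#' @return A ggplot.
#' @export
plot_de_summary <- function(de) {
  df <- if (inherits(de, "de_result")) de_summary(de) else de
  df <- df |>
    tidyr::pivot_longer(c("up", "down"), names_to = "direction",
                        values_to = "n") |>
    mutate(n_signed = ifelse(.data$direction == "up", .data$n, -.data$n))
  ggplot(df, aes(x = factor(.data$time_h), y = .data$n_signed,
                 fill = .data$direction)) +
    geom_col() +
    facet_wrap(~condition, scales = "free_x") +
    scale_fill_manual(values = c(up = "firebrick", down = "steelblue")) +
    labs(x = "time (h)", y = "DE genes (down < 0 < up)", fill = NULL) +
    theme_bw()
}

#' Heatmap of module-trait correlations
#'
#' @param object A `module_trait_correlation`.
#' @param ... Unused.
#' @return A ggplot tile map of Pearson r; non-significant cells are
#'   crossed out.
#' @export
autoplot.module_trait_correlation <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile(colour = "white") +
    geom_point(data = df |> filter(!.data$significant),
               shape = 4, size = 2, colour = "grey30") +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot an exponential decay fit over its data
#'
#' @param object An `exp_decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  grid <- tibble(time_h = seq(min(object$time_h), max(object$time_h),
                              length.out = 100))
  grid$value <- object$a * exp(-object$k * grid$time_h)
  ggplot(tibble(time_h = object$time_h, value = object$values),
         aes(.data$time_h, .data$value)) +
    geom_point() +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "time (h)", y = "Fv/Fm",
         subtitle = sprintf("k = %.3g /h", object$k)) +
    theme_bw()
}

#' Bar chart of exclusive DE condition-set counts
#'
#' @param object An `upset_membership`.
#' @param ... Unused.
#' @return A ggplot of counts per exclusive condition set, stacked by
#'   module.
#' @export
autoplot.upset_membership <- function(object, ...) {
  df <- object$counts |>
    mutate(set = stats::reorder(.data$set, -.data$n, sum))
  ggplot(df, aes(x = .data$set, y = .data$n,
                 fill = factor(.data$module))) +
    geom_col() +
    labs(x = "condition set", y = "genes", fill = "module") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
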