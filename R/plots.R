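#' @importFrom ggplot2 ggplot aes geom_tile geom_col scale_fill_gradient2
#'   scale_fill_viridis_c labs theme_minimal theme element_text autoplot
NULL

#' Heatmap of a concordance matrix
#'
#' @param object an `ens_concordance`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ens_concordance <- function(object, ...) {
  stat <- statistic_name(object)
  p <- ggplot(object, aes(x = .data$col_id, y = .data$row_id,
                          fill = .data$value)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = stat) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
  if (stat %in% c("spearman_rho", "nes", "mean_module_score")) {
    p + scale_fill_gradient2(low = "#2166AC", mid = "white",
                             high = "#B2182B", midpoint = 0)
  } else {
    p + scale_fill_viridis_c(limits = c(0, 1))
  }
}

#' Mono/multi-transmitter profile bar chart
#'
#' @param object an `ens_calls` object from [classify_neurochem()]
#' @param ... unused
#' @return a ggplot of the multiplicity profile over assigned cells
#' @export
autoplot.ens_calls <- function(object, ...) {
  prof <- multiplicity_profile(object)
  ggplot(dplyr::filter(prof, .data$multiplicity_bin != "0"),
         aes(x = .data$multiplicity_bin, y = .data$frac_assigned)) +
    geom_col(fill = "#4477AA") +
    labs(x = "neurotransmitter classes per neuron",
         y = "fraction of assigned cells",
         title = paste0("multi-transmitter profile (",
                        attr(object, "layer"), " layer)")) +
    theme_minimal()
}

#' Neurochemical class abundance per cluster, as a heatmap
#'
#' @param calls an `ens_calls` object
#' @param cell_meta cell metadata with `barcode` and `cluster`
#' @return a ggplot
#' @export
plot_class_by_cluster <- function(calls, cell_meta) {
  df <- class_by_cluster(calls, cell_meta)
  ggplot(df, aes(x = .data$class, y = .data$cluster,
                 fill = .data$fraction)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "fraction called") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Held-out confusion heatmap of a transfer model
#'
#' @param object an `ens_transfer`
#' @param ... unused
#' @return a ggplot of row-normalized held-out confusion fractions
#' @export
autoplot.ens_transfer <- function(object, ...) {
  tab <- as.data.frame(object$heldout_confusion)
  tab <- tab |>
    group_by(.data$truth) |>
    mutate(frac = .data$Freq / sum(.data$Freq)) |>
    ungroup()
  ggplot(tab, aes(x = .data$label, y = .data$truth, fill = .data$frac)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "assigned", y = "true cluster", fill = "fraction") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @export
ggplot2::autoplot
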