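#' Plot an enrichment report
#'
#' Bar plot of the observed DMC statistic against the control-subset mean
#' (error bars: subset mean +/- one SD) per proximity bin or repeat class.
#'
#' @param object An `enrich_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrich_tbl <- function(object, ...) {
  key <- attr(object, "key")
  long <- tibble::as_tibble(object) %>%
    dplyr::mutate(.key = factor(as.character(.data[[key]]),
                                levels = unique(as.character(.data[[key]])))) %>%
    dplyr::select(".key", "observed", "subset_mean", "subset_sd") %>%
    tidyr::pivot_longer(c("observed", "subset_mean"),
                        names_to = "set", values_to = "value") %>%
    dplyr::mutate(
      set = dplyr::recode(.data$set, observed = "DMCs", subset_mean = "r-Cs"),
      sd = ifelse(.data$set == "r-Cs", .data$subset_sd, NA_real_)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.key, y = .data$value,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::labs(x = key, y = "statistic", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sample PCA scores
#'
#' @param object A `meth_pca` from [pca_samples()].
#' @param components Length-2 integer, which components to draw; default 1:2.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_pca <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ve <- round(100 * object$var_explained[components], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste0(pcs[1], " (", ve[1], "%)"),
                  y = paste0(pcs[2], " (", ve[2], "%)"),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot next-CpG distance-class fractions
#'
#' Grouped bar plot of the distance-class composition (1 bp dyad, short
#' range, long range) for the DMC set and each control subset.
#'
#' @param classes The `distance_classes` tibble from [stretch_enrichment()].
#' @return A ggplot object.
#' @export
plot_distance_classes <- function(classes) {
  ggplot2::ggplot(classes,
                  ggplot2::aes(x = .data$class, y = .data$fraction,
                               fill = .data$set == "DMC",
                               group = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "#F4A582"),
                               labels = c(`TRUE` = "DMCs", `FALSE` = "r-Cs"),
                               name = NULL) +
    ggplot2::labs(x = "distance to next CpG", y = "fraction of sites") +
    ggplot2::theme_minimal()
}
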