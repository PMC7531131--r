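# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   geom_text labs facet_wrap scale_y_reverse theme_bw
#' @export
ggplot2::autoplot

#' Soft-threshold scan plot
#'
#' Scale-free fit index and mean connectivity as functions of the candidate
#' power, mirroring the usual two-panel topology diagnostic.
#'
#' @param scan scan tibble from [pick_soft_threshold()].
#' @param r2_cut horizontal guide at the fit threshold.
#' @return a ggplot object.
#' @export
plot_soft_threshold <- function(scan, r2_cut = 0.8) {
  d <- tidyr::pivot_longer(
    select(scan, "power", "fit_r2", "mean_k"),
    c("fit_r2", "mean_k"),
    names_to = "panel", values_to = "value"
  )
  d$panel <- factor(d$panel, c("fit_r2", "mean_k"),
                    c("scale-free fit index", "mean connectivity"))
  guide <- tibble(panel = factor("scale-free fit index",
                                 levels(d$panel)), y = r2_cut)
  ggplot(d, aes(x = .data$power, y = .data$value)) +
    geom_line(colour = "grey60") +
    geom_text(aes(label = .data$power), size = 3) +
    geom_hline(data = guide, aes(yintercept = .data$y),
               linetype = 2, colour = "red") +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "soft-thresholding power", y = NULL) +
    theme_bw()
}

#' Preservation composite scatter plots
#'
#' `Z_summary` and `medianRank` against module size, with the usual guides at
#' `Z_summary = 2` and `10`. Strongly preserved modules sit high on the left
#' panel; perturbed modules sit low with large median ranks.
#'
#' @param object a `module_preservation`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot module_preservation
#' @export
autoplot.module_preservation <- function(object, ...) {
  s <- object$summary
  d <- bind_rows(
    tibble(module = s$module, size = s$size, panel = "Z_summary",
           value = s$z_summary, class = s$class),
    tibble(module = s$module, size = s$size, panel = "medianRank",
           value = s$median_rank, class = s$class)
  )
  guides <- tibble(panel = "Z_summary", y = c(2, 10))
  ggplot(d, aes(x = .data$size, y = .data$value, colour = .data$class)) +
    geom_hline(data = guides, aes(yintercept = .data$y),
               linetype = 2, colour = "grey40") +
    geom_point(size = 2) +
    geom_text(aes(label = .data$module), vjust = -0.8, size = 3,
              show.legend = FALSE) +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "module size (genes)", y = NULL, colour = "class") +
    theme_bw()
}

#' Methylation level vs a network property
#'
#' Scatter of per-gene methylation level against a chosen property, split by
#' preservation stratum, with least-squares lines.
#'
#' @inheritParams regress_level_on_property
#' @return a ggplot object.
#' @export
plot_level_vs_property <- function(levels, props,
                                   property = c("kim", "kme", "dc_score"),
                                   region = c("body", "regulatory")) {
  property <- match.arg(property)
  region <- match.arg(region)
  d <- integration_table(levels, props, region)
  d <- d[!is.na(d[[property]]), , drop = FALSE]
  ggplot(d, aes(x = .data[[property]], y = .data$level)) +
    geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red") +
    facet_wrap(~stratum) +
    labs(x = property, y = sprintf("methylation level (%s)", region)) +
    theme_bw()
}
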