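#' Plot a cumulative tract-length curve
#'
#' @param object A `roh_cumulative` tibble from [cumulative_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_cumulative
#' @export
autoplot.roh_cumulative <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length / 1e6, y = .data$frac_ge)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Tract length (Mb)", y = "Fraction of tracts ≥ length") +
    ggplot2::theme_minimal()
}

#' Plot a resampling null envelope with an observed curve
#'
#' @param object A `roh_null` from [resample_null()].
#' @param observed Optional tract tibble whose curve is overlaid in red.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_null
#' @export
autoplot.roh_null <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$envelope, ggplot2::aes(x = .data$length / 1e6)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(data = object$full_curve,
                       ggplot2::aes(y = .data$frac_ge), colour = "goldenrod") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Tract length (Mb)", y = "Fraction of tracts ≥ length") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- eval_cumulative(observed$length, object$envelope$length, object$weight)
    p <- p + ggplot2::geom_line(data = obs, ggplot2::aes(y = .data$frac_ge),
                                colour = "red")
  }
  p
}

#' Plot an ROH density track
#'
#' @param object A `density_track` from [roh_density()].
#' @param ... Unused.
#' @return A ggplot, faceted by chromosome.
#' @method autoplot density_track
#' @export
autoplot.density_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Position (Mb)", y = "Fraction of dogs in ROH",
                  title = unique(object$breed)) +
    ggplot2::theme_minimal()
}

#' Plot per-class relative risks
#'
#' @param object An `enrichment_table` from [enrichment_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object[-1, ], ggplot2::aes(x = .data$class, y = .data$rr)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "ROH length class", y = "Relative risk vs non-ROH") +
    ggplot2::theme_minimal()
}

#' Plot F_ROH distributions by breed
#'
#' @param object A `froh_summary` from [froh_by_group()].
#' @param ... Unused.
#' @return A ggplot (one box per breed, ordered by mean, split by scope).
#' @method autoplot froh_summary
#' @export
autoplot.froh_summary <- function(object, ...) {
  ord <- object$groups$breed[!duplicated(object$groups$breed)]
  vals <- dplyr::mutate(object$values, breed = factor(.data$breed, levels = ord))
  ggplot2::ggplot(vals, ggplot2::aes(x = .data$breed, y = .data$froh,
                                     fill = .data$scope)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
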