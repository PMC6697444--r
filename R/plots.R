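#' Plot a fitted binding isotherm
#'
#' Observed points and the fitted one-site curve on a log concentration
#' axis (the zero point is shown at the lowest nonzero concentration / 4).
#'
#' @param object A `one_site_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.one_site_fit <- function(object, ...) {
  d <- object$data
  xmin <- min(d$concentration_nM[d$concentration_nM > 0]) / 4
  d$x <- pmax(d$concentration_nM, xmin)
  grid <- tibble::tibble(
    x = exp(seq(log(xmin), log(max(d$x)), length.out = 200))
  )
  grid$y <- object$bmax * grid$x / (object$kd + grid$x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$signal)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                       colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (nM)", y = "bound signal",
                  title = sprintf("one-site fit: Kd = %.3g nM",
                                  object$kd)) +
    ggplot2::theme_minimal()
}

#' Plot per-position information content of a PFM
#'
#' A bar per motif position, in bits (0 = uninformative, 2 = fully
#' determined base).
#'
#' @param object A `puf_pfm` from [build_pfm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.puf_pfm <- function(object, ...) {
  d <- tibble::tibble(
    position = factor(names(object$ic), levels = names(object$ic)),
    ic = unname(object$ic)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 2) +
    ggplot2::labs(x = "motif position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Plot compact:extended ratios by +4 base
#'
#' Column plot of the ratio per dataset and +4 base, with the neutral
#' ratio of 1 marked.
#'
#' @param ratios Output of [ratio_table()].
#' @return A ggplot object.
#' @export
plot_ratios <- function(ratios) {
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$base4, y = .data$ratio,
                               fill = .data$dataset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "+4 base", y = "compact / extended") +
    ggplot2::theme_minimal()
}

#' Plot term-enrichment results
#'
#' -log10 q-value per term, with the 0.05 threshold marked.
#'
#' @param enrichment Output of [hypergeom_enrich()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  d <- dplyr::mutate(enrichment,
                     term = stats::reorder(.data$term, -.data$q_value))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$q_value),
                                  y = .data$term)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = expression(-log[10]~q), y = NULL) +
    ggplot2::theme_minimal()
}
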