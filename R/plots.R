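#' Plot a hydrogen-bond census
#'
#' Per-class hydrogen-bond counts against time, the standard way these
#' censuses are displayed (total in black, amyloid-amyloid, cross-species
#' and cyclic-cyclic classes in colour).
#'
#' @param object An `hbond_series` from [hbond_census()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hbond_series
#' @export
autoplot.hbond_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", HB_CLASSES, "total")],
    -"time", names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$time / 1000, .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      AB_AB = "red3", AB_SCP = "blue3", SCP_SCP = "green4",
      total = "black")) +
    ggplot2::labs(x = "time (ns)", y = "hydrogen bonds", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a flexibility profile
#'
#' @param object A `flexibility_profile` from [ecd_flexibility()].
#' @param ... Unused.
#' @return A ggplot, one panel per chain.
#' @method autoplot flexibility_profile
#' @export
autoplot.flexibility_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$resid, .data$flexibility)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "main-chain flexibility") +
    ggplot2::theme_minimal()
}

#' Plot a pair-correlation map
#'
#' Heat map of image-space distances; dark = strongly correlated motion.
#'
#' @param object A `pair_correlation` from [ecd_pair_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_correlation
#' @export
autoplot.pair_correlation <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$rho <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("black", "red3", "orange", "yellow", "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(C[alpha]~index),
                  y = expression(C[alpha]~index),
                  fill = expression(rho)) +
    ggplot2::theme_minimal()
}

#' Plot a SASA time series
#'
#' @param object A `sasa_series` (the `series` element of
#'   [sasa_timeseries()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sasa_series
#' @export
autoplot.sasa_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("hydrophobic", "hydrophilic", "total"),
                              names_to = "split", values_to = "area")
  ggplot2::ggplot(long, ggplot2::aes(.data$time / 1000, .data$area,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "time (ns)", y = expression(SASA~(nm^2)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
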