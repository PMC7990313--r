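#' Tidy an essential-modes object
#'
#' One row per retained mode with its eigenvalue (nm^2), variance fraction
#' and cumulative fraction.
#'
#' @param x An `essential_modes` object.
#' @param ... Unused.
#' @return A tibble with `mode`, `eigenvalue`, `fraction`, `cumulative`.
#' @export
tidy.essential_modes <- function(x, ...) {
  frac <- if (x$trace > 0) x$values / x$trace else rep(0, x$d)
  tibble::tibble(mode = seq_len(x$d), eigenvalue = x$values,
                 fraction = frac, cumulative = cumsum(frac))
}

#' One-row summary of an essential-modes object
#'
#' @inheritParams tidy.essential_modes
#' @return Tibble with `d`, `trace`, `fraction` (cumulative variance
#'   captured by the d modes).
#' @export
glance.essential_modes <- function(x, ...) {
  tibble::tibble(d = x$d, trace = x$trace, fraction = x$fraction)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
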