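#' Resolve a time-window specification to frame indices
#'
#' Windows mirror the reporting conventions of aggregation studies:
#' `"first:20ns"`, `"last:5ns"`, `"all"`, a numeric range in ps
#' `c(from, to)`, or an integer vector of frame indices.
#'
#' @param window Window specification.
#' @param times Frame times in ps.
#' @return Integer vector of frame indices.
#' @export
resolve_window <- function(window, times) {
  if (is.null(window)) return(seq_along(times))
  if (is.character(window)) {
    if (identical(window, "all")) return(seq_along(times))
    m <- regmatches(window,
                    regexec("^(first|last):([0-9.]+)(ns|ps)$", window))[[1]]
    if (length(m) == 0) {
      abort(sprintf("cannot parse window '%s' (use e.g. 'last:20ns')", window))
    }
    span <- as.numeric(m[3]) * if (m[4] == "ns") 1000 else 1
    ## half-open: a "first:20ns" window at 0.2 ns spacing holds exactly
    ## 100 frames
    idx <- if (m[2] == "first") {
      which(times < times[1] + span - 1e-9)
    } else {
      which(times > times[length(times)] - span + 1e-9)
    }
  } else if (length(window) == 2 && is.double(window)) {
    idx <- which(times >= window[1] & times <= window[2])
  } else {
    idx <- as.integer(window)
    stopifnot(all(idx >= 1 & idx <= length(times)))
  }
  if (length(idx) == 0) abort("window selects no frames")
  idx
}
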