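#' Uniform or irregular scalar time series with declared units
#'
#' @param t sample times, strictly increasing.
#' @param y values, same length as `t`.
#' @param unit unit string for `y` (e.g. `"nm"`, `"pN"`).
#' @param name channel name (e.g. `"length"`, `"force"`).
#' @param t_unit unit string for `t` (e.g. `"ns"`, `"s"`).
#' @return object of class `time_series`.
#' @export
time_series <- function(t, y, unit, name = "value", t_unit = "ns") {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) == 0) stop("empty time series")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("time series must be finite")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (missing(unit) || !nzchar(unit)) stop("y unit must be declared")
  structure(list(t = t, y = y, unit = unit, name = name, t_unit = t_unit),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series '%s': %d samples, t in [%g, %g] %s, y in %s\n",
              x$name, length(x$t), min(x$t), max(x$t), x$t_unit, x$unit))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$t)

as_time_series <- function(x, unit = "a.u.", name = "value") {
  if (inherits(x, "time_series")) return(x)
  if (is.numeric(x)) return(time_series(seq_along(x), x, unit, name))
  if (is.data.frame(x) && ncol(x) >= 2)
    return(time_series(x[[1]], x[[2]], unit, name))
  stop("cannot interpret input as a time series")
}
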