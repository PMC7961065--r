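#' Piecewise-linear time-varying activity rate
#'
#' A per-cell remodeling rate defined as a continuous piecewise-linear
#' function of time: the rate equals `rate_0` at the first breakpoint and
#' changes with slope `slopes[k]` on the k-th segment.  Hard bounds
#' (`lower_bound`, `upper_bound`) describe the physiologically admissible
#' range; they are *not* applied silently during evaluation -- the calibration
#' penalty is what keeps a fitted rate inside them, and
#' [rate_bounds_violation()] measures how far outside a candidate lies.
#' Beyond the last breakpoint (and before the first) the rate is held constant
#' at the nearest node value.
#'
#' @param t_breaks strictly increasing breakpoint times (day), length >= 1.
#' @param rate_0 rate value at the first breakpoint.
#' @param slopes per-segment slopes (rate units per day),
#'   `length(slopes) == length(t_breaks) - 1`.
#' @param lower_bound,upper_bound hard bounds on the rate.
#' @return An object of class `"piecewise_rate"`.
#' @examples
#' fn <- piecewise_rate(0:3, rate_0 = 1e-6, slopes = c(1e-6, 0, -5e-7))
#' eval_rate(fn, c(0, 0.5, 2.5, 10))
#' @export
piecewise_rate <- function(t_breaks, rate_0, slopes,
                           lower_bound = 0, upper_bound = Inf) {
  if (length(t_breaks) < 1L) stop("t_breaks must not be empty")
  if (any(!is.finite(t_breaks))) stop("t_breaks must be finite")
  if (any(diff(t_breaks) <= 0)) stop("t_breaks must be strictly increasing")
  if (length(slopes) != length(t_breaks) - 1L) {
    stop("length(slopes) must equal length(t_breaks) - 1")
  }
  if (!is.finite(rate_0)) stop("rate_0 must be finite")
  if (length(slopes) && any(!is.finite(slopes))) stop("slopes must be finite")
  if (lower_bound > upper_bound) stop("lower_bound must be <= upper_bound")
  structure(list(t_breaks = as.numeric(t_breaks), rate_0 = as.numeric(rate_0),
                 slopes = as.numeric(slopes),
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "piecewise_rate")
}

#' Node values of a piecewise-linear rate
#'
#' The rate evaluated at each breakpoint.  Because the function is linear in
#' between, its extrema over the covered interval occur at these nodes.
#'
#' @param fn a [piecewise_rate()].
#' @return Numeric vector, one value per breakpoint.
#' @export
rate_nodes <- function(fn) {
  stopifnot(inherits(fn, "piecewise_rate"))
  fn$rate_0 + cumsum(c(0, fn$slopes * diff(fn$t_breaks)))
}

#' Evaluate a piecewise-linear rate
#'
#' Continuous linear interpolation between breakpoints; constant extrapolation
#' beyond the covered interval.  Out-of-bound values are returned as computed
#' unless `bounds_action` asks for a warning or an error -- the fitting
#' penalty must be able to see violations, so clamping is never silent.
#'
#' @param fn a [piecewise_rate()].
#' @param t evaluation times (day), any numeric vector.
#' @param bounds_action what to do when an evaluated rate falls outside
#'   `[lower_bound, upper_bound]`: `"none"` (default) returns it unchanged,
#'   `"warn"` warns, `"error"` stops.
#' @return Numeric vector of rates, one per element of `t`.
#' @export
eval_rate <- function(fn, t, bounds_action = c("none", "warn", "error")) {
  stopifnot(inherits(fn, "piecewise_rate"))
  bounds_action <- match.arg(bounds_action)
  tb <- fn$t_breaks
  nodes <- rate_nodes(fn)
  tc <- pmin(pmax(t, tb[1L]), tb[length(tb)])
  if (length(tb) == 1L) {
    out <- rep(fn$rate_0, length(t))
  } else {
    i <- findInterval(tc, tb, rightmost.closed = TRUE, all.inside = TRUE)
    out <- nodes[i] + fn$slopes[i] * (tc - tb[i])
  }
  if (bounds_action != "none") {
    bad <- out < fn$lower_bound | out > fn$upper_bound
    if (any(bad)) {
      msg <- sprintf("piecewise rate outside [%g, %g] at %d evaluation point(s)",
                     fn$lower_bound, fn$upper_bound, sum(bad))
      if (bounds_action == "error") stop(msg) else warning(msg)
    }
  }
  out
}

#' Normalized bound violation of a piecewise rate
#'
#' Largest normalized excursion of the node values outside the hard bounds
#' (0 when every node is inside).  Used by the calibration penalty.
#'
#' @param fn a [piecewise_rate()].
#' @return A single non-negative number.
#' @export
rate_bounds_violation <- function(fn) {
  nodes <- rate_nodes(fn)
  scale <- max(abs(fn$upper_bound), abs(fn$lower_bound), 1e-300)
  if (!is.finite(scale)) scale <- max(abs(fn$lower_bound), 1)
  over <- if (is.finite(fn$upper_bound)) max(0, max(nodes) - fn$upper_bound) else 0
  under <- max(0, fn$lower_bound - min(nodes))
  max(over, under) / scale
}

#' @export
print.piecewise_rate <- function(x, ...) {
  cat(sprintf("Piecewise-linear rate: %d breakpoint(s) on [%g, %g]\n",
              length(x$t_breaks), x$t_breaks[1L], x$t_breaks[length(x$t_breaks)]))
  cat(sprintf("  nodes: %s\n", paste(signif(rate_nodes(x), 4), collapse = ", ")))
  cat(sprintf("  bounds: [%g, %g]\n", x$lower_bound, x$upper_bound))
  invisible(x)
}
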