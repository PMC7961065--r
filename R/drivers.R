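#' Myeloid driver curve
#'
#' An imposed (not dynamically coupled) time course for one polarized myeloid
#' population, expressed as *excess* fold change over its homeostatic level:
#' 0 at time 0, non-negative everywhere, returning to 0 as the injury
#' resolves.  A curve is the sum of asymmetric log-normal-shaped pulses
#'
#' \deqn{a \exp\{-[\ln((t - t_0)/r)]^2 / d\} \quad (t > t_0),}
#'
#' with amplitude `a` (the peak excess, attained at `t_0 + r`), onset `t_0`,
#' rise time `r` and a width parameter `d` (larger `d` = broader pulse in
#' log-time, hence a longer decaying tail).  The kernel is smooth, unimodal,
#' exactly 0 for `t <= t_0` and vanishes as `t` grows -- the analogue of
#' drawing a smooth curve through the error bars of a fold-change time series.
#'
#' @param pulses a list of pulses, each a list or named vector with elements
#'   `amplitude` (>= 0), `onset` (day, >= 0), `rise_time` (day, > 0) and
#'   `decay_time` (> 0).  May be empty (the zero driver).
#' @param name population label, one of `"pro_mono"`, `"pro_mac"`,
#'   `"anti_mac"`, `"anti_mono"` or a combined label.
#' @return An object of class `"driver_curve"`.
#' @examples
#' d <- driver_curve(list(list(amplitude = 20, onset = 0.25,
#'                             rise_time = 0.75, decay_time = 0.5)),
#'                   name = "pro_mono")
#' eval_driver(d, c(0, 1, 2, 14))
#' @export
driver_curve <- function(pulses = list(), name = "pro_mono") {
  stopifnot(is.list(pulses), is.character(name), length(name) == 1L)
  pulses <- lapply(pulses, function(p) {
    p <- as.list(p)
    need <- c("amplitude", "onset", "rise_time", "decay_time")
    if (!all(need %in% names(p))) {
      stop("each pulse needs amplitude, onset, rise_time and decay_time")
    }
    p <- p[need]
    if (p$amplitude < 0) stop("pulse amplitude must be >= 0")
    if (p$onset < 0) stop("pulse onset must be >= 0")
    if (p$rise_time <= 0) stop("pulse rise_time must be > 0")
    if (p$decay_time <= 0) stop("pulse decay_time must be > 0")
    p
  })
  structure(list(pulses = pulses, name = name), class = "driver_curve")
}

#' Evaluate a driver curve
#'
#' Sum of the pulse kernels at the requested times.  Always >= 0, exactly 0
#' at `t = 0` (no pulse has started) and for any `t` before the earliest
#' onset.
#'
#' @param curve a [driver_curve()].
#' @param t times (day), numeric vector, `t >= 0`.
#' @return Excess fold change over homeostasis at each `t`.
#' @export
eval_driver <- function(curve, t) {
  stopifnot(inherits(curve, "driver_curve"))
  if (any(t < 0)) stop("driver curves are defined for t >= 0")
  out <- numeric(length(t))
  for (p in curve$pulses) {
    x <- (t - p$onset) / p$rise_time
    pos <- x > 0
    if (any(pos)) {
      out[pos] <- out[pos] + p$amplitude * exp(-log(x[pos])^2 / p$decay_time)
    }
  }
  out
}

#' Combine pro-inflammatory monocyte and macrophage drivers
#'
#' Pointwise weighted sum of the two pro-inflammatory curves.  The default
#' unit weights treat monocytes and macrophages as equally potent; the
#' weights are configurable because the data do not pin the combination down.
#'
#' @param mono,mac [driver_curve()]s for pro-inflammatory monocytes and
#'   macrophages.
#' @param weights two non-negative scalars, defaults `c(1, 1)`.
#' @return A `"driver_curve"` whose evaluation equals
#'   `weights[1] * mono + weights[2] * mac`.
#' @export
combine_pro_driver <- function(mono, mac, weights = c(1, 1)) {
  stopifnot(inherits(mono, "driver_curve"), inherits(mac, "driver_curve"))
  if (length(weights) != 2L || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be two finite non-negative scalars")
  }
  scale_pulses <- function(curve, w) {
    lapply(curve$pulses, function(p) {
      p$amplitude <- p$amplitude * w
      p
    })
  }
  pulses <- c(scale_pulses(mono, weights[1L]), scale_pulses(mac, weights[2L]))
  pulses <- Filter(function(p) p$amplitude > 0, pulses)
  driver_curve(pulses, name = "pro_combined")
}

#' @export
print.driver_curve <- function(x, ...) {
  cat(sprintf("Driver curve '%s': %d pulse(s)\n", x$name, length(x$pulses)))
  for (p in x$pulses) {
    cat(sprintf("  amplitude %.4g, onset %.3g d, rise %.3g d, decay %.3g\n",
                p$amplitude, p$onset, p$rise_time, p$decay_time))
  }
  invisible(x)
}

# onset heuristic: times of the n largest local maxima of the mean excess
# series (falls back to the n largest values when fewer maxima exist)
.driver_onset_starts <- function(times, excess, n_pulses) {
  n <- length(excess)
  is_max <- rep(FALSE, n)
  for (i in seq_len(n)) {
    left <- if (i > 1L) excess[i - 1L] else -Inf
    right <- if (i < n) excess[i + 1L] else -Inf
    is_max[i] <- excess[i] > 0 && excess[i] >= left && excess[i] >= right
  }
  cand <- order(ifelse(is_max, excess, -Inf), decreasing = TRUE)
  cand <- cand[is_max[cand]]
  if (length(cand) < n_pulses) {
    extra <- setdiff(order(excess, decreasing = TRUE), cand)
    cand <- c(cand, extra)
  }
  peaks <- sort(times[cand[seq_len(n_pulses)]])
  pmax(0, peaks - 1)  # onset about one rise time before the peak
}

#' Fit a driver curve to one myeloid time series
#'
#' Reproducible parametric substitute for a manual fit: the pulse parameters
#' minimize the weighted sum of squared residuals
#' `sum_i (curve(t_i) - m_i)^2 / sigma_i^2`, where `m_i` is the replicate
#' mean *excess* fold change (observed fold change minus 1) at time `t_i`.
#' Onsets are initialized at the largest local maxima of the mean series and
#' the search uses the penalized seeded Nelder-Mead of [simplex_minimize()].
#'
#' @param data a [bone_dataset()] containing `variable`.
#' @param variable one of `"pro_mono"`, `"pro_mac"`, `"anti_mac"`,
#'   `"anti_mono"`.  Values are fold changes relative to homeostasis (1 at
#'   day 0).
#' @param n_pulses number of pulses to fit (>= 1).
#' @param bounds optional list with elements `amplitude`, `onset`,
#'   `rise_time`, `decay_time`, each a `c(lo, hi)` pair, replacing the
#'   defaults.
#' @param restarts,seed multi-start settings passed to [simplex_minimize()].
#' @return A list of class `"driver_fit"`: `curve` (the fitted
#'   [driver_curve()]), `sse` (weighted SSE), `converged`, `n_evals`, `seed`.
#' @export
fit_driver <- function(data, variable, n_pulses = 1, bounds = NULL,
                       restarts = 5, seed = 1) {
  stopifnot(inherits(data, "bone_dataset"))
  s <- data$summary[data$summary$variable == variable, , drop = FALSE]
  if (nrow(s) == 0L) stop(sprintf("variable '%s' not present in dataset", variable))
  s <- s[order(s$time_day), ]
  times <- s$time_day
  excess <- pmax(0, s$mean - 1)
  sigma <- s$sigma
  if (nrow(s) < 4L * n_pulses) {
    warning(sprintf("only %d time points for %d pulse(s); fit may be unidentifiable",
                    nrow(s), n_pulses))
  }

  tmax <- max(times)
  b <- list(amplitude = c(0, 10 * max(excess, 1)), onset = c(0, tmax),
            rise_time = c(0.05, tmax), decay_time = c(0.01, 10))
  if (!is.null(bounds)) b <- modifyList(b, bounds)

  onsets0 <- .driver_onset_starts(times, excess, n_pulses)
  amp0 <- vapply(onsets0, function(o) {
    max(excess[times > o], 0.1 * max(excess, 1))
  }, numeric(1))
  start <- as.vector(rbind(amp0, onsets0, rep(1, n_pulses), rep(0.5, n_pulses)))
  lower <- rep(c(b$amplitude[1], b$onset[1], b$rise_time[1], b$decay_time[1]), n_pulses)
  upper <- rep(c(b$amplitude[2], b$onset[2], b$rise_time[2], b$decay_time[2]), n_pulses)

  par_to_curve <- function(par) {
    pulses <- lapply(seq_len(n_pulses), function(k) {
      i <- 4L * (k - 1L)
      list(amplitude = max(par[i + 1L], 0), onset = max(par[i + 2L], 0),
           rise_time = max(par[i + 3L], 1e-6), decay_time = max(par[i + 4L], 1e-6))
    })
    driver_curve(pulses, name = variable)
  }
  sse_fun <- function(par) {
    pred <- eval_driver(par_to_curve(par), times)
    sum((pred - excess)^2 / sigma^2)
  }
  obj <- penalized_objective(sse_fun, bounds = list(lower = lower, upper = upper))
  res <- simplex_minimize(obj, start, restarts = restarts, seed = seed,
                          parscale = pmax(abs(start), 0.1))
  if (!res$converged) {
    warning("driver fit did not converge; best point so far returned")
  }
  structure(list(curve = par_to_curve(res$par), sse = sse_fun(res$par),
                 converged = res$converged, n_evals = res$n_evals, seed = seed),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("Driver fit (weighted SSE %.4g, %sconverged)\n",
              x$sse, if (x$converged) "" else "NOT "))
  print(x$curve)
  invisible(x)
}
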