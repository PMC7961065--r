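#' Coefficient of determination against replicate means
#'
#' `R^2 = 1 - SS_res / SS_tot`, computed on the replicate means of the
#' post-baseline time points (day 0 is the imposed initial condition, not a
#' fitted point; set `include_baseline = TRUE` to count it anyway).  Can be
#' negative for fits worse than the grand mean.
#'
#' @param predictions a data frame with columns `variable`, `time_day`,
#'   `value` covering the observed times.
#' @param data a [bone_dataset()].
#' @param variable the variable to score.
#' @param include_baseline include the day-0 point (default `FALSE`).
#' @return The R^2 value; `NA` (with a warning) when the data are flat and
#'   `SS_tot = 0`.
#' @export
r_squared <- function(predictions, data, variable, include_baseline = FALSE) {
  s <- .var_summary(data, variable)
  if (!include_baseline) s <- s[s$time_day > 0, , drop = FALSE]
  if (nrow(s) == 0L) stop("no time points to score")
  idx <- match(paste(variable, s$time_day), paste(predictions$variable, predictions$time_day))
  if (anyNA(idx)) stop(sprintf("predictions missing for '%s' at some observed times", variable))
  f <- predictions$value[idx]
  ss_tot <- sum((s$mean - mean(s$mean))^2)
  if (ss_tot == 0) {
    warning("flat data: SS_tot = 0, R^2 undefined")
    return(NA_real_)
  }
  1 - sum((f - s$mean)^2) / ss_tot
}

#' Count standardized residuals below one
#'
#' The `#R < 1` diagnostic: the number of post-baseline time points whose
#' standardized residual `|f(t_i) - D_i| / sigma_i` is *strictly* less than
#' 1 (the boundary counts as a miss).
#'
#' @inheritParams r_squared
#' @return A named numeric vector `c(count =, total =)`.
#' @export
count_residuals_below_one <- function(predictions, data, variable) {
  s <- .var_summary(data, variable)
  s <- s[s$time_day > 0, , drop = FALSE]
  idx <- match(paste(variable, s$time_day), paste(predictions$variable, predictions$time_day))
  if (anyNA(idx)) stop(sprintf("predictions missing for '%s' at some observed times", variable))
  if (any(!is.finite(s$sigma)) || any(s$sigma <= 0)) {
    stop("sigma must be available and positive at every counted point")
  }
  f <- predictions$value[idx]
  r <- abs(f - s$mean) / s$sigma
  c(count = sum(r < 1), total = nrow(s))
}

#' Fold range of an activity time course
#'
#' `max(rate) / min(rate)` over the time course: how much a per-cell
#' remodeling activity varies in time.  A constant activity has fold range 1.
#'
#' @param tc an `"activity_timecourse"` (from [activity_timecourses()]) or a
#'   plain numeric vector of rates.
#' @return A single number >= 1.  A minimum of 0 (infinite fold) is an error,
#'   never a returned number.
#' @examples
#' fold_range(c(4.26e-7, 7.28e-6))  # ~17.09
#' @export
fold_range <- function(tc) {
  rate <- if (inherits(tc, "activity_timecourse")) tc$rate else as.numeric(tc)
  if (any(!is.finite(rate))) stop("activity must be finite")
  if (min(rate) <= 0) stop("minimum activity is 0: fold range is infinite")
  max(rate) / min(rate)
}

#' Per-cell activity time courses implied by a fit or parameter set
#'
#' Derives the resorption activity `delta_B (1 + alpha P(t))` and formation
#' activity `Pi_B (1 + beta A(t))` of a myeloid-modulated model (or the
#' piecewise rate directly, with the other rate constant) on a time grid.
#'
#' @param x a `"bone_fit"` from [fit_modulation()] / [fit_piecewise_rate()],
#'   or an [expanded_parameters()] set.
#' @param t_grid evaluation times (day).
#' @param ... unused.
#' @return A list with `resorption` and `formation`, each an
#'   `"activity_timecourse"` data frame (`time_day`, `rate`) with a `kind`
#'   attribute.
#' @export
activity_timecourses <- function(x, t_grid = seq(0, 14, by = 0.01), ...) {
  UseMethod("activity_timecourses")
}

.activity_tc <- function(t_grid, rate, kind) {
  structure(data.frame(time_day = t_grid, rate = rate),
            kind = kind, class = c("activity_timecourse", "data.frame"))
}

#' @rdname activity_timecourses
#' @export
activity_timecourses.expanded_model_params <- function(x, t_grid = seq(0, 14, by = 0.01), ...) {
  P <- eval_driver(x$pro_driver, t_grid)
  A <- eval_driver(x$anti_driver, t_grid)
  list(resorption = .activity_tc(t_grid, x$base$delta_B * (1 + x$alpha * P),
                                 "resorption"),
       formation = .activity_tc(t_grid, x$base$Pi_B * (1 + x$beta * A),
                                "formation"))
}

#' @rdname activity_timecourses
#' @export
activity_timecourses.bone_fit <- function(x, t_grid = seq(0, 14, by = 0.01), ...) {
  if (x$workflow == "modulation") {
    return(activity_timecourses(x$params, t_grid))
  }
  if (x$workflow == "piecewise") {
    rate <- eval_rate(x$extras$rate_fn, t_grid)
    if (x$extras$which == "resorption") {
      return(list(resorption = .activity_tc(t_grid, rate, "resorption"),
                  formation = .activity_tc(t_grid, rep(x$extras$fixed_rate,
                                                       length(t_grid)),
                                           "formation")))
    }
    return(list(resorption = .activity_tc(t_grid, rep(x$extras$fixed_rate,
                                                      length(t_grid)),
                                          "resorption"),
                formation = .activity_tc(t_grid, rate, "formation")))
  }
  # constant-rate workflows: both activities are flat
  list(resorption = .activity_tc(t_grid, rep(x$params$delta_B, length(t_grid)),
                                 "resorption"),
       formation = .activity_tc(t_grid, rep(x$params$Pi_B, length(t_grid)),
                                "formation"))
}

#' Diagnostics for a fitted model
#'
#' Bundles the fit statistics of a `"bone_fit"` (per-variable R^2,
#' standardized-residual counts, LS, AIC and -- where activities are defined
#' -- their fold ranges) into one list, suitable for JSON export.
#'
#' @param fit a `"bone_fit"`.
#' @param t_grid grid for the activity fold ranges.
#' @return A named list of diagnostics.
#' @export
fit_diagnostics <- function(fit, t_grid = seq(0, 14, by = 0.01)) {
  stopifnot(inherits(fit, "bone_fit"))
  out <- list(workflow = fit$workflow, LS = fit$LS, AIC = fit$AIC,
              r_squared = as.list(fit$r_squared),
              n_residuals_below_one = lapply(fit$n_residuals_below_one, as.list))
  if (fit$workflow %in% c("modulation", "piecewise")) {
    act <- activity_timecourses(fit, t_grid)
    out$fold_range <- list(resorption = fold_range(act$resorption),
                           formation = fold_range(act$formation))
  }
  out
}
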