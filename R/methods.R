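#' @export
print.bone_fit <- function(x, ...) {
  cat(sprintf("Bone repair model fit (workflow '%s')\n", x$workflow))
  cat(sprintf("  LS = %.6g, AIC = %.6g (%d free parameter(s))%s\n",
              x$LS, x$AIC, length(coef(x)),
              if (x$converged) "" else "  [NOT converged]"))
  cat("  coefficients:\n")
  co <- coef(x)
  for (nm in names(co)) cat(sprintf("    %-14s %.6g\n", nm, co[[nm]]))
  invisible(x)
}

#' @export
coef.bone_fit <- function(object, ...) object$coefficients

#' @export
summary.bone_fit <- function(object, ...) {
  structure(list(fit = object, diagnostics = fit_diagnostics(object)),
            class = "summary.bone_fit")
}

#' @export
print.summary.bone_fit <- function(x, ...) {
  print(x$fit)
  d <- x$diagnostics
  for (v in names(d$r_squared)) {
    nr <- d$n_residuals_below_one[[v]]
    cat(sprintf("  %s: R^2 = %.4f, #R<1 = %d/%d\n", v, d$r_squared[[v]],
                nr$count, nr$total))
  }
  if (!is.null(d$fold_range)) {
    cat(sprintf("  activity fold range: resorption %.3g, formation %.3g\n",
                d$fold_range$resorption, d$fold_range$formation))
  }
  invisible(x)
}

#' Model predictions from a fit
#'
#' Evaluates the fitted model on an arbitrary time grid: exact cell
#' trajectories for `OB`/`OC` and, for the bone-stage workflows, the bone
#' trajectory implied by the fitted rates with the cells frozen.
#'
#' @param object a `"bone_fit"`.
#' @param times output times (day).
#' @param ... unused.
#' @return A data frame with `time_day`, `OB`, `OC` and (except for the
#'   cells workflow) `B`.
#' @export
predict.bone_fit <- function(object, times = seq(0, 14, by = 0.1), ...) {
  base <- if (inherits(object$params, "expanded_model_params")) {
    object$params$base
  } else object$params
  if (object$workflow == "cells") {
    return(cell_trajectories(base, object$baseline, times))
  }
  dt <- if (!is.null(object$extras$grid_dt)) object$extras$grid_dt else 0.005
  knots <- if (object$workflow == "piecewise") object$extras$rate_fn$t_breaks
  grid <- .bone_grid(times, max(times), dt = dt, knots = knots)
  cells <- cell_trajectories(base, object$baseline, grid)
  act <- activity_timecourses(object, grid)
  B_g <- .project_bone(grid, cells$OB, cells$OC, act$resorption$rate,
                       act$formation$rate, object$baseline$B_0)
  i <- match(times, grid)
  out <- data.frame(time_day = times, OB = cells$OB[i], OC = cells$OC[i],
                    B = B_g[i])
  if (object$workflow == "modulation") {
    out$P <- eval_driver(object$params$pro_driver, times)
    out$A <- eval_driver(object$params$anti_driver, times)
  }
  out
}

#' Standardized residuals of a fit
#'
#' `(f(t_i) - D_ij) / sigma_ij` at the observed points of every fitted
#' variable.
#'
#' @param object a `"bone_fit"`.
#' @param ... unused.
#' @return A data frame with `variable`, `time_day`, `residual`.
#' @export
residuals.bone_fit <- function(object, ...) {
  p <- object$predictions
  s <- object$data$summary
  idx <- match(paste(p$variable, p$time_day), paste(s$variable, s$time_day))
  data.frame(variable = p$variable, time_day = p$time_day,
             residual = (p$value - s$mean[idx]) / s$sigma[idx])
}

#' Plot a fit against the data
#'
#' One panel per fitted variable: replicate means with +/- sigma error bars
#' and the fitted trajectory.
#'
#' @param x a `"bone_fit"`.
#' @param times plotting grid.
#' @param ... forwarded to `plot`.
#' @return `x`, invisibly.
#' @export
plot.bone_fit <- function(x, times = seq(0, max(x$data$times), by = 0.05), ...) {
  vars <- names(x$r_squared)
  pred <- predict(x, times)
  old <- par(mfrow = c(1, length(vars)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (v in vars) {
    s <- x$data$summary[x$data$summary$variable == v, ]
    yl <- range(c(s$mean + s$sigma, s$mean - s$sigma, pred[[v]]), finite = TRUE)
    plot(s$time_day, s$mean, ylim = yl, xlab = "time (day)", ylab = v,
         main = sprintf("%s (R^2 = %.3f)", v, x$r_squared[[v]]), pch = 19, ...)
    segments(s$time_day, s$mean - s$sigma, s$time_day, s$mean + s$sigma)
    lines(pred$time_day, pred[[v]], col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Simulate replicated datasets from a fitted model
#'
#' Draws synthetic datasets from the fitted parameters under a given study
#' design (parametric resampling of the fitted model).
#'
#' @param object a `"bone_fit"` whose workflow defines a complete model
#'   (`"cells"`, `"free_rates"`, `"scan"` entries or `"modulation"`).
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param design a [study_design()].
#' @param ... unused.
#' @return A [bone_dataset()] if `nsim = 1`, else a list of them.
#' @export
simulate.bone_fit <- function(object, nsim = 1, seed = 1,
                              design = study_design(), ...) {
  if (object$workflow == "piecewise") {
    stop("piecewise fits have no closed generative model; simulate the rates explicitly")
  }
  vars <- if (object$workflow == "cells") c("OB", "OC") else c("OB", "OC", "B")
  design$variables <- intersect(design$variables, vars)
  truth <- ground_truth(object$params, object$baseline, design = design)
  out <- lapply(seq_len(nsim), function(k) {
    generate_dataset(truth, design, seed = seed + k - 1L)
  })
  if (nsim == 1) out[[1L]] else out
}

#' @export
print.bone_trajectory <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Simulated bone repair trajectory (%s model, %d time point(s), rtol %g)\n",
              m$variant, nrow(x), m$rtol))
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
plot.bone_trajectory <- function(x, ...) {
  vars <- intersect(c("OB", "OC", "B"), names(x))
  old <- par(mfrow = c(1, length(vars)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (v in vars) {
    plot(x$time_day, x[[v]], type = "l", lwd = 2, xlab = "time (day)",
         ylab = v, main = v, ...)
  }
  invisible(x)
}
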