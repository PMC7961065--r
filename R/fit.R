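# staged fitting workflows: cells first, then the bone equation with the
# cell trajectories frozen (no global refit)

.new_bone_fit <- function(workflow, params, baseline, free, predictions, data,
                          converged, n_evals, seed, extras = list(),
                          variables = NULL) {
  obj <- objective_ls(predictions, data, variables = variables)
  diag_vars <- names(obj$per_variable)
  r2 <- vapply(diag_vars, function(v) {
    r_squared(predictions, data, v)
  }, numeric(1))
  nr <- lapply(diag_vars, function(v) count_residuals_below_one(predictions, data, v))
  names(nr) <- diag_vars
  fit <- list(workflow = workflow, params = params, baseline = baseline,
              coefficients = free, LS = obj$LS,
              per_variable_SS = obj$per_variable,
              AIC = aic(length(free), obj$LS),
              r_squared = r2, n_residuals_below_one = nr,
              converged = converged, n_evals = n_evals, seed = seed,
              predictions = predictions, data = data, extras = extras)
  class(fit) <- "bone_fit"
  fit
}

.baseline_from_data <- function(data) {
  m0 <- function(v, default = NULL) {
    m <- data$summary$mean[data$summary$variable == v & data$summary$time_day == 0]
    if (length(m) == 0L) {
      if (is.null(default)) stop(sprintf("variable '%s' has no baseline observation", v))
      default
    } else m[1L]
  }
  homeostatic_baseline(OB_0 = m0("OB"), OC_0 = m0("OC"), B_0 = m0("B", default = 1))
}

.var_summary <- function(data, v) {
  s <- data$summary[data$summary$variable == v, , drop = FALSE]
  if (nrow(s) == 0L) stop(sprintf("dataset has no '%s' observations", v))
  s[order(s$time_day), , drop = FALSE]
}

#' Calibrate the cell (OB/OC) dynamics
#'
#' First stage of the pipeline.  With the osteoblast clearance `delta_OB`
#' fixed from literature (0.19/day) and the catabolism start `T_Catab`
#' imposed, the osteoblast sub-fit estimates `{gamma_OB, T_anab}` against the
#' OB series and the osteoclast sub-fit estimates
#' `{Inhib_OC, T_antiCatab, R_OC}` against the OC series, each minimizing its
#' own weighted sum of squares (for a single variable the minimax objective
#' reduces to that sum).  The homeostasis closures
#' `H_OB = delta_OB * OB_0` and `delta_OC_clear = R_OC / OC_0` are enforced
#' throughout.  Bone is excluded; the fitted cell trajectories are frozen for
#' every downstream bone-stage workflow.
#'
#' @param data a [bone_dataset()] with `OB` and `OC` series.
#' @param delta_OB fixed osteoblast clearance rate (1/day).
#' @param T_Catab imposed catabolism start time (day).
#' @param start optional named list overriding the default start values
#'   (`gamma_OB`, `T_anab`, `Inhib_OC`, `T_antiCatab`, `R_OC`).
#' @param bounds optional named list of `c(lo, hi)` pairs overriding the
#'   default parameter bounds.
#' @param restarts,seed multi-start settings (see [simplex_minimize()]).
#' @return A `"bone_fit"` (workflow `"cells"`) with 5 free parameters.
#' @export
calibrate_cell_dynamics <- function(data, delta_OB = 0.19, T_Catab = 2,
                                    start = NULL, bounds = NULL,
                                    restarts = 5, seed = 1) {
  stopifnot(inherits(data, "bone_dataset"))
  baseline <- .baseline_from_data(data)
  sob <- .var_summary(data, "OB")
  soc <- .var_summary(data, "OC")
  tmax <- max(data$times)

  st <- list(gamma_OB = 0.5, T_anab = 5, Inhib_OC = 1, T_antiCatab = 2,
             R_OC = baseline$OC_0)
  if (!is.null(start)) st <- modifyList(st, start)
  bd <- list(gamma_OB = c(0, 5), T_anab = c(0, tmax), Inhib_OC = c(0, 20),
             T_antiCatab = c(0, tmax), R_OC = c(0, 1e3 * baseline$OC_0))
  if (!is.null(bounds)) bd <- modifyList(bd, bounds)

  s_all <- data$summary[data$summary$variable %in% c("OB", "OC"), ]
  keys <- paste0(s_all$variable, "@", s_all$time_day)
  base <- s_all$mean[match(paste0(s_all$variable, "@0"), keys)]
  flat <- all(abs(s_all$mean - base) <= s_all$sigma)
  if (isTRUE(flat)) {
    warning("data look like flat homeostasis; expansion/decrease parameters are weakly identified")
  }

  base_params <- function(gamma_OB = 0, T_anab = 0, Inhib_OC = 0,
                          T_antiCatab = 0, R_OC = 0) {
    initial_parameters(delta_OB = delta_OB, gamma_OB = gamma_OB,
                       T_anab = T_anab, Inhib_OC = Inhib_OC,
                       T_antiCatab = T_antiCatab, T_Catab = T_Catab,
                       R_OC = R_OC, baseline = baseline)
  }

  obj_ob <- function(th) {
    p <- base_params(gamma_OB = max(th[1L], 0), T_anab = max(th[2L], 0))
    ct <- cell_trajectories(p, baseline, sob$time_day)
    sum((ct$OB - sob$mean)^2 / sob$sigma^2)
  }
  obj_oc <- function(th) {
    p <- base_params(Inhib_OC = max(th[1L], 0), T_antiCatab = max(th[2L], 0),
                     R_OC = max(th[3L], 0))
    ct <- cell_trajectories(p, baseline, soc$time_day)
    sum((ct$OC - soc$mean)^2 / soc$sigma^2)
  }

  res_ob <- simplex_minimize(
    penalized_objective(obj_ob, list(lower = c(bd$gamma_OB[1], bd$T_anab[1]),
                                     upper = c(bd$gamma_OB[2], bd$T_anab[2]))),
    c(st$gamma_OB, st$T_anab), restarts = restarts, seed = seed)
  res_oc <- simplex_minimize(
    penalized_objective(obj_oc, list(
      lower = c(bd$Inhib_OC[1], bd$T_antiCatab[1], bd$R_OC[1]),
      upper = c(bd$Inhib_OC[2], bd$T_antiCatab[2], bd$R_OC[2]))),
    c(st$Inhib_OC, st$T_antiCatab, st$R_OC), restarts = restarts, seed = seed)

  free <- c(gamma_OB = max(res_ob$par[1L], 0), T_anab = max(res_ob$par[2L], 0),
            Inhib_OC = max(res_oc$par[1L], 0),
            T_antiCatab = max(res_oc$par[2L], 0),
            R_OC = max(res_oc$par[3L], 0))
  params <- base_params(gamma_OB = free[["gamma_OB"]], T_anab = free[["T_anab"]],
                        Inhib_OC = free[["Inhib_OC"]],
                        T_antiCatab = free[["T_antiCatab"]],
                        R_OC = free[["R_OC"]])
  obs_t <- sort(unique(c(sob$time_day, soc$time_day)))
  ct <- cell_trajectories(params, baseline, obs_t)
  predictions <- rbind(
    data.frame(variable = "OB", time_day = ct$time_day, value = ct$OB),
    data.frame(variable = "OC", time_day = ct$time_day, value = ct$OC))

  .new_bone_fit("cells", params, baseline, free, predictions, data,
                converged = res_ob$converged && res_oc$converged,
                n_evals = res_ob$n_evals + res_oc$n_evals, seed = seed,
                variables = c("OB", "OC"))
}

# frozen cell trajectories of a cell fit, evaluated on a grid
.frozen_cells <- function(cell_fit, grid) {
  stopifnot(inherits(cell_fit, "bone_fit"))
  cell_trajectories(cell_fit$params, cell_fit$baseline, grid)
}

.bone_stage_setup <- function(data, cell_fit, grid_dt, knots = NULL) {
  sB <- .var_summary(data, "B")
  tmax <- max(data$times)
  grid <- .bone_grid(sB$time_day, tmax, dt = grid_dt, knots = knots)
  cells <- .frozen_cells(cell_fit, grid)
  list(sB = sB, grid = grid, ob_g = cells$OB, oc_g = cells$OC,
       idx_obs = match(sB$time_day, grid),
       B_0 = .baseline_from_data(data)$B_0)
}

.bone_predictions <- function(setup, B_grid) {
  data.frame(variable = "B", time_day = setup$sB$time_day,
             value = B_grid[setup$idx_obs])
}

#' Scan constant bone resorption rates under the homeostasis closure
#'
#' The "closure-constrained" workflow: constant resorption rates `delta_B`
#' are sampled on a log-uniform grid across the published range and, for each
#' sample, the formation rate is fixed by the closure
#' `Pi_B = delta_B * OC_0 * B_0 / OB_0` (so the prediction must eventually
#' return to baseline bone volume).  The bone trajectory is computed with the
#' cell dynamics frozen from `cell_fit`, and R^2, the standardized-residual
#' count and the weighted SS are recorded for every sample.
#'
#' @param data a [bone_dataset()] with a `B` series.
#' @param cell_fit a `"bone_fit"` from [calibrate_cell_dynamics()].
#' @param rate_range sampled resorption-rate range (1/cell/day); default the
#'   published `[1e-8, 5e-5]`.
#' @param n_samples number of log-uniform grid points (default 25).
#' @param grid_dt integration grid step (day) for the bone stage.
#' @return A `"rate_scan"`: `results` (data frame sorted by decreasing R^2),
#'   `fits` (one `"bone_fit"` per sample, same order) and `best`.
#' @export
scan_constant_rates <- function(data, cell_fit, rate_range = c(1e-8, 5e-5),
                                n_samples = 25, grid_dt = 0.02) {
  stopifnot(length(rate_range) == 2L, all(rate_range > 0),
            rate_range[1] <= rate_range[2])
  su <- .bone_stage_setup(data, cell_fit, grid_dt)
  baseline <- cell_fit$baseline
  rates <- exp(seq(log(rate_range[1L]), log(rate_range[2L]),
                   length.out = n_samples))
  fits <- lapply(rates, function(db) {
    pb <- closure_formation_rate(db, baseline)
    B_g <- .project_bone(su$grid, su$ob_g, su$oc_g,
                         rep(db, length(su$grid)), rep(pb, length(su$grid)),
                         su$B_0)
    preds <- .bone_predictions(su, B_g)
    params <- cell_fit$params
    params$delta_B <- db
    params$Pi_B <- pb
    .new_bone_fit("scan", params, baseline, c(delta_B = db), preds, data,
                  converged = TRUE, n_evals = n_samples, seed = NA_integer_,
                  variables = "B",
                  extras = list(cell_fit = cell_fit, grid_dt = grid_dt))
  })
  results <- data.frame(
    delta_B = rates,
    Pi_B = vapply(fits, function(f) f$params$Pi_B, numeric(1)),
    r_squared = vapply(fits, function(f) f$r_squared[["B"]], numeric(1)),
    n_resid_lt1 = vapply(fits, function(f) f$n_residuals_below_one$B[["count"]],
                         numeric(1)),
    LS = vapply(fits, function(f) f$LS, numeric(1)))
  ord <- order(results$r_squared, decreasing = TRUE)
  structure(list(results = results[ord, ], fits = fits[ord],
                 best = fits[[ord[1L]]], rate_range = rate_range),
            class = "rate_scan")
}

#' Fit free constant resorption and formation rates
#'
#' The unconstrained constant-rate workflow: `delta_B` and `Pi_B` are
#' optimized jointly (internally on a log10 scale) *without* the formation
#' closure, so the prediction is not forced to return to baseline bone
#' volume.  The signed terminal deficit `B(T_end)/B_0 - 1` is reported in
#' `extras$terminal_deficit`.
#'
#' @inheritParams scan_constant_rates
#' @param bounds list with `delta_B` and `Pi_B` elements, each `c(lo, hi)`
#'   on the natural scale.
#' @param start optional named list (`delta_B`, `Pi_B`) of start values.
#' @param restarts,seed multi-start settings.
#' @return A `"bone_fit"` (workflow `"free_rates"`, 2 free parameters).
#' @export
fit_free_constant_rates <- function(data, cell_fit,
                                    bounds = list(delta_B = c(1e-9, 1e-3),
                                                  Pi_B = c(1e-9, 1e-3)),
                                    start = NULL, restarts = 5, seed = 1,
                                    grid_dt = 0.02) {
  su <- .bone_stage_setup(data, cell_fit, grid_dt)
  baseline <- cell_fit$baseline
  st <- list(delta_B = 1e-6,
             Pi_B = closure_formation_rate(1e-6, baseline))
  if (!is.null(start)) st <- modifyList(st, start)

  sse <- function(th) {
    db <- 10^th[1L]; pb <- 10^th[2L]
    B_g <- .project_bone(su$grid, su$ob_g, su$oc_g,
                         rep(db, length(su$grid)), rep(pb, length(su$grid)),
                         su$B_0)
    sum((B_g[su$idx_obs] - su$sB$mean)^2 / su$sB$sigma^2)
  }
  obj <- penalized_objective(sse, list(
    lower = log10(c(bounds$delta_B[1L], bounds$Pi_B[1L])),
    upper = log10(c(bounds$delta_B[2L], bounds$Pi_B[2L]))))
  res <- simplex_minimize(obj, log10(c(st$delta_B, st$Pi_B)),
                          restarts = restarts, seed = seed,
                          parscale = c(1, 1))

  db <- 10^res$par[1L]; pb <- 10^res$par[2L]
  params <- cell_fit$params
  params$delta_B <- db; params$Pi_B <- pb
  B_g <- .project_bone(su$grid, su$ob_g, su$oc_g,
                       rep(db, length(su$grid)), rep(pb, length(su$grid)),
                       su$B_0)
  preds <- .bone_predictions(su, B_g)
  .new_bone_fit("free_rates", params, baseline,
                c(delta_B = db, Pi_B = pb), preds, data,
                converged = res$converged, n_evals = res$n_evals, seed = seed,
                variables = "B",
                extras = list(cell_fit = cell_fit, grid_dt = grid_dt,
                              terminal_deficit = B_g[length(B_g)] / su$B_0 - 1))
}

#' Fit myeloid-driven modulation of remodeling activity
#'
#' The expanded-model workflow: with cell dynamics frozen and the formation
#' rate tied to the closure `Pi_B = delta_B * OC_0 * B_0 / OB_0`, the
#' homeostatic resorption rate `delta_B` and the stimulation factors `alpha`
#' (pro-inflammatory, resorption) and `beta` (anti-inflammatory, formation)
#' are fitted to the bone series.  The modulated activities
#' `delta_B (1 + alpha P(t))` and `Pi_B (1 + beta A(t))` are constrained to
#' the published range via the quadratic penalty, and are exposed through
#' [activity_timecourses()] for fold-range analysis.
#'
#' @inheritParams scan_constant_rates
#' @param pro_driver combined pro-inflammatory [driver_curve()] (see
#'   [combine_pro_driver()]).
#' @param anti_driver anti-inflammatory macrophage [driver_curve()].
#' @param rate_limits admissible activity range (default the published
#'   `[1e-8, 5e-5]` mm^3/cell/day).
#' @param start optional named list (`delta_B`, `alpha`, `beta`).
#' @param bounds optional named list of `c(lo, hi)` pairs for `delta_B`
#'   (natural scale), `alpha`, `beta`.
#' @param restarts,seed multi-start settings.
#' @return A `"bone_fit"` (workflow `"modulation"`, 3 free parameters) whose
#'   `params` element is an [expanded_parameters()] set.
#' @export
fit_modulation <- function(data, cell_fit, pro_driver, anti_driver,
                           rate_limits = c(1e-8, 5e-5),
                           start = NULL, bounds = NULL,
                           restarts = 5, seed = 1, grid_dt = 0.02) {
  stopifnot(inherits(pro_driver, "driver_curve"),
            inherits(anti_driver, "driver_curve"))
  onsets <- unlist(lapply(c(pro_driver$pulses, anti_driver$pulses),
                          `[[`, "onset"))
  su <- .bone_stage_setup(data, cell_fit, grid_dt, knots = onsets)
  baseline <- cell_fit$baseline
  P_g <- eval_driver(pro_driver, su$grid)
  A_g <- eval_driver(anti_driver, su$grid)
  lim <- rate_limits

  st <- list(delta_B = sqrt(prod(lim)), alpha = 1, beta = 1)
  if (!is.null(start)) st <- modifyList(st, start)
  bd <- list(delta_B = lim, alpha = c(0, 1e3), beta = c(0, 1e3))
  if (!is.null(bounds)) bd <- modifyList(bd, bounds)

  range_penalty <- function(r_g, f_g) {
    v <- max(0, max(r_g) - lim[2L]) / lim[2L] +
      max(0, lim[1L] - min(r_g)) / lim[2L] +
      max(0, max(f_g) - lim[2L]) / lim[2L] +
      max(0, lim[1L] - min(f_g)) / lim[2L]
    1e10 * v^2
  }
  sse <- function(th) {
    db <- 10^th[1L]; al <- max(th[2L], 0); be <- max(th[3L], 0)
    pb <- closure_formation_rate(db, baseline)
    r_g <- db * (1 + al * P_g)
    f_g <- pb * (1 + be * A_g)
    B_g <- .project_bone(su$grid, su$ob_g, su$oc_g, r_g, f_g, su$B_0)
    sum((B_g[su$idx_obs] - su$sB$mean)^2 / su$sB$sigma^2) +
      range_penalty(r_g, f_g)
  }
  obj <- penalized_objective(sse, list(
    lower = c(log10(bd$delta_B[1L]), bd$alpha[1L], bd$beta[1L]),
    upper = c(log10(bd$delta_B[2L]), bd$alpha[2L], bd$beta[2L])))
  res <- simplex_minimize(obj, c(log10(st$delta_B), st$alpha, st$beta),
                          restarts = restarts, seed = seed,
                          parscale = c(1, max(st$alpha, 1), max(st$beta, 1)))

  db <- 10^res$par[1L]
  al <- max(res$par[2L], 0); be <- max(res$par[3L], 0)
  base_params <- cell_fit$params
  base_params$delta_B <- db
  base_params$Pi_B <- closure_formation_rate(db, baseline)
  params <- expanded_parameters(base_params, alpha = al, beta = be,
                                pro_driver = pro_driver,
                                anti_driver = anti_driver)
  r_g <- db * (1 + al * P_g)
  f_g <- base_params$Pi_B * (1 + be * A_g)
  B_g <- .project_bone(su$grid, su$ob_g, su$oc_g, r_g, f_g, su$B_0)
  preds <- .bone_predictions(su, B_g)
  .new_bone_fit("modulation", params, baseline,
                c(delta_B = db, alpha = al, beta = be), preds, data,
                converged = res$converged, n_evals = res$n_evals, seed = seed,
                variables = "B",
                extras = list(cell_fit = cell_fit, grid_dt = grid_dt,
                              rate_limits = lim,
                              max_resorption_rate = max(r_g),
                              min_resorption_rate = min(r_g),
                              max_formation_rate = max(f_g),
                              min_formation_rate = min(f_g)))
}

#' Fit a piecewise-linear time-varying activity rate
#'
#' The agnostic workflow: one per-cell rate (resorption or formation) is a
#' [piecewise_rate()] with breakpoints fixed on a uniform grid, and its
#' initial value plus per-segment slopes are optimized against the bone
#' series with the cell dynamics frozen.  Slopes may be positive or negative;
#' the quadratic penalty keeps the rate inside `rate_limits` (it can neither
#' become negative nor exceed the published upper bound).  Multi-start runs
#' use randomized initial slopes; the best run is returned.
#'
#' @inheritParams scan_constant_rates
#' @param which which rate varies in time: `"resorption"` or `"formation"`.
#' @param fixed_rate the constant rate of the *other* process (required; the
#'   staged pipeline leaves it at its previously fitted or closure value).
#' @param n_segments number of linear segments on `t_range` (default 8).
#' @param t_range breakpoint span (default `c(0, max(data$times))`).
#' @param rate_limits hard bounds on the rate (default `[1e-8, 5e-5]`).
#' @param slope_limits optional `c(lo, hi)` bounds on every slope.
#' @param restarts,seed multi-start settings.
#' @return A `"bone_fit"` (workflow `"piecewise"`, `1 + n_segments` free
#'   parameters) with the fitted [piecewise_rate()] in `extras$rate_fn` and
#'   every restart's objective value in `extras$restart_values`.
#' @export
fit_piecewise_rate <- function(data, cell_fit,
                               which = c("resorption", "formation"),
                               fixed_rate = NULL, n_segments = 8,
                               t_range = NULL, rate_limits = c(1e-8, 5e-5),
                               slope_limits = NULL, restarts = 5, seed = 1,
                               grid_dt = 0.02) {
  which <- match.arg(which)
  if (is.null(fixed_rate)) {
    stop("fixed_rate (the constant rate of the other process) must be supplied")
  }
  if (is.null(t_range)) t_range <- c(0, max(data$times))
  t_breaks <- seq(t_range[1L], t_range[2L], length.out = n_segments + 1L)
  su <- .bone_stage_setup(data, cell_fit, grid_dt, knots = t_breaks)
  n_grid <- length(su$grid)
  scale <- sqrt(prod(rate_limits))
  seg <- diff(t_range) / n_segments

  make_fn <- function(th) {
    piecewise_rate(t_breaks, rate_0 = th[1L], slopes = th[-1L],
                   lower_bound = rate_limits[1L], upper_bound = rate_limits[2L])
  }
  sse <- function(th) {
    fn <- make_fn(th)
    rate_g <- eval_rate(fn, su$grid)
    pen <- 1e10 * rate_bounds_violation(fn)^2
    if (!is.null(slope_limits)) {
      sv <- pmax(0, slope_limits[1L] - th[-1L], th[-1L] - slope_limits[2L]) /
        max(abs(slope_limits))
      pen <- pen + 1e6 * sum(sv^2)
    }
    if (which == "resorption") {
      r_g <- rate_g; f_g <- rep(fixed_rate, n_grid)
    } else {
      r_g <- rep(fixed_rate, n_grid); f_g <- rate_g
    }
    B_g <- .project_bone(su$grid, su$ob_g, su$oc_g, r_g, f_g, su$B_0)
    sum((B_g[su$idx_obs] - su$sB$mean)^2 / su$sB$sigma^2) + pen
  }

  starts <- with_seed(seed, {
    lapply(seq_len(max(restarts, 1L)), function(k) {
      if (k == 1L) c(scale, rep(0, n_segments))
      else c(scale * exp(rnorm(1, 0, 0.5)),
             rnorm(n_segments, 0, 0.5 * scale / seg))
    })
  })
  parscale <- c(scale, rep(scale / seg, n_segments))
  runs <- lapply(seq_along(starts), function(k) {
    simplex_minimize(sse, starts[[k]], restarts = 1, seed = seed + k,
                     parscale = parscale)
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]

  fn <- make_fn(best$par)
  if (rate_bounds_violation(fn) > 1e-6) {
    warning("fitted piecewise rate violates its hard bounds; penalty did not bind")
  }
  rate_g <- eval_rate(fn, su$grid)
  if (which == "resorption") {
    r_g <- rate_g; f_g <- rep(fixed_rate, n_grid)
  } else {
    r_g <- rep(fixed_rate, n_grid); f_g <- rate_g
  }
  B_g <- .project_bone(su$grid, su$ob_g, su$oc_g, r_g, f_g, su$B_0)
  preds <- .bone_predictions(su, B_g)
  params <- cell_fit$params
  if (which == "resorption") params$Pi_B <- fixed_rate else params$delta_B <- fixed_rate
  free <- c(rate_0 = best$par[1L],
            setNames(best$par[-1L], paste0("slope_", seq_len(n_segments))))
  .new_bone_fit("piecewise", params, cell_fit$baseline, free, preds, data,
                converged = best$converged,
                n_evals = sum(vapply(runs, `[[`, numeric(1), "n_evals")),
                seed = seed, variables = "B",
                extras = list(cell_fit = cell_fit, grid_dt = grid_dt,
                              which = which, fixed_rate = fixed_rate,
                              rate_fn = fn, restart_values = values))
}

#' Fit a bone repair model (umbrella interface)
#'
#' Dispatches to the staged workflow functions.  For any bone-stage workflow
#' the cell dynamics are calibrated first (or taken from `cell_fit` if
#' supplied) and frozen, exactly as in the staged scheme the model was built
#' for.
#'
#' @param data a [bone_dataset()].
#' @param workflow one of `"cells"`, `"scan"`, `"free_rates"`,
#'   `"modulation"`, `"piecewise"`.
#' @param cell_fit optional precomputed `"bone_fit"` from
#'   [calibrate_cell_dynamics()]; computed with default settings when absent
#'   and needed.
#' @param ... passed on to the workflow function.
#' @return A `"bone_fit"` (or a `"rate_scan"` for `workflow = "scan"`).
#' @examples
#' \donttest{
#' truth <- paper_like_truth()
#' d <- generate_dataset(truth, study_design(noise_cv = 0), seed = 1)
#' cells <- fit_bone_model(d, "cells")
#' coef(cells)
#' }
#' @export
fit_bone_model <- function(data,
                           workflow = c("cells", "scan", "free_rates",
                                        "modulation", "piecewise"),
                           cell_fit = NULL, ...) {
  workflow <- match.arg(workflow)
  if (workflow == "cells") return(calibrate_cell_dynamics(data, ...))
  if (is.null(cell_fit)) cell_fit <- calibrate_cell_dynamics(data)
  switch(workflow,
         scan = scan_constant_rates(data, cell_fit, ...),
         free_rates = fit_free_constant_rates(data, cell_fit, ...),
         modulation = fit_modulation(data, cell_fit, ...),
         piecewise = fit_piecewise_rate(data, cell_fit, ...))
}

#' Bootstrap standard errors for a fitting workflow
#'
#' Bootstrap over replicated datasets, refitting the supplied workflow on
#' each resample; the standard error of a free parameter is the standard
#' deviation of its refitted values.  Two resampling schemes:
#'
#' * `"parametric"` (default): the workflow is fitted once, and bootstrap
#'   replicates are drawn around the *fitted* predictions with the per-point
#'   replicate spread observed in the data (truncated at 0).  Variables the
#'   workflow does not model keep their observed replicates resampled with
#'   replacement.  This captures the full sampling variability of the
#'   estimator, including jumps between local basins.
#' * `"nonparametric"`: replicate values are resampled with replacement
#'   within every (variable, time) cell.
#'
#' Deterministic given `seed`.  Refit failures are counted; more than 20%
#' failures invalidates the result (all SEs `NA`).
#'
#' @param fit_fun a function `bone_dataset -> bone_fit` (e.g.
#'   `function(d) calibrate_cell_dynamics(d)`).
#' @param data a [bone_dataset()].
#' @param n_boot number of bootstrap refits; `0` returns SEs as unavailable
#'   (`NULL`), never as zero.
#' @param seed RNG seed.
#' @param type `"parametric"` or `"nonparametric"`.
#' @return A list of class `"bootstrap_se"`: `se` (named vector or `NULL`),
#'   `n_boot`, `n_failed`, `samples` (refitted coefficient matrix), `seed`.
#' @export
bootstrap_se <- function(fit_fun, data, n_boot = 50, seed = 1,
                         type = c("parametric", "nonparametric")) {
  stopifnot(is.function(fit_fun), inherits(data, "bone_dataset"))
  type <- match.arg(type)
  if (n_boot == 0) {
    return(structure(list(se = NULL, n_boot = 0L, n_failed = 0L,
                          samples = NULL, seed = seed),
                     class = "bootstrap_se"))
  }
  pred0 <- NULL
  if (type == "parametric") {
    fit0 <- suppressWarnings(fit_fun(data))
    pred0 <- fit0$predictions
  }
  sd_tab <- data$summary
  # actual replicate spread (un-floored): zero-noise data must yield zero SEs
  sd_tab$rep_sd <- sd_tab$sem * sqrt(sd_tab$n)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      reps <- data$replicates
      parts <- split(reps, list(reps$variable, reps$time_day), drop = TRUE)
      parts <- lapply(parts, function(d) {
        v <- d$variable[1L]; t0 <- d$time_day[1L]
        mu <- if (is.null(pred0)) NA_real_ else {
          i <- which(pred0$variable == v & pred0$time_day == t0)
          if (length(i)) pred0$value[i[1L]] else NA_real_
        }
        if (is.finite(mu)) {
          s <- sd_tab$rep_sd[sd_tab$variable == v & sd_tab$time_day == t0][1L]
          d$value <- pmax(0, rnorm(nrow(d), mu, s))
        } else {
          d$value <- sample(d$value, nrow(d), replace = TRUE)
        }
        d
      })
      do.call(rbind, parts)
    })
  })
  samples <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    fit <- tryCatch(
      suppressWarnings(fit_fun(bone_dataset(draws[[b]], data$sigma_floor_frac))),
      error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L else samples[[length(samples) + 1L]] <- coef(fit)
  }
  mat <- if (length(samples)) do.call(rbind, samples) else NULL
  se <- if (!is.null(mat)) apply(mat, 2L, sd) else NULL
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d/%d bootstrap refits failed; standard errors invalidated",
                    n_failed, n_boot))
    if (!is.null(se)) se[] <- NA_real_
  }
  structure(list(se = se, n_boot = n_boot, n_failed = n_failed,
                 samples = mat, seed = seed),
            class = "bootstrap_se")
}

#' @export
print.bootstrap_se <- function(x, ...) {
  if (is.null(x$se)) {
    cat("Bootstrap standard errors: unavailable (n_boot = 0)\n")
  } else {
    cat(sprintf("Bootstrap standard errors (%d refits, %d failed):\n",
                x$n_boot, x$n_failed))
    print(signif(x$se, 5))
  }
  invisible(x)
}

#' @export
print.rate_scan <- function(x, ...) {
  cat(sprintf("Constant resorption-rate scan: %d sample(s) on [%g, %g]\n",
              nrow(x$results), x$rate_range[1L], x$rate_range[2L]))
  cat("Best samples by bone R^2:\n")
  print(head(x$results, 5), row.names = FALSE)
  invisible(x)
}
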