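#' Right-hand side of the initial (constant-rate) model
#'
#' The three coupled equations:
#' \deqn{dOB/dt = H_{OB} + \gamma_{OB}\,OB\,[0 \le t \le T_{anab}] - \delta_{OB}\,OB}
#' \deqn{dOC/dt = -Inhib_{OC}\,OC\,[t \le T_{antiCatab}] + R_{OC}\,[t \ge T_{Catab}] - \delta_{OC,clear}\,OC}
#' \deqn{dB/dt = -\delta_B\,OC\,B + \Pi_B\,OB}
#'
#' Resorption is proportional to both osteoclast number and the bone
#' available to resorb; formation is proportional to osteoblast number only.
#' The indicator windows are sharp; [simulate_model()] restarts the solver at
#' every switch time so a discontinuity never straddles a step silently.
#'
#' @param t time (day).
#' @param state named numeric vector `c(OB=, OC=, B=)`.
#' @param params an [initial_parameters()] set.
#' @return Named numeric vector of derivatives `c(OB=, OC=, B=)`.
#' @export
initial_rhs <- function(t, state, params) {
  stopifnot(inherits(params, "initial_model_params"))
  if (any(!is.finite(state))) stop("state must be finite")
  OB <- state[["OB"]]; OC <- state[["OC"]]; B <- state[["B"]]
  dOB <- params$H_OB + params$gamma_OB * OB * (t >= 0 && t <= params$T_anab) -
    params$delta_OB * OB
  dOC <- -params$Inhib_OC * OC * (t <= params$T_antiCatab) +
    params$R_OC * (t >= params$T_Catab) - params$delta_OC_clear * OC
  dB <- -params$delta_B * OC * B + params$Pi_B * OB
  c(OB = dOB, OC = dOC, B = dB)
}

#' Right-hand side of the myeloid-modulated (expanded) model
#'
#' Same OB/OC equations as [initial_rhs()]; the bone equation becomes
#' \deqn{dB/dt = -\delta_B (1 + \alpha P(t))\,OC\,B + \Pi_B (1 + \beta A(t))\,OB,}
#' where `P(t)` and `A(t)` are the pro- and anti-inflammatory driver
#' evaluations (excess fold change over homeostasis, >= 0).  With
#' `alpha = beta = 0` or zero drivers the output equals [initial_rhs()]
#' exactly.
#'
#' @inheritParams initial_rhs
#' @param params an [expanded_parameters()] set.
#' @return Named derivative vector `c(OB=, OC=, B=)`.
#' @export
expanded_rhs <- function(t, state, params) {
  stopifnot(inherits(params, "expanded_model_params"))
  base <- params$base
  d <- initial_rhs(t, state, base)
  P <- eval_driver(params$pro_driver, t)
  A <- eval_driver(params$anti_driver, t)
  OB <- state[["OB"]]; OC <- state[["OC"]]; B <- state[["B"]]
  d[["B"]] <- -base$delta_B * (1 + params$alpha * P) * OC * B +
    base$Pi_B * (1 + params$beta * A) * OB
  d
}

#' Right-hand side with piecewise-linear time-varying rate(s)
#'
#' The initial model with `delta_B` and/or `Pi_B` replaced by the evaluation
#' of a [piecewise_rate()] at `t`.  OB/OC derivatives are unchanged (in the
#' fitting pipeline the cell dynamics are frozen from a prior fit; this RHS
#' simply keeps integrating them from the same parameters).
#'
#' @inheritParams initial_rhs
#' @param resorption_fn,formation_fn [piecewise_rate()] objects or `NULL`
#'   (use the constant rate from `params`).  At most one may be `NULL` when
#'   both are supplied by convention, but any combination is accepted.
#' @return Named derivative vector `c(OB=, OC=, B=)`.
#' @export
piecewise_rhs <- function(t, state, params, resorption_fn = NULL,
                          formation_fn = NULL) {
  d <- initial_rhs(t, state, params)
  db <- eval_rate_or_const(resorption_fn, t, params$delta_B)
  pb <- eval_rate_or_const(formation_fn, t, params$Pi_B)
  d[["B"]] <- -db * state[["OC"]] * state[["B"]] + pb * state[["OB"]]
  d
}

eval_rate_or_const <- function(fn, t, const) {
  if (is.null(fn)) rep(const, length(t)) else eval_rate(fn, t)
}

# switch times where the RHS is non-smooth: indicator edges, piecewise
# breakpoints, driver onsets
.switch_times <- function(params, t_max, resorption_fn = NULL,
                          formation_fn = NULL) {
  base <- if (inherits(params, "expanded_model_params")) params$base else params
  sw <- c(base$T_anab, base$T_antiCatab, base$T_Catab)
  if (!is.null(resorption_fn)) sw <- c(sw, resorption_fn$t_breaks)
  if (!is.null(formation_fn)) sw <- c(sw, formation_fn$t_breaks)
  if (inherits(params, "expanded_model_params")) {
    for (cv in list(params$pro_driver, params$anti_driver)) {
      sw <- c(sw, vapply(cv$pulses, `[[`, numeric(1), "onset"))
    }
  }
  sort(unique(sw[sw > 0 & sw < t_max]))
}

#' Simulate a bone repair model
#'
#' Integrates one of the model variants with the adaptive explicit
#' Runge-Kutta solver (`deSolve::ode`, method `"ode45"`), starting from the
#' homeostatic baseline `(OB_0, OC_0, B_0)`.  The integration is split into
#' sub-intervals at every indicator switch time, piecewise breakpoint and
#' driver onset, so the solver never steps across a discontinuity silently.
#'
#' @param params an [initial_parameters()] or [expanded_parameters()] set;
#'   the variant is inferred from the class.
#' @param baseline a [homeostatic_baseline()]; the initial condition.
#' @param times output grid (day), starting at 0, strictly increasing.
#' @param rtol,atol relative/absolute solver tolerances (defaults 1e-8 and
#'   1e-10).
#' @param resorption_fn,formation_fn optional [piecewise_rate()] objects
#'   replacing the constant rates (initial-model params only).
#' @return A `"bone_trajectory"`: a data frame with columns `time_day`, `OB`,
#'   `OC`, `B` (plus `P`, `A` for the expanded model) and a `meta` attribute
#'   recording the variant, tolerances and parameter snapshot.
#' @examples
#' bl <- homeostatic_baseline(100, 50, 0.2)
#' p <- initial_parameters(delta_B = 7.034e-6, R_OC = 50, baseline = bl,
#'                         close_formation = TRUE)
#' tr <- simulate_model(p, bl, times = 0:14)
#' head(tr)
#' @export
simulate_model <- function(params, baseline, times = seq(0, 14, by = 0.1),
                           rtol = 1e-8, atol = 1e-10,
                           resorption_fn = NULL, formation_fn = NULL) {
  stopifnot(inherits(baseline, "homeostatic_baseline"))
  if (times[1L] != 0) stop("the output grid must start at 0 (baseline defines the initial condition)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  expanded <- inherits(params, "expanded_model_params")
  if (expanded && (!is.null(resorption_fn) || !is.null(formation_fn))) {
    stop("piecewise rates are only supported with initial-model parameters")
  }
  if (!expanded && !inherits(params, "initial_model_params")) {
    stop("params must be initial_model_params or expanded_model_params")
  }

  rhs <- if (expanded) {
    function(t, y, parms) list(unname(expanded_rhs(t, c(OB = y[1L], OC = y[2L], B = y[3L]), params)))
  } else {
    function(t, y, parms) {
      list(unname(piecewise_rhs(t, c(OB = y[1L], OC = y[2L], B = y[3L]), params,
                                resorption_fn, formation_fn)))
    }
  }

  t_max <- times[length(times)]
  sw <- .switch_times(params, t_max, resorption_fn, formation_fn)
  edges <- unique(c(0, sw, t_max))
  y <- c(baseline$OB_0, baseline$OC_0, baseline$B_0)
  out_t <- numeric(0); out_y <- NULL
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    seg_t <- unique(sort(c(a, times[times > a & times <= b], b)))
    sol <- tryCatch(
      deSolve::ode(y = y, times = seg_t, func = rhs, parms = NULL,
                   method = "ode45", rtol = rtol, atol = atol),
      error = function(e) e
    )
    if (inherits(sol, "error") || any(!is.finite(sol[, -1L]))) {
      stop(sprintf(paste0("integration failed on [%g, %g]: %s\n",
                          "parameter snapshot: %s"),
                   a, b,
                   if (inherits(sol, "error")) conditionMessage(sol) else "non-finite state",
                   paste(deparse(unlist(if (expanded) params$base else params)),
                         collapse = " ")))
    }
    keep <- sol[, 1L] %in% times & !(sol[, 1L] %in% out_t)
    out_t <- c(out_t, sol[keep, 1L])
    out_y <- rbind(out_y, sol[keep, -1L, drop = FALSE])
    y <- unname(sol[nrow(sol), -1L])
  }
  ord <- order(out_t)
  out_t <- out_t[ord]; out_y <- out_y[ord, , drop = FALSE]
  # the model is structurally non-negative; clip solver-level rounding only
  neg <- out_y < 0
  if (any(neg)) {
    worst <- min(out_y[neg])
    if (worst < -1e4 * atol) {
      stop(sprintf("simulation produced a negative state (%g) beyond solver rounding", worst))
    }
    out_y[neg] <- 0
  }
  traj <- data.frame(time_day = out_t, OB = out_y[, 1L], OC = out_y[, 2L],
                     B = out_y[, 3L])
  if (expanded) {
    traj$P <- eval_driver(params$pro_driver, traj$time_day)
    traj$A <- eval_driver(params$anti_driver, traj$time_day)
  }
  structure(traj,
            meta = list(variant = if (expanded) "expanded" else
              if (is.null(resorption_fn) && is.null(formation_fn)) "initial" else "piecewise",
              rtol = rtol, atol = atol, params = params, baseline = baseline),
            class = c("bone_trajectory", "data.frame"))
}

#' Exact cell (OB/OC) trajectories of the initial model
#'
#' The osteoblast and osteoclast equations are linear with
#' piecewise-constant coefficients, so between switch times they solve in
#' closed form: `x(t) = -c/a + (x0 + c/a) exp(a (t - t0))` for `x' = c + a x`.
#' This exact solution is what the calibration stage evaluates (it is fast
#' and free of integration error); [simulate_model()] provides the
#' independent numerical route and the two are cross-checked in the tests.
#'
#' @param params an [initial_parameters()] set.
#' @param baseline a [homeostatic_baseline()].
#' @param times evaluation times (day), `>= 0`, any order.
#' @return A data frame with columns `time_day`, `OB`, `OC`.
#' @export
cell_trajectories <- function(params, baseline, times) {
  stopifnot(inherits(params, "initial_model_params"),
            inherits(baseline, "homeostatic_baseline"))
  if (any(times < 0)) stop("times must be >= 0")
  ord <- order(times)
  ts <- times[ord]
  t_max <- if (length(ts)) ts[length(ts)] else 0
  edges <- unique(sort(c(0, .switch_times(params, t_max), t_max)))
  step <- function(x0, a, c0, dt) {
    if (abs(a) < 1e-14) x0 + c0 * dt else -c0 / a + (x0 + c0 / a) * exp(a * dt)
  }
  step_vec <- function(x0, a, c0, dts) {
    if (abs(a) < 1e-14) x0 + c0 * dts else -c0 / a + (x0 + c0 / a) * exp(a * dts)
  }
  OB <- numeric(length(ts)); OC <- numeric(length(ts))
  ob0 <- baseline$OB_0; oc0 <- baseline$OC_0
  if (length(ts) && ts[1L] == 0) { OB[ts == 0] <- ob0; OC[ts == 0] <- oc0 }
  for (k in seq_len(max(length(edges) - 1L, 0L))) {
    a0 <- edges[k]; b0 <- edges[k + 1L]
    tm <- (a0 + b0) / 2
    a_ob <- params$gamma_OB * (tm <= params$T_anab) - params$delta_OB
    c_ob <- params$H_OB
    a_oc <- -params$Inhib_OC * (tm <= params$T_antiCatab) - params$delta_OC_clear
    c_oc <- params$R_OC * (tm >= params$T_Catab)
    inside <- ts > a0 & ts <= b0
    if (any(inside)) {
      dts <- ts[inside] - a0
      OB[inside] <- step_vec(ob0, a_ob, c_ob, dts)
      OC[inside] <- step_vec(oc0, a_oc, c_oc, dts)
    }
    ob0 <- step(ob0, a_ob, c_ob, b0 - a0)
    oc0 <- step(oc0, a_oc, c_oc, b0 - a0)
  }
  res <- data.frame(time_day = times, OB = NA_real_, OC = NA_real_)
  res$OB[ord] <- OB
  res$OC[ord] <- OC
  res
}

# exact integrating-factor solution of the (linear, scalar) bone equation
#   b' = -r(t) oc(t) b + f(t) ob(t)
# on a fixed grid, with cumulative trapezoidal quadrature.  Used by the
# bone-stage fitting workflows where the cell dynamics are frozen.
.project_bone <- function(grid, ob_g, oc_g, r_g, f_g, B0) {
  a <- r_g * oc_g
  A <- as.vector(pracma::cumtrapz(grid, a))
  g <- f_g * ob_g * exp(A)
  as.vector(exp(-A) * (B0 + as.vector(pracma::cumtrapz(grid, g))))
}

# fitting grid for the bone stage: fine regular grid plus the observation
# times and any rate/driver knots
.bone_grid <- function(times_obs, t_max, dt = 0.005, knots = NULL) {
  sort(unique(c(seq(0, t_max, by = dt), t_max, times_obs,
                knots[knots >= 0 & knots <= t_max])))
}
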