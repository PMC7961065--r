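#' Homeostatic baseline state
#'
#' The pre-injury steady state `(OB_0, OC_0, B_0)`.  Baseline values double as
#' the initial conditions of every simulation and as the anchors of the
#' homeostasis closures (see [closure_source_ob()], [closure_oc_clearance()],
#' [closure_formation_rate()]).
#'
#' @param OB_0 baseline osteoblast abundance (cells per reference marrow
#'   volume), strictly positive.
#' @param OC_0 baseline osteoclast abundance (same units), strictly positive.
#' @param B_0 baseline bone volume (mm^3, or a BV/TV fraction used
#'   consistently), strictly positive.
#' @return An object of class `"homeostatic_baseline"`.
#' @examples
#' homeostatic_baseline(OB_0 = 100, OC_0 = 50, B_0 = 0.2)
#' @export
homeostatic_baseline <- function(OB_0, OC_0, B_0) {
  for (nm in c("OB_0", "OC_0", "B_0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("baseline component '%s' must be a single finite value > 0", nm))
    }
  }
  structure(list(OB_0 = OB_0, OC_0 = OC_0, B_0 = B_0),
            class = "homeostatic_baseline")
}

#' @export
print.homeostatic_baseline <- function(x, ...) {
  cat(sprintf("Homeostatic baseline: OB_0 = %g, OC_0 = %g, B_0 = %g\n",
              x$OB_0, x$OC_0, x$B_0))
  invisible(x)
}

.check_nonneg <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single finite value >= 0", nm))
  }
  x
}

#' Homeostasis closure: osteoblast source term
#'
#' Fixes the osteoblast source at `H_OB = delta_OB * OB_0` so that, absent
#' injury, the osteoblast level is stationary at its baseline.
#'
#' @param delta_OB osteoblast clearance rate (1/day), >= 0.
#' @param baseline a [homeostatic_baseline()].
#' @return The source rate `H_OB` (cells/day).
#' @examples
#' closure_source_ob(0.19, homeostatic_baseline(100, 50, 0.2))
#' @export
closure_source_ob <- function(delta_OB, baseline) {
  .check_nonneg(delta_OB, "delta_OB")
  stopifnot(inherits(baseline, "homeostatic_baseline"))
  delta_OB * baseline$OB_0
}

#' Homeostasis closure: osteoclast clearance rate
#'
#' Fixes the homeostatic osteoclast clearance at `R_OC / OC_0` so that the
#' replenishment source returns the osteoclast pool to its baseline level.
#'
#' @param R_OC osteoclast replenishment rate (cells/day), >= 0.
#' @inheritParams closure_source_ob
#' @return The clearance rate `delta_OC_clear` (1/day).
#' @export
closure_oc_clearance <- function(R_OC, baseline) {
  .check_nonneg(R_OC, "R_OC")
  stopifnot(inherits(baseline, "homeostatic_baseline"))
  R_OC / baseline$OC_0
}

#' Homeostasis closure: bone formation rate
#'
#' Fixes the per-cell bone formation rate at
#' `Pi_B = delta_B * OC_0 * B_0 / OB_0`, which makes `dB/dt = 0` exactly when
#' all three variables sit at baseline.
#'
#' @param delta_B per-cell, per-bone-volume resorption rate (1/cell/day), >= 0.
#' @inheritParams closure_source_ob
#' @return The formation rate `Pi_B` (mm^3/cell/day).
#' @examples
#' closure_formation_rate(7.034e-6, homeostatic_baseline(100, 50, 0.2))
#' @export
closure_formation_rate <- function(delta_B, baseline) {
  .check_nonneg(delta_B, "delta_B")
  stopifnot(inherits(baseline, "homeostatic_baseline"))
  if (baseline$OB_0 == 0) stop("OB_0 must be > 0 for the formation closure")
  delta_B * baseline$OC_0 * baseline$B_0 / baseline$OB_0
}

#' Parameters of the initial (constant-rate) bone repair model
#'
#' Collects all rate constants and switch times of the three-variable model.
#' Injury is encoded by sharp indicator windows: osteoblasts proliferate at
#' rate `gamma_OB` while `0 <= t <= T_anab`; osteoclasts decrease at rate
#' `Inhib_OC` while `t <= T_antiCatab` and are replenished at rate `R_OC`
#' once `t >= T_Catab` (with `T_Catab = 0` meaning the source is never
#' interrupted); homeostatic clearance of osteoclasts is always active.
#'
#' `H_OB`, `delta_OC_clear` and (optionally) `Pi_B` are usually not chosen
#' freely but set by the homeostasis closures: pass a `baseline` and they are
#' filled in via [closure_source_ob()], [closure_oc_clearance()] and, when
#' `close_formation = TRUE`, [closure_formation_rate()].
#'
#' @param delta_OB osteoblast clearance rate (1/day); the literature value is
#'   0.19/day.
#' @param gamma_OB osteoblast proliferation rate during the anabolic window
#'   (1/day).
#' @param T_anab duration of the anabolic osteoblast expansion (day).
#' @param Inhib_OC osteoclast decrease rate after injury (1/day).
#' @param T_antiCatab duration of the osteoclast decrease (day).
#' @param T_Catab start time of osteoclast replenishment (day).
#' @param R_OC osteoclast replenishment rate (cells/day).
#' @param delta_B per-cell, per-bone-volume resorption rate (1/cell/day).
#' @param Pi_B per-cell bone formation rate (mm^3/cell/day).
#' @param H_OB osteoblast source term (cells/day); set by closure when a
#'   `baseline` is supplied.
#' @param delta_OC_clear homeostatic osteoclast clearance rate (1/day); set by
#'   closure when a `baseline` is supplied.
#' @param baseline optional [homeostatic_baseline()]; if given, the closures
#'   are applied.
#' @param close_formation if `TRUE` (and `baseline` given), also fix `Pi_B` by
#'   the formation closure, overriding any supplied value.
#' @return An object of class `"initial_model_params"`.
#' @examples
#' bl <- homeostatic_baseline(100, 50, 0.2)
#' p <- initial_parameters(gamma_OB = 0.873, T_anab = 6.6924,
#'                         Inhib_OC = 1.2186, T_antiCatab = 2, T_Catab = 2,
#'                         R_OC = 6774.8, delta_B = 7.034e-6,
#'                         baseline = bl, close_formation = TRUE)
#' p$Pi_B  # delta_B * OC_0 * B_0 / OB_0
#' @export
initial_parameters <- function(delta_OB = 0.19, gamma_OB = 0, T_anab = 0,
                               Inhib_OC = 0, T_antiCatab = 0, T_Catab = 0,
                               R_OC = 0, delta_B = 0, Pi_B = 0,
                               H_OB = 0, delta_OC_clear = 0,
                               baseline = NULL, close_formation = FALSE) {
  p <- list(delta_OB = delta_OB, gamma_OB = gamma_OB, T_anab = T_anab,
            Inhib_OC = Inhib_OC, T_antiCatab = T_antiCatab, T_Catab = T_Catab,
            R_OC = R_OC, delta_B = delta_B, Pi_B = Pi_B,
            H_OB = H_OB, delta_OC_clear = delta_OC_clear)
  for (nm in names(p)) .check_nonneg(p[[nm]], nm)
  p <- structure(p, class = "initial_model_params")
  if (!is.null(baseline)) {
    p <- apply_closures(p, baseline, formation = close_formation)
  }
  p
}

#' Apply the homeostasis closures to a parameter set
#'
#' Sets `H_OB = delta_OB * OB_0`, `delta_OC_clear = R_OC / OC_0` and, if
#' `formation = TRUE`, `Pi_B = delta_B * OC_0 * B_0 / OB_0`.
#'
#' @param params an `"initial_model_params"` object.
#' @param baseline a [homeostatic_baseline()].
#' @param formation apply the formation-rate closure as well?
#' @return The updated parameter set.
#' @export
apply_closures <- function(params, baseline, formation = TRUE) {
  stopifnot(inherits(params, "initial_model_params"))
  params$H_OB <- closure_source_ob(params$delta_OB, baseline)
  params$delta_OC_clear <- closure_oc_clearance(params$R_OC, baseline)
  if (formation) {
    params$Pi_B <- closure_formation_rate(params$delta_B, baseline)
  }
  params
}

#' @export
print.initial_model_params <- function(x, ...) {
  cat("Initial bone repair model parameters:\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-14s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Parameters of the myeloid-modulated (expanded) model
#'
#' Extends the initial model with multiplicative modulation of the per-cell
#' remodeling rates by imposed myeloid driver curves: the bone equation
#' becomes
#' `dB/dt = -delta_B * (1 + alpha * P(t)) * OC * B + Pi_B * (1 + beta * A(t)) * OB`,
#' where `P(t)` is the combined pro-inflammatory monocyte/macrophage excess
#' fold change over homeostasis and `A(t)` the anti-inflammatory macrophage
#' excess.  Both drivers are 0 at homeostasis, so at `alpha = beta = 0` (or
#' with zero drivers) the model reduces exactly to the initial model.
#'
#' @param base an `"initial_model_params"` object (OB/OC equations and the
#'   homeostatic `delta_B`, `Pi_B`).
#' @param alpha pro-inflammatory resorption-stimulation factor
#'   (dimensionless per unit driver fold change), >= 0.
#' @param beta anti-inflammatory formation-stimulation factor, >= 0.
#' @param pro_driver a [driver_curve()] for the combined pro-inflammatory
#'   signal (see [combine_pro_driver()]).
#' @param anti_driver a [driver_curve()] for the anti-inflammatory macrophage
#'   signal.
#' @return An object of class `"expanded_model_params"`.
#' @export
expanded_parameters <- function(base, alpha, beta, pro_driver, anti_driver) {
  stopifnot(inherits(base, "initial_model_params"))
  .check_nonneg(alpha, "alpha")
  .check_nonneg(beta, "beta")
  stopifnot(inherits(pro_driver, "driver_curve"),
            inherits(anti_driver, "driver_curve"))
  structure(list(base = base, alpha = alpha, beta = beta,
                 pro_driver = pro_driver, anti_driver = anti_driver),
            class = "expanded_model_params")
}

#' @export
print.expanded_model_params <- function(x, ...) {
  cat("Myeloid-modulated bone repair model parameters:\n")
  cat(sprintf("  alpha = %g, beta = %g\n", x$alpha, x$beta))
  cat(sprintf("  pro driver: %d pulse(s); anti driver: %d pulse(s)\n",
              length(x$pro_driver$pulses), length(x$anti_driver$pulses)))
  print(x$base)
  invisible(x)
}
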