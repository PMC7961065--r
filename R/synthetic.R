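#' Study design for synthetic data generation
#'
#' The sampling scheme of the injury time-course study: sparse time points
#' (days 0, 1, 2, 3, 7 and 14), a fixed number of animals per time point and
#' multiplicative observation noise.
#'
#' @param times sampling days (sorted, must include 0).
#' @param n_replicates animals per time point (>= 1, default 5).
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise (default 0.10).
#' @param seed default RNG seed for [generate_dataset()].
#' @param variables variables to emit (default all six study variables).
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(times = c(0, 1, 2, 3, 7, 14), n_replicates = 5,
                         noise_cv = 0.10, seed = 1,
                         variables = c("OB", "OC", "B", "pro_mono",
                                       "pro_mac", "anti_mac")) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1L] != 0) stop("times must include day 0 (the baseline)")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(times = times, n_replicates = n_replicates,
                 noise_cv = noise_cv, seed = seed, variables = variables),
            class = "study_design")
}

#' Ground truth for synthetic data
#'
#' Bundles a simulable parameter set, its baseline and (for the expanded
#' model) the individual myeloid driver curves, so that every generated
#' dataset carries its generating truth for parameter-recovery tests.
#'
#' @param params an [initial_parameters()] or [expanded_parameters()] set.
#' @param baseline a [homeostatic_baseline()].
#' @param drivers optional named list of per-population [driver_curve()]s
#'   (`pro_mono`, `pro_mac`, `anti_mac`, `anti_mono`) used to emit myeloid
#'   variables.
#' @param design default [study_design()].
#' @param resorption_fn,formation_fn optional [piecewise_rate()] objects for
#'   a time-varying-rate truth (initial-model `params` only).
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(params, baseline, drivers = NULL,
                         design = study_design(),
                         resorption_fn = NULL, formation_fn = NULL) {
  stopifnot(inherits(params, "initial_model_params") ||
              inherits(params, "expanded_model_params"),
            inherits(baseline, "homeostatic_baseline"),
            inherits(design, "study_design"))
  structure(list(params = params, baseline = baseline, drivers = drivers,
                 design = design, resorption_fn = resorption_fn,
                 formation_fn = formation_fn),
            class = "ground_truth")
}

#' Packaged study-like ground truth
#'
#' A fixture with the literature/estimated cell parameters
#' (`delta_OB = 0.19`, `gamma_OB = 0.873`, `T_anab = 6.6924`,
#' `Inhib_OC = 1.2186`, `T_antiCatab = 2`, `T_Catab = 2`,
#' `R_OC = 6774.8`), documented synthetic baselines
#' (`OB_0 = 2000`, `OC_0 = 20000`, `B_0 = 0.28404` mm^3 -- chosen once so
#' that the formation closure lands on the reported homeostatic osteoblast
#' activity of 1.21e-6 mm^3/cell/day), a two-wave pro-inflammatory driver
#' (waves near day 1 and day 7) and an anti-inflammatory macrophage pulse
#' spanning days 1-3.  The homeostatic resorption rate is 4.26e-7
#' mm^3/cell/day and `alpha`, `beta` are set so the modulated osteoclast and
#' osteoblast activities span exactly 4.26e-7..7.28e-6 and
#' 1.21e-6..2.63e-6 mm^3/cell/day: an ~17-fold and ~2.2-fold range.
#' The implied bone trajectory is biphasic: a resorption-driven dip by day 2
#' followed by an overshoot past baseline by day 7.
#'
#' @return A [ground_truth()] with expanded-model parameters.
#' @examples
#' truth <- paper_like_truth()
#' truth$params$alpha
#' @export
paper_like_truth <- function() {
  baseline <- homeostatic_baseline(OB_0 = 2000, OC_0 = 20000, B_0 = 0.28404)
  base <- initial_parameters(delta_OB = 0.19, gamma_OB = 0.873,
                             T_anab = 6.6924, Inhib_OC = 1.2186,
                             T_antiCatab = 2, T_Catab = 2, R_OC = 6774.8,
                             delta_B = 4.26e-7, baseline = baseline,
                             close_formation = TRUE)
  pro_mono <- driver_curve(list(
    list(amplitude = 20, onset = 0.1, rise_time = 0.6, decay_time = 1.2),
    list(amplitude = 4, onset = 5.5, rise_time = 1.5, decay_time = 0.3)),
    name = "pro_mono")
  pro_mac <- driver_curve(list(
    list(amplitude = 10, onset = 0.3, rise_time = 0.9, decay_time = 1.1)),
    name = "pro_mac")
  anti_mac <- driver_curve(list(
    list(amplitude = 8, onset = 1.8, rise_time = 1.5, decay_time = 0.6)),
    name = "anti_mac")
  anti_mono <- driver_curve(list(), name = "anti_mono")
  pro <- combine_pro_driver(pro_mono, pro_mac)

  tg <- seq(0, 14, by = 0.001)
  P_max <- max(eval_driver(pro, tg))
  A_max <- max(eval_driver(anti_mac, tg))
  alpha <- (7.28e-6 / base$delta_B - 1) / P_max
  beta <- (2.63e-6 / base$Pi_B - 1) / A_max

  params <- expanded_parameters(base, alpha = alpha, beta = beta,
                                pro_driver = pro, anti_driver = anti_mac)
  ground_truth(params, baseline,
               drivers = list(pro_mono = pro_mono, pro_mac = pro_mac,
                              anti_mac = anti_mac, anti_mono = anti_mono))
}

#' Generate a replicated synthetic dataset
#'
#' Simulates the ground truth at the design time points, then draws each
#' replicate as `trajectory * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`, truncated at zero (counts and volumes are
#' non-negative).  Myeloid variables are emitted as fold change relative to
#' homeostasis (1 at day 0): `1 + driver excess`.  Per-time-point sigma is
#' the SEM of the replicates (with the [bone_dataset()] floor where the
#' replicates carry no spread).  Deterministic given `seed`.
#'
#' @param truth a [ground_truth()].
#' @param design a [study_design()] (default: the truth's own design).
#' @param seed RNG seed (default: the design's seed).
#' @param trajectory optional precomputed noiseless trajectory (a
#'   `"bone_trajectory"` on exactly `design$times`) to avoid re-simulating;
#'   used when drawing many datasets from one truth.
#' @return A [bone_dataset()].
#' @export
generate_dataset <- function(truth, design = truth$design, seed = design$seed,
                             trajectory = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"))
  if (is.null(trajectory)) {
    trajectory <- simulate_model(truth$params, truth$baseline,
                                 times = design$times,
                                 resorption_fn = truth$resorption_fn,
                                 formation_fn = truth$formation_fn)
  }
  stopifnot(identical(as.numeric(trajectory$time_day), as.numeric(design$times)))

  clean <- list(OB = trajectory$OB, OC = trajectory$OC, B = trajectory$B)
  if (!is.null(truth$drivers)) {
    for (nm in names(truth$drivers)) {
      clean[[nm]] <- 1 + eval_driver(truth$drivers[[nm]], design$times)
    }
  }
  vars <- intersect(design$variables, names(clean))
  if (length(vars) == 0L) stop("no requested variable is defined by the truth")

  rows <- with_seed(seed, {
    out <- list()
    for (v in vars) {
      for (i in seq_along(design$times)) {
        mu <- clean[[v]][i]
        eps <- rnorm(design$n_replicates, 0, design$noise_cv)
        out[[length(out) + 1L]] <- data.frame(
          variable = v, time_day = design$times[i],
          replicate = seq_len(design$n_replicates),
          value = pmax(0, mu * (1 + eps)))
      }
    }
    do.call(rbind, out)
  })
  bone_dataset(rows)
}
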