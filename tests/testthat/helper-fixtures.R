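# shared fixtures, memoized so expensive fits are computed once per run

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# Table-1-style generating truth for the cell dynamics
table1_cells <- c(gamma_OB = 0.873, T_anab = 6.6924, Inhib_OC = 1.2186,
                  T_antiCatab = 2, R_OC = 6774.8)

fx_truth <- function() memo("truth", paper_like_truth())

# noiseless dataset from the study-like fixture (all six variables)
fx_data0 <- function() memo("data0", {
  generate_dataset(fx_truth(), study_design(noise_cv = 0), seed = 1)
})

fx_cell_fit0 <- function() memo("cell_fit0", {
  calibrate_cell_dynamics(fx_data0())
})

# constant-rate initial-model truth (free-rate workflow recovery)
fx_const_truth <- function() memo("const_truth", {
  truth <- fx_truth()
  p <- truth$params$base
  p$delta_B <- 5.7687e-6
  p$Pi_B <- 1.2164e-6
  ground_truth(p, truth$baseline,
               design = study_design(noise_cv = 0,
                                     variables = c("OB", "OC", "B")))
})

# two-wave time-varying resorption truths: a sharp wave between days 1 and 2
# and a milder persistent wave after day 3; the "overshoot" variant resorbs
# hard enough late that the bone data end below baseline
two_wave_rate_fn <- function(kind = c("recovery", "overshoot")) {
  kind <- match.arg(kind)
  tb <- c(0, 1, 2, 3, 5, 7, 10, 14)
  nodes <- if (kind == "recovery") {
    c(4.26e-7, 7e-6, 4e-6, 1e-6, 8e-6, 1.8e-5, 1.6e-5, 1.2e-5)
  } else {
    c(4.26e-7, 7e-6, 4e-6, 1.5e-6, 2e-5, 4.2e-5, 3.2e-5, 2.4e-5)
  }
  piecewise_rate(tb, nodes[1L], diff(nodes) / diff(tb),
                 lower_bound = 1e-8, upper_bound = 5e-5)
}

fx_two_wave_data <- function() memo("two_wave_data", {
  truth <- fx_truth()
  gt <- ground_truth(truth$params$base, truth$baseline,
                     design = study_design(times = 0:14, noise_cv = 0,
                                           variables = c("OB", "OC", "B")),
                     resorption_fn = two_wave_rate_fn("recovery"))
  generate_dataset(gt, seed = 5)
})

fx_two_wave_cells <- function() memo("two_wave_cells", {
  calibrate_cell_dynamics(fx_two_wave_data())
})

fx_piecewise_fit <- function() memo("piecewise_fit", {
  fit_piecewise_rate(fx_two_wave_data(), fx_two_wave_cells(),
                     which = "resorption",
                     fixed_rate = fx_truth()$params$base$Pi_B,
                     n_segments = 8, seed = 7)
})

fx_modulation_fit0 <- function() memo("modulation_fit0", {
  truth <- fx_truth()
  fit_modulation(fx_data0(), fx_cell_fit0(), truth$params$pro_driver,
                 truth$params$anti_driver, seed = 2)
})

# small driver dataset generator (dense design so pulses are identifiable)
driver_dataset <- function(curve, times = seq(0, 14, by = 0.5), n_rep = 3,
                           variable = "pro_mono") {
  rows <- do.call(rbind, lapply(times, function(t) {
    data.frame(variable = variable, time_day = t, replicate = seq_len(n_rep),
               value = 1 + eval_driver(curve, t))
  }))
  bone_dataset(rows)
}
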