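make_tiny_dataset <- function(seed = 1, vars = c("OB", "OC", "B"),
                              times = c(0, 1, 2, 3, 7, 14)) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(vars, function(v) {
    do.call(rbind, lapply(times, function(t) {
      mu <- runif(1, 10, 100)
      data.frame(variable = v, time_day = t, replicate = 1:5,
                 value = abs(mu + rnorm(5, 0, 5)))
    }))
  }))
  bone_dataset(rows)
}

test_that("the minimax objective equals a brute-force double loop", {
  d <- make_tiny_dataset(11)
  set.seed(12)
  preds <- d$summary[, c("variable", "time_day")]
  preds$value <- d$summary$mean * exp(rnorm(nrow(preds), 0, 0.2))
  obj <- objective_ls(preds, d)
  # independent double loop over variables and time points
  per <- sapply(unique(as.character(d$summary$variable)), function(v) {
    tot <- 0
    for (i in seq_len(nrow(d$summary))) {
      if (d$summary$variable[i] == v) {
        j <- which(preds$variable == v & preds$time_day == d$summary$time_day[i])
        tot <- tot + (preds$value[j] - d$summary$mean[i])^2 / d$summary$sigma[i]^2
      }
    }
    tot
  })
  expect_equal(obj$per_variable[names(per)], per, tolerance = 1e-12)
  expect_equal(obj$LS, max(per), tolerance = 1e-12)
})

test_that("the objective is invariant under variable and time permutations", {
  d <- make_tiny_dataset(13)
  preds <- d$summary[, c("variable", "time_day")]
  preds$value <- d$summary$mean * 1.1
  obj1 <- objective_ls(preds, d)
  obj2 <- objective_ls(preds[rev(seq_len(nrow(preds))), ], d,
                       variables = rev(d$variables))
  expect_equal(obj1$LS, obj2$LS)
  expect_equal(sort(obj1$per_variable), sort(obj2$per_variable))
})

test_that("perfect predictions give LS = 0 and the max picks the worst variable", {
  d <- make_tiny_dataset(14)
  perfect <- d$summary[, c("variable", "time_day")]
  perfect$value <- d$summary$mean
  expect_equal(objective_ls(perfect, d)$LS, 0)
  # two variables with known inner sums: the max is reported
  rows <- rbind(
    data.frame(variable = "OB", time_day = c(0, 1), replicate = 1,
               value = c(10, 10)),
    data.frame(variable = "OC", time_day = c(0, 1), replicate = 1,
               value = c(10, 10)))
  d2 <- bone_dataset(rows)  # sigma floor: 0.5 for both variables
  preds <- data.frame(variable = c("OB", "OB", "OC", "OC"),
                      time_day = c(0, 1, 0, 1),
                      value = c(10 + 0.5 * sqrt(3), 10, 10 + 0.5 * sqrt(7.5), 10))
  obj <- objective_ls(preds, d2)
  expect_equal(unname(obj$per_variable[c("OB", "OC")]), c(3, 7.5))
  expect_equal(obj$LS, 7.5)
  expect_error(objective_ls(preds[1:2, ], d2), "missing prediction")
})

test_that("the box penalty is zero inside bounds and grows with violation", {
  f <- function(p) sum(p^2)
  pf <- penalized_objective(f, list(lower = c(-1, 0), upper = c(1, 2)))
  expect_equal(pf(c(0.5, 1)), f(c(0.5, 1)))
  expect_equal(pf(c(-1, 2)), f(c(-1, 2)))  # boundary is feasible
  expect_gt(pf(c(0, 4)), f(c(0, 4)))       # 2x the upper bound
  set.seed(5)
  for (r in 1:20) {
    v1 <- runif(1, 0, 3); v2 <- v1 + runif(1, 0.1, 2)
    expect_lt(pf(c(0, 2 + v1)) - f(c(0, 2 + v1)),
              pf(c(0, 2 + v2)) - f(c(0, 2 + v2)))
  }
})

test_that("the simplex finds a quadratic bowl minimum and is deterministic", {
  f <- function(p) (p[1] - 3)^2 + (p[2] + 1)^2
  res <- simplex_minimize(f, c(0, 0), restarts = 3, seed = 9)
  expect_equal(res$par, c(3, -1), tolerance = 1e-4)
  res2 <- simplex_minimize(f, c(0, 0), restarts = 3, seed = 9)
  expect_identical(res$par, res2$par)
  expect_identical(res$value, res2$value)
})

test_that("AIC is 2p + LS and penalizes extra parameters at equal fit", {
  expect_identical(aic(3, 10), 16)
  expect_identical(aic(0, 0), 0)
  expect_lt(aic(2, 5.5), aic(4, 5.5))
  expect_error(aic(-1, 0), ">= 0")
})

test_that("cell calibration recovers the generating truth on noiseless data", {
  cf <- fx_cell_fit0()
  est <- coef(cf)[names(table1_cells)]
  expect_true(all(abs(est - table1_cells) / table1_cells < 0.05))
  expect_true(cf$converged)
  # the stored pieces re-derive the objective and AIC exactly
  expect_identical(cf$LS, max(cf$per_variable_SS))
  expect_identical(cf$AIC, 2 * 5 + cf$LS)
})

test_that("flat homeostatic data are flagged and shrink the injury terms", {
  truth <- fx_truth()
  flat_p <- initial_parameters(delta_OB = 0.19, R_OC = 6774.8, T_Catab = 0,
                               baseline = truth$baseline)
  gt <- ground_truth(flat_p, truth$baseline,
                     design = study_design(noise_cv = 0,
                                           variables = c("OB", "OC", "B")))
  d <- generate_dataset(gt, seed = 2)
  w <- capture_warnings(cf <- calibrate_cell_dynamics(d))
  expect_true(any(grepl("flat homeostasis", w)))
  expect_lt(coef(cf)[["gamma_OB"]], 0.05)
  expect_lt(coef(cf)[["Inhib_OC"]], 0.05)
})

test_that("the constant-rate scan lands on the grid point nearest the truth", {
  truth <- fx_truth()
  p <- truth$params$base
  p$delta_B <- 7.034e-6
  p <- apply_closures(p, truth$baseline, formation = TRUE)
  gt <- ground_truth(p, truth$baseline,
                     design = study_design(noise_cv = 0,
                                           variables = c("OB", "OC", "B")))
  d <- generate_dataset(gt, seed = 4)
  cf <- calibrate_cell_dynamics(d)
  sc <- scan_constant_rates(d, cf, n_samples = 25)
  grid <- exp(seq(log(1e-8), log(5e-5), length.out = 25))
  nearest <- grid[which.min(abs(log(grid) - log(7.034e-6)))]
  expect_equal(sc$results$delta_B[1], nearest)
  # every scanned fit satisfies the closure identity exactly
  for (f in sc$fits) {
    expect_identical(f$params$Pi_B * truth$baseline$OB_0,
                     f$params$delta_B * truth$baseline$OC_0 * truth$baseline$B_0)
  }
  # a single sample placed at the truth reproduces the bone data
  sc1 <- scan_constant_rates(d, cf, rate_range = c(7.034e-6, 7.034e-6),
                             n_samples = 1)
  expect_equal(sc1$results$r_squared[1], 1, tolerance = 1e-6)
})

test_that("free constant rates are recovered and closure-consistent truths stay so", {
  d <- generate_dataset(fx_const_truth(), seed = 3)
  cf <- calibrate_cell_dynamics(d)
  ff <- fit_free_constant_rates(d, cf, seed = 2)
  truth_rates <- c(delta_B = 5.7687e-6, Pi_B = 1.2164e-6)
  expect_true(all(abs(coef(ff) - truth_rates) / truth_rates < 0.05))
  expect_identical(ff$AIC, 2 * 2 + ff$LS)

  # closure-consistent generating truth: the recovered pair satisfies the
  # closure identity within the fit tolerance
  truth <- fx_truth()
  p <- truth$params$base
  p$delta_B <- 7.034e-6
  p <- apply_closures(p, truth$baseline, formation = TRUE)
  gt <- ground_truth(p, truth$baseline,
                     design = study_design(noise_cv = 0,
                                           variables = c("OB", "OC", "B")))
  dc <- generate_dataset(gt, seed = 4)
  cfc <- calibrate_cell_dynamics(dc)
  ffc <- fit_free_constant_rates(dc, cfc, seed = 2)
  pi_closure <- closure_formation_rate(coef(ffc)[["delta_B"]], truth$baseline)
  expect_equal(coef(ffc)[["Pi_B"]], pi_closure, tolerance = 0.05)
})

test_that("free rates on resorption-overshoot data end below baseline", {
  truth <- fx_truth()
  gt <- ground_truth(truth$params$base, truth$baseline,
                     design = study_design(noise_cv = 0,
                                           variables = c("OB", "OC", "B")),
                     resorption_fn = two_wave_rate_fn("overshoot"))
  d <- generate_dataset(gt, seed = 6)
  cf <- suppressWarnings(calibrate_cell_dynamics(d))
  ff <- fit_free_constant_rates(d, cf, seed = 2)
  expect_lt(ff$extras$terminal_deficit, 0)
})

test_that("modulation fitting recovers (delta_B, alpha, beta) on noiseless data", {
  truth <- fx_truth()
  mf <- fx_modulation_fit0()
  tv <- c(delta_B = truth$params$base$delta_B, alpha = truth$params$alpha,
          beta = truth$params$beta)
  expect_true(all(abs(coef(mf) - tv) / tv < 0.05))
  expect_identical(mf$AIC, 2 * 3 + mf$LS)
  # the modulated activities never leave the published range
  expect_lte(mf$extras$max_resorption_rate, 5e-5 * (1 + 1e-6))
  expect_gte(mf$extras$min_resorption_rate, 1e-8 * (1 - 1e-6))
})

test_that("a no-modulation truth is detected as alpha = beta = 0", {
  truth <- fx_truth()
  p0 <- expanded_parameters(truth$params$base, 0, 0,
                            truth$params$pro_driver, truth$params$anti_driver)
  gt0 <- ground_truth(p0, truth$baseline, drivers = truth$drivers)
  d0 <- generate_dataset(gt0, study_design(noise_cv = 0), seed = 2)
  cf0 <- calibrate_cell_dynamics(d0)
  mf0 <- fit_modulation(d0, cf0, truth$params$pro_driver,
                        truth$params$anti_driver, seed = 3)
  expect_lte(coef(mf0)[["alpha"]], 1e-3)
  expect_lte(coef(mf0)[["beta"]], 1e-3)
})

test_that("piecewise fitting recovers a two-wave resorption rate", {
  pf <- fx_piecewise_fit()
  tg <- seq(0, 14, by = 0.05)
  r_true <- eval_rate(two_wave_rate_fn("recovery"), tg)
  r_fit <- eval_rate(pf$extras$rate_fn, tg)
  expect_gte(cor(r_true, r_fit), 0.9)
  # hard bounds hold after the fit (to penalty resolution)
  expect_lte(rate_bounds_violation(pf$extras$rate_fn), 1e-6)
  expect_identical(pf$AIC, 2 * 9 + pf$LS)
})

test_that("piecewise fitting of a constant-rate truth returns a flat rate", {
  truth <- fx_truth()
  gt <- ground_truth(truth$params$base, truth$baseline,
                     design = study_design(times = 0:14, noise_cv = 0,
                                           variables = c("OB", "OC", "B")))
  d <- generate_dataset(gt, seed = 8)
  cf <- calibrate_cell_dynamics(d)
  pf <- fit_piecewise_rate(d, cf, which = "resorption",
                           fixed_rate = truth$params$base$Pi_B,
                           n_segments = 8, seed = 9)
  rate <- eval_rate(pf$extras$rate_fn, seq(0, 14, by = 0.05))
  # recovered rate varies by < 2% of the generating constant
  expect_lt(diff(range(rate)), 0.02 * truth$params$base$delta_B)
})

test_that("the piecewise optimum is independent of the slope initialization", {
  truth <- fx_truth()
  gt <- ground_truth(truth$params$base, truth$baseline,
                     design = study_design(times = 0:14, noise_cv = 0.10,
                                           variables = c("OB", "OC", "B")),
                     resorption_fn = two_wave_rate_fn("recovery"))
  d <- generate_dataset(gt, seed = 5)
  cf <- calibrate_cell_dynamics(d)
  pf <- fit_piecewise_rate(d, cf, which = "resorption",
                           fixed_rate = truth$params$base$Pi_B,
                           n_segments = 8, restarts = 5, seed = 7)
  v <- pf$extras$restart_values
  expect_length(v, 5)
  expect_true(all(v <= 1.1 * min(v)))
})

test_that("bootstrap SEs vanish on noiseless data and track the noise level", {
  d0 <- fx_data0()
  bs0 <- bootstrap_se(function(dd) calibrate_cell_dynamics(dd, restarts = 1),
                      d0, n_boot = 5, seed = 2)
  expect_true(all(abs(bs0$se) / pmax(abs(coef(fx_cell_fit0())), 1e-8) < 1e-3))

  truth <- fx_truth()
  d_lo <- generate_dataset(truth, study_design(noise_cv = 0.05), seed = 3)
  d_hi <- generate_dataset(truth, study_design(noise_cv = 0.10), seed = 3)
  fit2 <- function(dd) calibrate_cell_dynamics(dd, restarts = 2)
  b_lo <- bootstrap_se(fit2, d_lo, n_boot = 15, seed = 4)
  b_hi <- bootstrap_se(fit2, d_hi, n_boot = 15, seed = 4)
  expect_true(all(b_hi$se > b_lo$se))

  # n_boot = 0: unavailable, not zero
  bs_none <- bootstrap_se(fit2, d0, n_boot = 0)
  expect_null(bs_none$se)
})

test_that("noisy recovery stays within three bootstrap standard errors", {
  truth <- fx_truth()
  d <- generate_dataset(truth, study_design(noise_cv = 0.10), seed = 1)
  cf <- calibrate_cell_dynamics(d)
  bs <- bootstrap_se(function(dd) calibrate_cell_dynamics(dd, restarts = 3),
                     d, n_boot = 30, seed = 101)
  z <- abs(coef(cf)[names(table1_cells)] - table1_cells) /
    bs$se[names(table1_cells)]
  expect_true(all(z < 3))
})

test_that("identical seeds give bitwise-identical fits", {
  truth <- fx_truth()
  d <- generate_dataset(truth, study_design(noise_cv = 0.1), seed = 5)
  f1 <- fit_modulation(d, fx_cell_fit0(), truth$params$pro_driver,
                       truth$params$anti_driver, seed = 3)
  f2 <- fit_modulation(d, fx_cell_fit0(), truth$params$pro_driver,
                       truth$params$anti_driver, seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$LS, f2$LS)
})
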