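bl <- homeostatic_baseline(OB_0 = 100, OC_0 = 50, B_0 = 0.2)

test_that("homeostasis closures reproduce their defining identities", {
  expect_equal(closure_source_ob(0.19, bl), 19.0)
  expect_equal(closure_source_ob(0, bl), 0)
  expect_equal(closure_source_ob(0.5, homeostatic_baseline(2, 1, 1)), 1.0)
  # Pi_B = delta_B * OC_0 * B_0 / OB_0
  expect_equal(closure_formation_rate(7.034e-6, bl), 7.034e-7,
               tolerance = 1e-12)
  expect_equal(closure_formation_rate(0, bl), 0)
  expect_equal(closure_formation_rate(1, homeostatic_baseline(50, 50, 1)), 1)
  expect_equal(closure_oc_clearance(6774.8, bl), 6774.8 / 50)
  expect_error(closure_source_ob(-0.1, bl), "must be")
  expect_error(homeostatic_baseline(0, 50, 0.2), "> 0")
})

test_that("closure-built parameter sets satisfy the identities to 1e-12", {
  p <- initial_parameters(delta_OB = 0.19, gamma_OB = 0.873, T_anab = 6.6924,
                          Inhib_OC = 1.2186, T_antiCatab = 2, T_Catab = 2,
                          R_OC = 6774.8, delta_B = 7.034e-6,
                          baseline = bl, close_formation = TRUE)
  expect_equal(p$H_OB, p$delta_OB * bl$OB_0, tolerance = 1e-12)
  expect_equal(p$delta_OC_clear, p$R_OC / bl$OC_0, tolerance = 1e-12)
  expect_equal(p$Pi_B, p$delta_B * bl$OC_0 * bl$B_0 / bl$OB_0,
               tolerance = 1e-12)
})

test_that("initial_rhs matches its algebraic form", {
  p <- initial_parameters(delta_OB = 0.19, gamma_OB = 0, T_anab = 5,
                          Inhib_OC = 0, T_antiCatab = 1, T_Catab = 2,
                          R_OC = 100, delta_B = 1e-5,
                          baseline = bl, close_formation = TRUE)
  # homeostatic state, all injury windows passed: stationary
  d <- initial_rhs(10, c(OB = 100, OC = 50, B = 0.2), p)
  expect_true(all(abs(d) < 1e-10 * c(100, 50, 0.2)))
  # depleted cells: source terms only, bone untouched when OB = OC = 0
  d2 <- initial_rhs(10, c(OB = 0, OC = 0, B = 0.2), p)
  expect_equal(unname(d2), c(p$H_OB, p$R_OC, 0))
  # anabolic window arithmetic with the literature proliferation rate
  p3 <- initial_parameters(delta_OB = 0.19, gamma_OB = 0.873, T_anab = 6.6924,
                           H_OB = 19)
  d3 <- initial_rhs(1, c(OB = 100, OC = 0, B = 0), p3)
  expect_equal(d3[["OB"]], 19 + 87.3 - 19)
})

test_that("expanded_rhs reduces exactly to initial_rhs and scales resorption", {
  p <- initial_parameters(delta_OB = 0.19, gamma_OB = 0.5, T_anab = 5,
                          Inhib_OC = 1, T_antiCatab = 2, T_Catab = 2,
                          R_OC = 100, delta_B = 1e-5,
                          baseline = bl, close_formation = TRUE)
  zero <- driver_curve(list(), "pro_mono")
  pe <- expanded_parameters(p, alpha = 3, beta = 4, pro_driver = zero,
                            anti_driver = zero)
  st <- c(OB = 80, OC = 60, B = 0.15)
  for (t in c(0.5, 1, 3, 10)) {
    expect_identical(expanded_rhs(t, st, pe), initial_rhs(t, st, p))
  }
  # a unit pro-driver with alpha = 1 exactly doubles the resorption term
  one <- driver_curve(list(list(amplitude = 1, onset = 0, rise_time = 1,
                                decay_time = 1e8)), "pro_mono")
  t_pk <- 1  # kernel peak: P(t) = 1
  pe2 <- expanded_parameters(p, alpha = 1, beta = 0, pro_driver = one,
                             anti_driver = zero)
  d0 <- initial_rhs(t_pk, st, p)
  d1 <- expanded_rhs(t_pk, st, pe2)
  resorb <- -p$delta_B * st[["OC"]] * st[["B"]]
  expect_equal(d1[["B"]] - d0[["B"]], resorb, tolerance = 1e-9)
  # hand-computed cancellation: stimulated resorption == stimulated formation
  # alpha=0.5, P=2 doubles resorption; beta=0.25, A=4 doubles formation
  pm <- initial_parameters(delta_B = 1e-6, Pi_B = 1e-6)
  st2 <- c(OB = 10, OC = 10, B = 1)
  base <- initial_rhs(0.5, st2, pm)
  expect_equal(base[["B"]], 0)  # -1e-5 + 1e-5
  # manual modulated evaluation of the stated functional form
  dB_mod <- -1e-6 * (1 + 0.5 * 2) * 10 * 1 + 1e-6 * (1 + 0.25 * 4) * 10
  expect_equal(dB_mod, 0)
})

test_that("piecewise evaluation is exact at nodes, linear between, clamped outside", {
  fn <- piecewise_rate(c(0, 2, 5), rate_0 = 1e-6, slopes = c(5e-7, -2e-7))
  nodes <- rate_nodes(fn)
  expect_equal(eval_rate(fn, c(0, 2, 5)), nodes)
  # midway through a segment: mean of segment endpoints
  expect_equal(eval_rate(fn, 1), mean(nodes[1:2]))
  expect_equal(eval_rate(fn, 3.5), mean(nodes[2:3]))
  # constant extrapolation
  expect_equal(eval_rate(fn, c(-1, 100)), nodes[c(1, 3)])
  # telescoping: symmetric slopes return to rate_0
  fn2 <- piecewise_rate(c(0, 1, 2), 1e-6, c(3e-7, -3e-7))
  expect_equal(eval_rate(fn2, 2), 1e-6)
  # linear evaluation example: rate_0 + slope * t
  fn3 <- piecewise_rate(c(0, 10), 1e-6, 1e-6)
  expect_equal(eval_rate(fn3, 2), 3e-6)
  expect_error(piecewise_rate(numeric(0), 1, numeric(0)), "empty")
  expect_error(piecewise_rate(c(0, 0), 1, 0), "strictly increasing")
})

test_that("piecewise evaluation agrees with a brute-force segment scan", {
  set.seed(42)
  for (rep in 1:5) {
    nb <- sample(2:9, 1)
    tb <- sort(runif(nb, 0, 14)); tb <- tb + seq_along(tb) * 1e-3
    r0 <- runif(1, 1e-7, 1e-5)
    sl <- rnorm(nb - 1, 0, 1e-6)
    fn <- piecewise_rate(tb, r0, sl)
    nodes <- rate_nodes(fn)
    ts <- runif(200, tb[1] - 1, tb[nb] + 1)
    oracle <- vapply(ts, function(t) {
      if (t <= tb[1]) return(nodes[1])
      if (t >= tb[nb]) return(nodes[nb])
      for (k in seq_len(nb - 1)) {
        if (t >= tb[k] && t <= tb[k + 1]) {
          return(nodes[k] + sl[k] * (t - tb[k]))
        }
      }
    }, numeric(1))
    expect_equal(eval_rate(fn, ts), oracle, tolerance = 1e-12)
  }
})

test_that("simulate_model matches closed-form exponential decay", {
  p <- initial_parameters(delta_OB = 0.19)  # everything else zero
  tr <- simulate_model(p, bl, times = c(0, 7, 14))
  expect_equal(tr$OB, 100 * exp(-0.19 * c(0, 7, 14)), tolerance = 1e-6)
  expect_equal(tr$B, rep(0.2, 3), tolerance = 1e-8)
})

test_that("the closed homeostatic system is a fixed point of the solver", {
  p <- initial_parameters(delta_OB = 0.19, R_OC = 6774.8, delta_B = 7.034e-6,
                          T_Catab = 0, baseline = bl, close_formation = TRUE)
  tr <- simulate_model(p, bl, times = seq(0, 14, by = 0.5))
  expect_lt(max(abs(tr$OB / bl$OB_0 - 1)), 1e-6)
  expect_lt(max(abs(tr$OC / bl$OC_0 - 1)), 1e-6)
  expect_lt(max(abs(tr$B / bl$B_0 - 1)), 1e-6)
  # and the RHS itself vanishes to 1e-10 in relative units
  d <- initial_rhs(5, c(OB = bl$OB_0, OC = bl$OC_0, B = bl$B_0), p)
  expect_true(all(abs(d) / c(bl$OB_0, bl$OC_0, bl$B_0) < 1e-10))
})

test_that("exact cell solution and the adaptive RK solver agree", {
  truth <- fx_truth()
  tg <- seq(0, 14, by = 0.25)
  tr <- simulate_model(truth$params$base, truth$baseline, times = tg)
  ct <- cell_trajectories(truth$params$base, truth$baseline, tg)
  expect_equal(tr$OB, ct$OB, tolerance = 1e-6)
  expect_equal(tr$OC, ct$OC, tolerance = 1e-6)
  # unsorted query times are returned in caller order
  shuffled <- c(3, 0, 7.2, 1.1)
  cs <- cell_trajectories(truth$params$base, truth$baseline, shuffled)
  expect_equal(cs$time_day, shuffled)
  expect_equal(cs$OB[2], truth$baseline$OB_0)
})

test_that("simulated states stay non-negative and finite", {
  set.seed(7)
  for (rep in 1:4) {
    p <- initial_parameters(delta_OB = runif(1, 0.1, 1),
                            gamma_OB = runif(1, 0, 1),
                            T_anab = runif(1, 1, 8),
                            Inhib_OC = runif(1, 0, 2),
                            T_antiCatab = runif(1, 0, 4),
                            T_Catab = runif(1, 0, 4),
                            R_OC = runif(1, 0, 500),
                            delta_B = 10^runif(1, -8, log10(5e-5)),
                            baseline = bl, close_formation = TRUE)
    tr <- simulate_model(p, bl, times = seq(0, 14, by = 0.5))
    expect_true(all(is.finite(as.matrix(tr[, c("OB", "OC", "B")]))))
    expect_true(all(tr$B >= 0))
    expect_true(all(tr$OB >= 0))
    expect_true(all(tr$OC >= 0))
  }
})

test_that("bone balance: net formation minus resorption integrates to B(T) - B(0)", {
  truth <- fx_truth()
  p <- truth$params$base
  tg <- seq(0, 14, by = 0.005)
  tr <- simulate_model(p, truth$baseline, times = tg)
  flux <- p$Pi_B * tr$OB - p$delta_B * tr$OC * tr$B
  net <- pracma::trapz(tg, flux)
  expect_equal(net, tr$B[length(tg)] - tr$B[1], tolerance = 1e-5)
})

test_that("myeloid-modulated system relaxes back to homeostasis", {
  truth <- fx_truth()
  p <- truth$params$base
  p$delta_B <- 7.034e-6
  p <- apply_closures(p, truth$baseline, formation = TRUE)
  pe <- expanded_parameters(p, alpha = 1, beta = 1,
                            pro_driver = truth$params$pro_driver,
                            anti_driver = truth$params$anti_driver)
  tr <- simulate_model(pe, truth$baseline, times = c(0, 50, 200))
  last <- nrow(tr)
  expect_lt(abs(tr$OB[last] / truth$baseline$OB_0 - 1), 1e-3)
  expect_lt(abs(tr$OC[last] / truth$baseline$OC_0 - 1), 1e-3)
  expect_lt(abs(tr$B[last] / truth$baseline$B_0 - 1), 1e-3)
})

test_that("piecewise_rhs with a flat single segment equals initial_rhs", {
  p <- initial_parameters(delta_OB = 0.19, R_OC = 100, delta_B = 3e-6,
                          baseline = bl, close_formation = TRUE)
  fn <- piecewise_rate(c(0, 14), rate_0 = p$delta_B, slopes = 0)
  st <- c(OB = 120, OC = 40, B = 0.18)
  expect_equal(piecewise_rhs(3, st, p, resorption_fn = fn),
               initial_rhs(3, st, p))
})
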