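test_that("effective rates follow the coarse-grained forms", {
  # w = 1 leaves the mRNA degradation rate at its naked value, any x
  for (x in c(0.01, 1, 30)) {
    er <- effective_rates(kinetic_params(w = 1, x = x))
    expect_equal(er$beta_m, 0.4)
  }
  # x = 0: no translation, interaction rate k0/(1+z)
  er0 <- effective_rates(kinetic_params(x = 0, z = 0.5))
  expect_equal(er0$gamma, 0)
  expect_equal(er0$k, 0.04 / 1.5)
  # frozen hand evaluation of the k formula
  er <- effective_rates(kinetic_params(k0 = 0.04, x = 1, y = 100, z = 0.001))
  expect_equal(er$k, 0.04 * 101 / (2 * 1.101), tolerance = 1e-12)
  expect_equal(er$k, 1.834696, tolerance = 1e-6)
  # lambda ties the two parameterizations together: fig2 prints lambda0 = 1
  er2 <- effective_rates(exact_rate_params())
  expect_equal(er2$lam, 1)
  # gamma strictly increasing in x with supremum gamma0
  g <- vapply(10^seq(-3, 5, 0.5), function(x)
    effective_rates(kinetic_params(x = x, gamma0 = 2))$gamma, 0)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < 2))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(kinetic_params(x = -1), "x")
  expect_error(kinetic_params(beta_m0 = 0), "beta_m0")
  expect_error(kinetic_params(alpha_s = -0.1), "alpha_s")
  expect_error(kinetic_params(w = -2), "w")
  expect_error(preset_params("fig2", nope = 1), "unknown")
})

test_that("closed-form steady state matches hand-derived fixtures", {
  # no sRNA: m = alpha_m/beta_m, s = 0, p = gamma*alpha_m/(beta_m*beta_p)
  p <- exact_rate_params(alpha_s = 0)
  ss <- steady_state(p)
  expect_equal(ss$m, 1 / 0.4)
  expect_equal(ss$s, 0)
  expect_equal(ss$p, 0.5 * 2.5 * 60)
  # frozen quadratic-root fixture (effective beta_m=0.4, beta_s=0.1, k=0.04,
  # lambda=1, alpha_m=1, alpha_s=2); residuals checked below
  ss2 <- steady_state(exact_rate_params(alpha_s = 2))
  expect_equal(ss2$m, 1.0355339, tolerance = 1e-7)
  expect_equal(ss2$s, 14.1421356, tolerance = 1e-7)
  expect_lt(ss2$residual_norm, 1e-10)
})

test_that("numeric solver is an independent oracle for the closed form", {
  for (p in random_params(100, seed = 7)) {
    cf <- steady_state(p)
    nm <- steady_state(p, method = "numeric", tol = 1e-12)
    expect_lt(abs(nm$m - cf$m) / cf$m, 1e-8)
    expect_lt(nm$residual_norm, 1e-8 * p$alpha_m)
  }
  # degenerate crossover point with lambda = alpha_m
  p <- kinetic_params(alpha_m = 1, alpha_s = 1, k0 = 0.04, x = 1, y = 1,
                      z = 0)
  expect_lt(steady_state(p, "numeric")$residual_norm, 1e-9)
})

test_that("mass balance holds at every steady state", {
  for (p in random_params(100, seed = 13)) {
    er <- effective_rates(p)
    ss <- steady_state(p)
    expect_equal(er$beta_m * ss$m + er$k * ss$s * ss$m, p$alpha_m,
                 tolerance = 1e-10)
    expect_equal(p$beta_s * ss$s + er$k * ss$s * ss$m, p$alpha_s,
                 tolerance = 1e-10)
  }
})

test_that("threshold-linear limit is reached in its asymptotic regime", {
  # sharp threshold requires |alpha_m - alpha_s| >> sqrt(lambda*alpha_m),
  # the width of the crossover transition; at 10 widths the error is < 5%
  set.seed(31)
  for (i in 1:50) {
    alpha_m <- 10^runif(1, -0.5, 0.5)
    lam_target <- 10^runif(1, -4, -2) * alpha_m
    p0 <- kinetic_params(alpha_m = alpha_m, alpha_s = 0,
                         x = 10^runif(1, -1, 1))
    er0 <- effective_rates(p0)
    p0 <- update_params(p0, k0 = p0$k0 * er0$lam / lam_target)
    lam <- effective_rates(p0)$lam
    d <- 10 * sqrt(lam * alpha_m) * 10^runif(1, 0, 0.5)
    for (alpha_s in c(max(alpha_m - d, 0), alpha_m + d)) {
      p <- update_params(p0, alpha_s = alpha_s)
      m <- steady_state(p)$m
      pred <- max(alpha_m - alpha_s, 0) / effective_rates(p)$beta_m
      scale <- alpha_m / effective_rates(p)$beta_m
      expect_lt(abs(m - pred), 0.05 * max(pred, scale))
    }
  }
})

test_that("efficacy is a pure mRNA ratio with the documented limits", {
  p <- exact_rate_params(alpha_s = 2)
  expect_equal(efficacy(p), 2.4142136, tolerance = 1e-7)
  expect_equal(efficacy(p, as_ratio = TRUE), 1 / efficacy(p))
  # k0 -> 0: no interaction, no repression
  expect_equal(efficacy(update_params(p, k0 = 1e-12)), 1, tolerance = 1e-5)
  # gamma0 and beta_p cancel
  expect_equal(efficacy(update_params(p, gamma0 = 7, beta_p = 0.4)),
               efficacy(p))
  # >= 1 over random parameters
  for (q in random_params(50, seed = 3)) {
    qa <- if (q$alpha_s == 0) update_params(q, alpha_s = 0.5) else q
    expect_gte(efficacy(qa), 1)
  }
  expect_error(efficacy(update_params(p, x = 0)), "undefined")
  expect_error(efficacy(update_params(p, alpha_s = 0)), "alpha_s")
})

test_that("response curves show the competition/recruitment dichotomy", {
  g <- 10^seq(-2, 2, length.out = 40)
  for (r in c(1, 2)) {
    eff_c <- response_curve(preset_params("fig2", y = 0.01, alpha_s = r),
                            "x", g)$efficacy
    expect_true(all(diff(eff_c) < 0))
    eff_r <- response_curve(preset_params("fig2", y = 100, alpha_s = r),
                            "x", g)$efficacy
    i <- which.max(eff_r)
    expect_gt(i, 1); expect_lt(i, length(g))
    expect_equal(sum(diff(sign(diff(eff_r))) != 0), 1)  # unimodal
  }
  # alpha_s = 0 everywhere: efficacy identically 1
  rc0 <- response_curve(preset_params("fig2", alpha_s = 0), "x",
                        c(0.1, 1, 10))
  expect_equal(rc0$efficacy, rep(1, 3))
  expect_error(response_curve(preset_params("fig2"), "x", c(2, 1, 3)),
               "increasing")
})

test_that("response curve alternative axes are consistent reparameterizations", {
  p <- preset_params("fig2", y = 100, alpha_s = 2)
  act <- c(0.2, 0.5, 0.9)           # gamma/gamma0 = x/(1+x)
  rc <- response_curve(p, "translational_activity", act)
  expect_equal(rc$x, act / (1 - act))
  expr <- c(20, 60, 120)
  rc2 <- response_curve(p, "unregulated_expression", expr)
  expect_equal(rc2$expression_off, expr, tolerance = 1e-10)
  rc3 <- response_curve(p, "alpha_s", c(0.5, 1, 2))
  expect_equal(rc3$efficacy[3], efficacy(p), tolerance = 1e-12)
})

test_that("find_max_efficacy separates boundary from interior optima", {
  comp <- find_max_efficacy(preset_params("fig2", y = 0.01, alpha_s = 2))
  expect_equal(comp$boundary, "lower")
  rec <- find_max_efficacy(preset_params("fig2", y = 100, alpha_s = 2))
  expect_equal(rec$boundary, "none")
  # brute-force validation on a dense grid
  dense <- 10^seq(-2, 2, length.out = 4000)
  eff <- response_curve(preset_params("fig2", y = 100, alpha_s = 2), "x",
                        dense)$efficacy
  expect_equal(rec$x_opt, dense[which.max(eff)], tolerance = 1e-3)
  expect_gte(rec$efficacy_opt, max(eff) - 1e-8)
  # gamma0 cancels: doubling it leaves the optimum where it was
  rec2 <- find_max_efficacy(preset_params("fig2", y = 100, alpha_s = 2,
                                          gamma0 = 2))
  expect_equal(rec2$x_opt, rec$x_opt, tolerance = 1e-6)
})

test_that("unregulated expression saturates and inverts", {
  p <- preset_params("fig5")
  expect_equal(unregulated_expression(update_params(p, x = 0)), 0)
  expect_equal(unregulated_expression(update_params(p, x = 1e9)),
               142.8571, tolerance = 1e-4)
  # round trip over nearly the whole dynamic range, w = 1
  p_max <- 1 / (0.42 / 60)
  for (r in seq(0.01, 0.99, by = 0.07)) {
    x <- invert_x_from_expression(r * p_max, p)
    expect_equal(unregulated_expression(update_params(p, x = x)), r * p_max,
                 tolerance = 1e-10)
  }
  # and with w != 1 (closed form handles the shifted saturation)
  pw <- update_params(p, w = 2.5)
  x <- invert_x_from_expression(30, pw)
  expect_equal(unregulated_expression(update_params(pw, x = x)), 30,
               tolerance = 1e-10)
  expect_error(invert_x_from_expression(p_max, p), "saturation")
})

test_that("regime classification matches the printed regimes", {
  expect_equal(classify_regime(preset_params("fig2", alpha_s = 1))$label,
               "crossover")
  expect_equal(classify_regime(preset_params("fig2", alpha_s = 2))$label,
               "silenced")
  expect_equal(classify_regime(preset_params("fig2", alpha_s = 0))$label,
               "expressed")
  expect_equal(classify_regime(preset_params("fig2", alpha_s = 0.3),
                               t_lo = 0.25)$label, "crossover")
})

test_that("parameter config files round-trip and presets ship", {
  p <- preset_params("fig2", y = 100, alpha_s = 2)
  f <- tempfile(fileext = ".conf")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  for (nm in c("fig2", "fig5")) {
    shipped <- read_params(system.file("extdata",
                                       paste0("params_", nm, ".conf"),
                                       package = "srnakin"))
    expect_equal(unclass(shipped), unclass(preset_params(nm)),
                 tolerance = 1e-12)
  }
  writeLines("alpha_m = 1\nbogus = 2", f)
  expect_error(read_params(f), "unknown")
})
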