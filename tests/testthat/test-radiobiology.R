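test_that("parameter constructors derive beta and lambda correctly", {
  p <- radiobio_params(alpha = 0.3)
  expect_equal(p$beta, 0.3 / 3.6)
  expect_equal(p$lambda_h, log(2) / 64.1)
  # protraction factor with the defaults
  expect_equal(p$lambda_h / (p$lambda_h + p$mu_h), 0.0212, tolerance = 0.01)
  expect_error(radiobio_params(alpha = -1), "positive")
  expect_error(logistic_params(d50_Gy = 0), "positive")
})

test_that("local survival follows the protracted linear-quadratic form", {
  p <- radiobio_params(alpha = 0.3)
  expect_equal(sf_local(0, p), 1)
  # closed form at D = 20 Gy
  lam <- log(2) / 64.1
  expected <- exp(-0.3 * 20 - lam * (0.3 / 3.6) * 400 / (lam + 0.5))
  expect_equal(sf_local(20, p), expected, tolerance = 1e-12)
  # fast repair kills the quadratic term
  p_fast <- radiobio_params(alpha = 0.3, mu_h = 1e9)
  expect_equal(sf_local(20, p_fast), exp(-0.3 * 20), tolerance = 1e-6)
  expect_error(sf_local(-1, p), "non-negative")
})

test_that("clonogen counts match the analytic shell integrals", {
  mc <- density_model("constant", 1e6, z0_mm = 0.5, k_mm = 3)
  ml <- density_model("linear", 1e6, z0_mm = 0.5, k_mm = 3)
  # pi * (3 cm)^2 * 0.3 cm * 1e6 cells/cm^3
  expect_equal(cell_count(mc, 30), pi * 9 * 0.3 * 1e6, tolerance = 1e-12)
  expect_equal(cell_count(ml, 30), cell_count(mc, 30) / 2)
  expect_equal(density_at(ml, 0.5), 1e6)
  expect_equal(density_at(ml, 3.5), 0)
  expect_equal(density_at(ml, 5), 0) # outside the shell
  expect_error(density_model("constant", rho0 = 0), "positive")
})

test_that("surviving cells agree with a fine-grid Simpson oracle", {
  fit <- ref_profile_fit(1)
  p <- radiobio_params(0.3)
  for (kind in c("constant", "linear")) {
    m <- density_model(kind, 1e6, z0_mm = 0.5, k_mm = 3)
    ns <- surviving_cells(fit, 35, 30, m, p)
    oracle <- bat90:::.simpson(function(z) {
      pi * 900 / 1000 * density_at(m, z) *
        sf_local(dose_at(pmax(z, 0.5), fit, 35, 30), p)
    }, 0.5, 3.5, 10000L)
    expect_equal(ns, oracle, tolerance = 1e-6)
  }
  # zero activity: everything survives
  m <- density_model("constant", 1e6, z0_mm = 0.5, k_mm = 3)
  expect_equal(surviving_cells(fit, 0, 30, m, p), cell_count(m, 30))
  # strictly decreasing in administered activity
  ns_a <- vapply(c(10, 20, 35, 50), function(a)
    surviving_cells(fit, a, 30, m, p), numeric(1))
  expect_true(all(diff(ns_a) < 0))
  expect_error(surviving_cells(fit, 35, 30,
                               density_model("constant", 1e6, z0_mm = 1,
                                             k_mm = 3), p),
               "must match")
})

test_that("surviving fraction is a clean ratio independent of rho0", {
  fit <- ref_profile_fit(1)
  p <- radiobio_params(0.3)
  sfs <- vapply(c(1e4, 1e5, 1e6, 1e7), function(r0) {
    m <- density_model("constant", r0, z0_mm = 0.5, k_mm = 3)
    surviving_cells(fit, 35, 30, m, p) / cell_count(m, 30)
  }, numeric(1))
  expect_lt(max(abs(sfs - sfs[1]) / sfs[1]), 1e-12)
  expect_equal(surviving_fraction(5, 5), 1)
  expect_error(surviving_fraction(1, 0), "positive")
  expect_error(surviving_fraction(-1, 5), "\\[0, n0\\]")
  # constant density + spatially constant dose collapses to sf_local
  expect_equal(surviving_fraction(cell_count(density_model("constant", 1e6,
                                                           0.5, 3), 30) *
                                    sf_local(20, p),
                                  cell_count(density_model("constant", 1e6,
                                                           0.5, 3), 30)),
               sf_local(20, p))
})

test_that("Poisson TCP is exp(-Ns)", {
  expect_equal(tcp_poisson(0), 1)
  expect_equal(tcp_poisson(log(2)), 0.5)
  expect_equal(tcp_poisson(10), exp(-10), tolerance = 1e-12)
  expect_error(tcp_poisson(-1), "non-negative")
})

test_that("EUD inverts the 2 Gy-per-fraction survival relation", {
  p <- radiobio_params(0.3)
  expect_equal(eud_2gy_from_sf(1, p), 0)
  sf <- 1e-4
  eud <- eud_2gy_from_sf(sf, p)
  expect_equal(exp(-p$alpha * eud - p$beta * 2 * eud), sf, tolerance = 1e-12)
  expect_error(eud_2gy_from_sf(0, p), "\\(0, 1\\]")
  expect_error(eud_2gy_from_sf(1.5, p), "\\(0, 1\\]")
})

test_that("logistic TCP has the right anchor points and monotonicity", {
  lp <- logistic_params()
  expect_equal(tcp_logistic(22.39, lp), 0.5)
  euds <- seq(5, 60, by = 5)
  expect_true(all(diff(tcp_logistic(euds, lp)) > 0))
  expect_error(tcp_logistic(0, lp), "positive")
})

test_that("the worked plan reproduces the published EUD and TCP pair", {
  fit <- ref_profile_fit(1)
  p <- radiobio_params(0.3)
  lp <- logistic_params()
  rc <- evaluate_tcp(fit, 35, 30,
                     density_model("constant", 1e6, 0.5, 3), p, lp)
  rl <- evaluate_tcp(fit, 35, 30,
                     density_model("linear", 1e6, 0.5, 3), p, lp)
  expect_equal(rc$eud_2gy, 19.8, tolerance = 0.3 / 19.8)
  expect_equal(rl$eud_2gy, 24.5, tolerance = 0.3 / 24.5)
  expect_equal(rc$tcp_logistic, 0.39, tolerance = 0.02 / 0.39)
  expect_equal(rl$tcp_logistic, 0.59, tolerance = 0.02 / 0.59)
  expect_equal(rc$ns, rc$sf * rc$n0)
  # linear density concentrates cells where the dose is highest:
  # lower SF, higher TCP
  expect_lt(rl$sf, rc$sf)
  expect_gt(rl$tcp_logistic, rc$tcp_logistic)
})

test_that("Poisson TCP is monotone in alpha, rho0, bed radius and thickness", {
  fit <- ref_profile_fit(1)
  m4 <- density_model("constant", 1e4, 0.5, 3)
  sw <- tcp_alpha_sweep(fit, 35, 30, m4, alphas = seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(sw$tcp_poisson) >= 0))
  expect_error(tcp_alpha_sweep(fit, 35, 30, m4, alphas = c(0.01)),
               "0.02")
  # denser residual disease is harder to control
  tcp_rho <- vapply(c(1e4, 1e5, 1e6, 1e7), function(r0) {
    m <- density_model("constant", r0, 0.5, 3)
    evaluate_tcp(fit, 35, 30, m, radiobio_params(0.45))$tcp_poisson
  }, numeric(1))
  expect_true(all(diff(tcp_rho) <= 0))
  expect_lt(tcp_rho[4], tcp_rho[1])
  # larger beds at fixed activity are harder to control
  tcp_R <- vapply(c(20, 30, 40), function(R) {
    m <- density_model("constant", 1e5, 0.5, 3)
    evaluate_tcp(fit, 35, R, m, radiobio_params(0.3))$tcp_poisson
  }, numeric(1))
  expect_true(all(diff(tcp_R) <= 0))
  expect_lt(tcp_R[3], tcp_R[1])
  # thicker device layers attenuate the tissue dose: TCP falls with t
  tcp_t <- vapply(c(0, 1, 3), function(t) {
    f <- ref_profile_fit(t)
    m <- density_model("constant", 1e5, z0_mm = f$z0_mm, k_mm = 3)
    evaluate_tcp(f, 35, 30, m, radiobio_params(0.5))$tcp_poisson
  }, numeric(1))
  expect_true(all(diff(tcp_t) <= 0))
  expect_lt(tcp_t[3], tcp_t[1])
  # linear-density TCP above constant-density TCP at equal (alpha, rho0)
  ml <- density_model("linear", 1e5, 0.5, 3)
  mc <- density_model("constant", 1e5, 0.5, 3)
  swl <- tcp_alpha_sweep(fit, 35, 30, ml, alphas = c(0.3, 0.5, 0.7))
  swc <- tcp_alpha_sweep(fit, 35, 30, mc, alphas = c(0.3, 0.5, 0.7))
  expect_true(all(swl$tcp_poisson >= swc$tcp_poisson))
})
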