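test_that("growth-law right-hand sides match hand arithmetic", {
  gl <- growth_params("gen_logistic", lam = 0.1, omega_bar = 4)
  expect_equal(growth_rhs(gl, 1), 0)                       # carrying capacity
  expect_equal(growth_rhs(gl, 0.5), 0.1 * 0.5 * (1 - 0.0625))
  go <- growth_params("gompertz", g = 0.2)
  expect_equal(growth_rhs(go, 1), 0)                       # ln 1 = 0
  expect_equal(growth_rhs(go, 0.5), -0.2 * 0.5 * log(0.5))
  expect_error(growth_rhs(go, 0), "ln 0")
  rad <- growth_params("radial", lam = 0.1, d = 2)
  expect_equal(growth_rhs(rad, 100), 0.1 * 2 * 10)
  fr <- growth_params("fractal", lam = 0.1, d = 2, D = 1.5, a = 2)
  expect_equal(growth_rhs(fr, 16), 0.1 * 2 * 16^0.75)
  es <- growth_params("exponential_saturating", lam = 0.1)
  expect_equal(growth_rhs(es, 0.5), 0.05)
  expect_equal(growth_rhs(es, 1), 0)
})

test_that("closed forms agree with adaptive ODE integration", {
  tt <- seq(0, 80, length.out = 100)
  cases <- list(
    growth_params("gompertz", g = 0.1, delta = 0.01, u0 = 0.1),
    growth_params("gen_logistic", lam = 0.1, omega_bar = 4, delta = 0.02, u0 = 0.05),
    growth_params("gen_logistic", lam = 0.05, omega_bar = 0.5, u0 = 0.2)
  )
  for (p in cases) {
    num <- solve_growth(p, tt)$value
    expect_lt(max(abs(num - closed_form(p, tt))), 1e-6)
  }
  # frozen oracle values (verified by ODE integration at rtol 1e-10)
  expect_equal(closed_form(growth_params("gompertz", g = 0.1, u0 = 0.1), 10),
               0.1^exp(-1), tolerance = 1e-12)
  expect_equal(closed_form(growth_params("gen_logistic", lam = 0.1, omega_bar = 4,
                                         u0 = 0.1), 10),
               (1 + (0.1^-4 - 1) * exp(-4)) ^ (-1 / 4), tolerance = 1e-12)
  # t = 0 returns u0 for every law with a closed form
  for (p in cases) expect_equal(closed_form(p, 0), p$u0)
})

test_that("radial growth follows the square-root-linear closed form", {
  p <- growth_params("radial", lam = 0.1, d = 2, u0 = 1)
  expect_equal(closed_form(p, 100), (1 + 10)^2)
  num <- solve_growth(p, seq(0, 100, 1))
  expect_lt(max(abs(num$value - closed_form(p, num$time))), 1e-4)
})

test_that("lam = delta generalized logistic uses the algebraic limiting branch", {
  p <- growth_params("gen_logistic", lam = 0.1, omega_bar = 2, delta = 0.1, u0 = 0.01)
  # u_dot(0) = -lam * u0^(omega+1): nearly flat start
  expect_equal(growth_rhs(p, 0.01), -0.1 * 0.01^3)
  num <- solve_growth(p, seq(0, 50, 1))
  expect_lt(max(abs(num$value - closed_form(p, num$time))), 1e-7)
})

test_that("steady states are fixed points of the dynamics", {
  cases <- list(
    growth_params("gen_logistic", lam = 0.1, omega_bar = 2, delta = 0.05),
    growth_params("gompertz", g = 0.1, delta = 0.001),
    growth_params("gen_logistic", lam = 0.1, omega_bar = 4, delta = 0)
  )
  for (p in cases) {
    us <- steady_state(p)
    expect_lte(abs(growth_rhs(p, us)), 1e-10)
  }
  expect_equal(steady_state(growth_params("gen_logistic", lam = 0.1,
                                          omega_bar = 2, delta = 0.05)),
               sqrt(0.5))
  expect_equal(steady_state(growth_params("gompertz", g = 0.1, delta = 0.001)),
               exp(-0.01))
  expect_equal(steady_state(growth_params("gen_logistic", lam = 0.05,
                                          omega_bar = 2, delta = 0.1)), 0)
  expect_equal(steady_state(growth_params("gompertz", g = 0.3)), 1)
})

test_that("density trajectories stay in [0,1] and are monotone without death", {
  tt <- seq(0, 200, 2)
  for (p in list(growth_params("gen_logistic", lam = 0.2, omega_bar = 8, u0 = 0.01),
                 growth_params("gompertz", g = 0.05, u0 = 0.02),
                 growth_params("exponential_saturating", lam = 0.1, u0 = 0.01))) {
    u <- solve_growth(p, tt)$value
    expect_true(all(u >= 0 & u <= 1 + 1e-9))
    # monotone up to integrator tolerance near saturation
    expect_true(all(diff(u) >= -1e-9))
  }
})

test_that("generalized logistic converges to Gompertz as omega_bar shrinks at fixed g", {
  g <- 0.1; u0 <- 0.05; tt <- seq(0, 100, 1)
  ug <- closed_form(growth_params("gompertz", g = g, u0 = u0), tt)
  sups <- vapply(c(1e-1, 1e-2, 1e-3), function(ob) {
    ul <- closed_form(growth_params("gen_logistic", lam = g / ob,
                                    omega_bar = ob, u0 = u0), tt)
    max(abs(ul - ug))
  }, 0)
  expect_true(all(diff(sups) < 0))
  expect_lt(sups[3], 1e-3)
})

test_that("fractal law at D = d - 1 reduces to the radial law", {
  rad <- growth_params("radial", lam = 0.1, d = 2, u0 = 4)
  # radial rhs is lam * d * n^((d-1)/d); fractal with D = d - 1, a = d matches
  fr <- growth_params("fractal", lam = 0.1, d = 2, D = 1 + 1e-12, a = 2, u0 = 4)
  for (n in c(4, 100, 2500)) {
    expect_equal(growth_rhs(fr, n), growth_rhs(rad, n), tolerance = 1e-6)
  }
})

test_that("Gompertz validity margin flags sparse populations", {
  m <- gompertz_condition_margin(0.5, 0, 1)
  expect_true(m$satisfied)     # u = 1 always satisfies the condition
  m <- gompertz_condition_margin(0.01, 0, exp(-1), strictness_factor = 10)
  expect_equal(m$margin, 2 * 0.01 / 0.01^2 - 10)  # 200 - 10 = 190
  expect_true(m$satisfied)
  m <- gompertz_condition_margin(8, 0, 0.01, strictness_factor = 10)
  expect_equal(m$margin, 2 * 8 / 64 - 10 * abs(log(0.01)))
  expect_false(m$satisfied)
  expect_error(gompertz_condition_margin(1, 0, 0), "positive")
})

test_that("parameter validation rejects inconsistent laws", {
  expect_error(growth_params("gen_logistic", lam = 0.1), "omega_bar")
  expect_error(growth_params("gompertz"), "'g'")
  expect_error(growth_params("fractal", lam = 0.1, d = 2, D = 0.5, a = 1),
               "d - 1 < D")
  expect_error(growth_params("gen_logistic", lam = 0.1, omega_bar = 2, u0 = 1.5),
               "u0")
  # g composed from lam and omega_bar
  p <- growth_params("gompertz", lam = 0.05, omega_bar = 2)
  expect_equal(p$g, 0.1)
})
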