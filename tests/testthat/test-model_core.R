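test_that("Hill activation and repression behave as regulatory gates", {
  # half-saturation, zero input, and the 3K/n=2 point
  expect_equal(hill_activation(1.7, 1.7, 3), 0.5)
  expect_equal(hill_activation(0, 2, 4), 0)
  expect_equal(hill_activation(3, 1, 2), 0.9)
  expect_equal(hill_repression(0, 1.3, 5), 1)
  expect_equal(hill_repression(0.8, 0.8, 2), 0.5)

  # complementarity and monotonicity at random points
  set.seed(7)
  x <- runif(20, 0, 5)
  K <- runif(20, 0.2, 3)
  n <- sample(1:6, 20, replace = TRUE)
  for (i in seq_along(x)) {
    expect_equal(hill_activation(x[i], K[i], n[i]) +
                 hill_repression(x[i], K[i], n[i]), 1, tolerance = 1e-12)
  }
  grid <- seq(0, 10, by = 0.1)
  expect_true(all(diff(hill_activation(grid, 2, 4)) >= 0))
  expect_true(all(diff(hill_repression(grid, 2, 4)) <= 0))

  expect_error(hill_activation(1, -1, 2), "K must be > 0")
  expect_error(hill_activation(1, 1, 0.5), "n must be >= 1")
  expect_error(hill_activation(-1, 1, 2), ">= 0")
})

test_that("secretion gates are saturating and monotone in their input", {
  p <- beta_params()
  expect_equal(f_glu(0, p), 0)
  expect_equal(f_glu(p$K_ig, p), 0.5)
  expect_equal(f_exo(0, p), 0)
  expect_equal(f_exo(p$K_ie, p), 0.5)
  expect_error(f_glu(-0.1, p), ">= 0")
  expect_error(f_exo(-2, p), ">= 0")

  # monotonicity against a finite-difference oracle
  g <- seq(0, 4 * p$K_ig, length.out = 200)
  fd <- diff(f_glu(g, p)) / diff(g)
  expect_true(all(fd >= 0))
  expect_true(all(f_glu(g, p) <= 1))
})

test_that("insulin balance is exactly secretion minus clearance", {
  p <- beta_params(k_i = 1, d_i = 0.5)
  expect_equal(insulin_derivative(2, 1, 1, p), 0)       # balance point
  expect_equal(insulin_derivative(3, 0, 0.7, p), -0.5 * 3)
  set.seed(11)
  for (i in 1:20) {
    ins <- runif(1, 0, 5); fg <- runif(1); fe <- runif(1)
    expect_equal(insulin_derivative(ins, fg, fe, p),
                 p$k_i * fg * fe - p$d_i * ins, tolerance = 1e-14)
  }
})

test_that("state layout has 13 model variables, 9 clock components, 2 food", {
  expect_length(bc_state_names(), 15)
  expect_length(bc_model_vars(), 13)
  expect_length(bc_clock_vars(), 9)
  expect_length(setdiff(bc_state_names(), bc_model_vars()), 2)
  expect_true(all(bc_clock_vars() %in% bc_model_vars()))
})

test_that("rhs: production-only at the zero state, insulin row consistent", {
  p <- beta_params()
  sched <- feeding_schedule()
  zero <- setNames(rep(0, 15), bc_state_names())
  d0 <- model_rhs(6, zero, p, sched, food_constant = TRUE)
  expect_true(all(d0 >= 0))

  set.seed(3)
  for (i in 1:10) {
    s <- setNames(runif(15, 0, 3), bc_state_names())
    d <- model_rhs(runif(1, 0, 24), s, p, sched)
    expect_equal(d[["insulin"]],
                 insulin_derivative(s[["insulin"]],
                                    f_glu(s[["glucose"]], p),
                                    f_exo(s[["exo_prot"]], p), p),
                 tolerance = 1e-12)
  }
})

test_that("with both couplings off the clock block is autonomous", {
  p <- beta_params(c_glu = 0, cneur = 0)
  sched <- feeding_schedule()
  set.seed(5)
  s <- setNames(runif(15, 0.5, 2), bc_state_names())
  d1 <- model_rhs(8, s, p, sched)
  s2 <- s
  s2[c("glucose", "insulin", "food_act", "food_sat")] <-
    s2[c("glucose", "insulin", "food_act", "food_sat")] * 3
  d2 <- model_rhs(8, s2, p, sched)
  expect_equal(d1[bc_clock_vars()], d2[bc_clock_vars()], tolerance = 1e-12)
})

test_that("compiled rhs matches the R reference implementation", {
  p <- beta_params()
  sched <- feeding_schedule(food_shift = 5)
  set.seed(9)
  for (arch in c("physiological", "no_central_clock", "no_clock")) {
    s <- setNames(runif(15, 0.1, 3), bc_state_names())
    # integrate one day with the compiled model and with the plain-R rhs
    compiled <- integrate_model(p, sched, c(0, 24), init = s,
                                architecture = arch, exo_const = 0.2,
                                dt = 0.5)
    r_fun <- function(t, y, parms)
      list(model_rhs(t, y, p, sched, architecture = arch,
                     exo_const = 0.2))
    plain <- deSolve::lsoda(y = s, times = seq(0, 24, by = 0.5),
                            func = r_fun, parms = NULL,
                            rtol = 1e-8, atol = 1e-10)
    expect_equal(unname(compiled$states[, seq_len(15)]),
                 unname(plain[, 2:16]), tolerance = 1e-5)
  }
})

test_that("parameter validation rejects bad sets and unknown keys", {
  expect_error(beta_params(cneur = -1), "negative coupling")
  expect_error(beta_params(n_rb = 0.5), "Hill exponent")
  expect_error(beta_params(d_i = 0), "non-positive")
  expect_error(beta_params(not_a_param = 1), "unknown parameter")
  p <- beta_params(cneur = 0)   # zero coupling is legal
  expect_s3_class(p, "beta_params")
})
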