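test_that("threshold infection cost is bounded, monotone, and hits the midpoint", {
  p <- infection_cost_params(100, 400, i_hc = 0.1, sigma = 300)
  expect_equal(infection_cost(p$i_hc, p), 250)  # tanh(0) = 0
  iseq <- seq(0, 1, length.out = 500)
  a <- infection_cost(iseq, p)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 100 & a <= 400))
  # strictly inside the bounds wherever tanh has not saturated in doubles
  near <- abs(iseq - p$i_hc) * p$sigma < 18
  expect_true(all(a[near] > 100 & a[near] < 400))
  # constant variant ignores the threshold entirely
  pc <- constant_cost(123)
  expect_equal(infection_cost(iseq, pc), rep(123, 500))
})

test_that("cost derivative matches a central finite difference", {
  p <- infection_cost_params(100, 400, i_hc = 0.01, sigma = 300)
  for (i in c(0.005, 0.01, 0.01 + 5 / 300, 0.02)) {
    h <- 1e-7
    fd <- (infection_cost(i + h, p) - infection_cost(i - h, p)) / (2 * h)
    expect_close(infection_cost_deriv(i, p) / fd, 1, 1e-5)
  }
  # at i = 0 only a one-sided difference is available: O(h) accurate
  h <- 1e-9
  fd0 <- (infection_cost(h, p) - infection_cost(0, p)) / h
  expect_close(infection_cost_deriv(0, p) / fd0, 1, 1e-5)
  expect_equal(infection_cost_deriv(p$i_hc, p), (400 - 100) * 300 / 2)
  expect_equal(infection_cost_deriv(0.5, constant_cost(5)), 0)
})

test_that("salvage term reproduces the tail quadrature for exponential decay", {
  # with constant alpha and i(t) = i_f exp(-(t - tf)), the tail integral
  # int_tf^inf f^-t (-alpha i) dt has the closed form -f^-tf alpha i_f/(1+ln f)
  p <- constant_cost(400)
  for (f in c(1, 1.05, 1.2)) {
    for (i_f in c(0, 1e-8, 1e-4)) {
      tail_quad <- stats::integrate(function(t)
        -f^(-t) * 400 * i_f * exp(-(t - 50)), 50, Inf,
        rel.tol = 1e-12)$value
      expect_close(salvage_value(i_f, f, 50, p), tail_quad,
                   1e-6 * max(abs(tail_quad), 1e-300))
    }
  }
  expect_equal(salvage_value(1e-8, 1, 50, p), -400 * 1e-8)
  expect_equal(salvage_value(0, 1.1, 50, p), 0)
})

test_that("objectives vanish on a disease-free, undisturbed trajectory", {
  g <- grid_fast(tf = 20, n = 801)
  p <- params_gov(alpha = 400, gamma_g = 0.5)
  traj <- integrate_sir(4, epidemic_params(i0 = 1e-300), g)
  traj$i[] <- 0
  traj$s[] <- 1
  for (w in c("individual", "population", "government"))
    expect_close(evaluate_objective(traj, w, p), 0, 1e-12)
  expect_error(evaluate_objective(traj, "nonsense", p))
})

test_that("objective quadrature matches a closed form on an analytic path", {
  # k = 0: i(t) = i0 exp(-t); with constant alpha and kappa* = 4 the
  # running utility is f^-t (-alpha i0 e^-t - 16), integrable in closed form
  g <- time_grid(tf = 40, n = 3201)
  i0 <- 1e-3
  for (f in c(1, 1.1)) {
    p <- model_params(epidemic_params(i0 = i0),
                      utility_params(f = f, cost = constant_cost(400)))
    traj <- integrate_sir(0, p$epidemic, g)
    lam <- 1 + log(f)
    int_disc <- if (f == 1) g$tf else (1 - f^(-g$tf)) / log(f)
    closed <- -400 * i0 * (1 - exp(-lam * g$tf)) / lam - 16 * int_disc +
      salvage_value(traj$i[g$n], f, g$tf, p$utility$cost)
    expect_close(evaluate_objective(traj, "population", p), closed,
                 1e-8 * abs(closed))
  }
})

test_that("objective value is stable under grid refinement", {
  ep <- epidemic_params()
  p <- params_const(400)
  o1 <- evaluate_objective(integrate_sir(4, ep, time_grid(100, 5001)),
                           "population", p)
  o2 <- evaluate_objective(integrate_sir(4, ep, time_grid(100, 10001)),
                           "population", p)
  expect_lt(abs(o1 - o2) / abs(o1), 1e-8)
})

test_that("printed tail-correction coefficients of the tanh cost are reproduced", {
  coeff <- function(i_hc, sigma = 300) (1 - tanh(i_hc * sigma)) / 2
  expect_equal(signif(coeff(0.01), 2), 2.5e-3)
  expect_equal(round(coeff(0.003), 2), 0.14)
  # and through the cost function itself
  p <- infection_cost_params(100, 400, i_hc = 0.01, sigma = 300)
  expect_close((infection_cost(0, p) - 100) / 300, coeff(0.01), 1e-12)
})
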