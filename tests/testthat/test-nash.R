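test_that("costates vanish when infection carries no cost", {
  g <- grid_fast(tf = 30, n = 1201)
  p <- params_const(alpha = 0)
  traj <- integrate_sir(4, p$epidemic, g)
  up0 <- utility_params(f = 1, cost = constant_cost(0))
  cs <- individual_costates(traj, up0)
  expect_equal(max(abs(cs$v_s)), 0)
  expect_equal(max(abs(cs$v_i)), 0)
})

test_that("v_s stays at its terminal value when there are no infections", {
  g <- grid_fast(tf = 30, n = 1201)
  traj <- integrate_sir(4, epidemic_params(i0 = 1e-300), g)
  traj$i[] <- 0
  up <- utility_params(cost = constant_cost(400))
  cs <- individual_costates(traj, up)
  expect_equal(max(abs(cs$v_s)), 0)   # v_s' = (v_s-v_i) k i = 0, v_s(tf) = 0
})

test_that("terminal conditions hold exactly", {
  g <- grid_fast(tf = 40, n = 1601)
  for (f in c(1, 1.1)) {
    up <- utility_params(f = f, cost = constant_cost(400))
    p <- model_params(epidemic_params(), up)
    traj <- integrate_sir(4, p$epidemic, g)
    for (cs in list(individual_costates(traj, up),
                    population_costates(traj, up))) {
      expect_equal(cs$v_s[g$n], 0)
      expect_equal(cs$v_i[g$n], -f^(-g$tf) * 400 / (1 + log(f)))
    }
  }
})

test_that("backward integration agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  g <- grid_fast(tf = 40, n = 1601)
  up <- utility_params(cost = constant_cost(400))
  p <- model_params(epidemic_params(), up)
  traj <- integrate_sir(4, p$epidemic, g)
  ifun <- stats::splinefun(g$t, traj$i)
  kfun <- stats::splinefun(g$t, traj$k)
  # independent oracle: lsoda run backward in transformed time tau = tf - t
  rhs <- function(tau, y, parms) {
    t <- g$tf - tau
    list(-c((y[1] - y[2]) * kfun(t) * ifun(t), 400 + y[2]))
  }
  y_tf <- c(0, -400)
  ode <- deSolve::lsoda(y_tf, seq(0, g$tf, length.out = 401), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  cs <- individual_costates(traj, up)
  vs_oracle <- rev(ode[, 2]); vi_oracle <- rev(ode[, 3])
  idx <- seq(1, g$n, by = 4)  # oracle grid is 4x coarser
  expect_lt(max(abs(cs$v_s[idx] - vs_oracle)), 1e-6 * max(abs(vs_oracle)))
  expect_lt(max(abs(cs$v_i[idx] - vi_oracle)), 1e-6 * max(abs(vi_oracle)))
})

test_that("the optimality rule reduces correctly in degenerate cases", {
  g <- grid_fast(tf = 10, n = 401)
  up <- utility_params(cost = constant_cost(400))
  traj <- integrate_sir(4, epidemic_params(i0 = 1e-4), g)
  cs_eq <- structure(list(grid = g, v_s = rep(-1, g$n), v_i = rep(-1, g$n)),
                     class = "costate_trajectory")
  # equal values: no infection incentive, candidate = kappa*
  expect_equal(control_update(traj, cs_eq, up, 4), rep(4, g$n))
  # a flat intervention shifts the candidate by eps/2
  traj$eps <- rep(-2, g$n)
  expect_equal(control_update(traj, cs_eq, up, 4), rep(3, g$n))
  # strong infection penalty clips at zero
  cs_big <- structure(list(grid = g,
                           v_s = 16 * 4 / (traj$s * traj$i), v_i = rep(0, g$n)),
                      class = "costate_trajectory")
  traj$eps <- rep(0, g$n)
  expect_equal(min(control_update(traj, cs_big, up, 4)), 0)
})

test_that("zero infection cost leaves behaviour at baseline", {
  g <- grid_fast(tf = 40, n = 1601)
  p <- params_const(alpha = 0)
  sol <- solve_nash(p, g, extend = FALSE)
  expect_true(sol$converged)
  expect_equal(sol$iterations, 0)
  expect_equal(sol$traj$k, rep(4, g$n))
  base <- integrate_sir(4, p$epidemic, g)
  expect_equal(sol$traj$i, base$i)
})

test_that("the converged equilibrium is a true Nash fixed point", {
  g <- grid_default()
  p <- params_const(400)
  sol <- solve_nash(p, g)
  expect_true(sol$converged)
  chk <- verify_nash_fixed_point(sol, p)
  expect_lt(chk$gap, 1e-4)
  # no profitable defection beyond numerical noise
  expect_lt(chk$utility_gain, 1e-4 * abs(sol$objective))
  expect_gte(chk$utility_gain, -1e-8 * abs(sol$objective))
})

test_that("defection from the uncontrolled baseline is profitable when infection is costly", {
  g <- grid_default()
  p <- params_const(400)
  br <- best_response(4, p, g)
  expect_true(br$converged)
  expect_gt(max(abs(br$kappa - 4)), 0.1)            # responds by distancing
  expect_gt(br$objective, br$objective_conform)     # and gains utility
})

test_that("equilibrium peak infections decrease with the constant infection cost", {
  g <- grid_default()
  peaks <- vapply(c(100, 175, 400), function(a) {
    sol <- solve_nash(params_const(a), g)
    expect_true(sol$converged)
    max(sol$traj$i)
  }, 0)
  expect_true(all(diff(peaks) < 0))
})

test_that("equilibrium utility is stable under grid refinement", {
  p <- params_const(400)
  u1 <- solve_nash(p, time_grid(100, 5001))$objective
  u2 <- solve_nash(p, time_grid(100, 10001))$objective
  expect_lt(abs(u1 - u2) / abs(u1), 1e-6)
})
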