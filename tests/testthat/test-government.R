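test_that("government costates vanish in the no-cost, no-signal case", {
  g <- grid_fast(tf = 30, n = 1201)
  traj <- integrate_sir(4, epidemic_params(), g)
  up <- utility_params(cost = constant_cost(400))
  gp0 <- government_params(gamma_g = 0, cost_g = constant_cost(0))
  # equal inner values carry no infection signal into Lambda
  cs_eq <- structure(list(grid = g, v_s = rep(-2, g$n), v_i = rep(-2, g$n)),
                     class = "costate_trajectory")
  gc <- government_costates(traj, cs_eq, gp0, up, 4)
  expect_equal(max(abs(gc$lambda_s)), 0)
  expect_equal(max(abs(gc$lambda_i)), 0)
  expect_equal(max(abs(gc$Lambda)), 0)
})

test_that("lambda_s stays at zero when there are no infections", {
  g <- grid_fast(tf = 30, n = 1201)
  traj <- integrate_sir(4, epidemic_params(i0 = 1e-300), g)
  traj$i[] <- 0
  up <- utility_params(cost = constant_cost(400))
  gp <- government_params(gamma_g = 0.5, cost_g = constant_cost(400))
  cs <- individual_costates(traj, up)
  gc <- government_costates(traj, cs, gp, up, 4)
  expect_equal(max(abs(gc$lambda_s)), 0)  # lambda_s' = i Lambda = 0
})

test_that("government backward pass agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  # costly-intervention scenario: constant alpha_g = 400, gamma_g = 0.5,
  # along a converged equilibrium under a non-trivial intervention field
  g <- grid_fast(tf = 40, n = 1601)
  up <- utility_params(cost = constant_cost(400))
  gp <- government_params(gamma_g = 0.5, cost_g = constant_cost(400))
  p <- model_params(epidemic_params(), up, gp)
  eps <- -1.5 * exp(-((g$t - 12) / 6)^2)
  sol <- solve_nash(p, g, eps = eps, extend = FALSE)
  expect_true(sol$converged)
  gc <- government_costates(sol$traj, sol$costates, gp, up, 4)
  sf <- stats::splinefun(g$t, sol$traj$s)
  iff <- stats::splinefun(g$t, sol$traj$i)
  ef <- stats::splinefun(g$t, eps)
  vsf <- stats::splinefun(g$t, sol$costates$v_s)
  vif <- stats::splinefun(g$t, sol$costates$v_i)
  rhs <- function(tau, y, parms) {
    t <- g$tf - tau
    s <- sf(t); i <- iff(t); e <- ef(t)
    dv <- vif(t) - vsf(t); dl <- y[2] - y[1]
    Lam <- -dl * (4 + e / 2) +
      0.5 * dv * (i * s * (dv - 2 * dl) + e * (0.5 + 1))
    list(-c(i * Lam, s * Lam + 400 + y[2]))
  }
  ode <- deSolve::lsoda(c(0, -400), seq(0, g$tf, length.out = 401), rhs,
                        NULL, rtol = 1e-10, atol = 1e-12)
  idx <- seq(1, g$n, by = 4)
  # before the epidemic takes off (s ~ 1, i ~ 0) the adjoint system has a
  # backward-unstable mode that amplifies interpolation noise, so the two
  # integrators are compared after onset
  late <- g$t[idx] >= 12
  scale <- max(abs(gc$lambda_i[idx][late]))
  expect_lt(max(abs((gc$lambda_s[idx] - rev(ode[, 2]))[late])), 1e-6 * scale)
  expect_lt(max(abs((gc$lambda_i[idx] - rev(ode[, 3]))[late])), 1e-6 * scale)
})

test_that("the intervention rule reduces correctly in degenerate cases", {
  g <- grid_fast(tf = 10, n = 401)
  up <- utility_params(cost = constant_cost(400))
  traj <- integrate_sir(4, epidemic_params(i0 = 1e-4), g)
  mk_cs <- function(vs, vi)
    structure(list(grid = g, v_s = rep(vs, g$n), v_i = rep(vi, g$n)),
              class = "costate_trajectory")
  mk_gc <- function(ls, li)
    structure(list(grid = g, lambda_s = rep(ls, g$n),
                   lambda_i = rep(li, g$n), Lambda = rep(0, g$n)),
              class = "gov_costates")
  gp <- government_params(gamma_g = 0.5, cost_g = constant_cost(400))
  # no infections -> no leverage -> eps = 0
  tr0 <- traj; tr0$i <- rep(0, g$n)
  expect_equal(max(abs(epsilon_update(tr0, mk_cs(-1, -3), mk_gc(0, -2),
                                      gp, up))), 0)
  # equal value differences cancel
  expect_equal(max(abs(epsilon_update(traj, mk_cs(-1, -1), mk_gc(-2, -2),
                                      gp, up))), 0)
  # beta_g = 1, gamma_g = 0 reduction: eps = i s [(v_s-v_i) - (l_s-l_i)]
  gp0 <- government_params(gamma_g = 0, cost_g = constant_cost(400))
  got <- epsilon_update(traj, mk_cs(-1, -4), mk_gc(-2, -3), gp0, up)
  expect_equal(got, traj$i * traj$s * ((-1 + 4) - (-2 + 3)))
  # degenerate weights are rejected
  gp_bad <- government_params(gamma_g = 0, cost_g = constant_cost(400))
  gp_bad$beta_g <- 0
  expect_error(epsilon_update(traj, mk_cs(-1, -4), mk_gc(-2, -3), gp_bad, up))
})

test_that("cost-free intervention decentralizes the coordinated optimum", {
  # matched preferences, moderate infection cost, short horizon: the
  # induced equilibrium must match the utilitarian optimum
  g <- grid_fast(tf = 60, n = 2401)
  p <- model_params(epidemic_params(),
                    utility_params(cost = constant_cost(100)),
                    government_params(gamma_g = 0,
                                      cost_g = constant_cost(100)))
  ut <- solve_utilitarian(p, g)
  gov <- solve_government(p, g)
  expect_true(gov$converged)
  n <- min(ut$traj$grid$n, gov$solution$traj$grid$n)
  expect_lt(max(abs(gov$solution$traj$k[1:n] - ut$traj$k[1:n])), 1e-3)
  expect_lt(abs(gov$V - ut$objective) / abs(ut$objective), 1e-6)
  # reported V is the government objective evaluated on the stored path
  expect_equal(gov$V,
               evaluate_objective(gov$solution$traj, "government", p))
})

test_that("no smooth perturbation of the optimal intervention raises V", {
  # at the cost-free matched optimum the decentralized coordinated maximum
  # is exact, so bumping eps in either direction can only lower V
  g <- grid_fast(tf = 60, n = 2401)
  p <- model_params(epidemic_params(),
                    utility_params(cost = constant_cost(100)),
                    government_params(gamma_g = 0,
                                      cost_g = constant_cost(100)))
  gov <- solve_government(p, g)
  expect_true(gov$converged)
  g2 <- gov$solution$traj$grid
  eps_star <- gov$solution$traj$eps
  k_warm <- gov$solution$traj$k
  for (centre in c(10, 20, 30)) {
    for (delta in c(-0.05, 0.05)) {
      bump <- delta * exp(-((g2$t - centre) / 3)^2)
      ns <- solve_nash(p, g2, eps = eps_star + bump, k_init = k_warm,
                       extend = FALSE)
      expect_true(ns$converged)
      V_pert <- evaluate_objective(ns$traj, "government", p)
      expect_lte(V_pert, gov$V + 1e-7 * abs(gov$V))
    }
  }
})

test_that("a frozen zero intervention reproduces the plain Nash solution", {
  g <- grid_fast(tf = 60, n = 2401)
  p <- model_params(epidemic_params(),
                    utility_params(cost = constant_cost(100)),
                    government_params(gamma_g = 0,
                                      cost_g = constant_cost(100)))
  nash <- solve_nash(p, g)
  inner <- solve_nash(p, g, eps = 0)  # what the outer loop sees at eps = 0
  expect_equal(inner$traj$k, nash$traj$k)
  expect_equal(inner$objective, nash$objective)
})
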