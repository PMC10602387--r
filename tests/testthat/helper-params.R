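# Shared fixtures: canonical parameter sets and small grids used across the
# suite. Grids are kept short where the scenario allows it so the default
# test run stays fast.

grid_fast <- function(tf = 60, n = 2401) time_grid(tf = tf, n = n)
grid_default <- function() time_grid(tf = 100, n = 5001)

params_const <- function(alpha = 400, f = 1, kappa_star = 4, i0 = 3e-8) {
  model_params(epidemic_params(kappa_star = kappa_star, i0 = i0),
               utility_params(f = f, cost = constant_cost(alpha)))
}

params_threshold <- function(alpha0 = 100, alpha1 = 400, i_hc = 0.1,
                             sigma = 300, f = 1) {
  model_params(epidemic_params(),
               utility_params(f = f,
                              cost = infection_cost_params(alpha0, alpha1,
                                                           i_hc, sigma)))
}

params_gov <- function(alpha = 400, gamma_g = 0, alpha_g = alpha,
                       f = 1, f_g = 1) {
  model_params(epidemic_params(),
               utility_params(f = f, cost = constant_cost(alpha)),
               government_params(f_g = f_g, gamma_g = gamma_g,
                                 cost_g = constant_cost(alpha_g)))
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
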