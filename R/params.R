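#' Uniform time grid
#'
#' Builds the shared uniform grid on which states, costates and controls are
#' tabulated. Time is dimensionless, measured in units of the mean infectious
#' period, so `tf = 100` corresponds to one hundred infectious periods.
#'
#' @param tf Final (horizon) time, in units of the mean infectious period.
#' @param n Number of uniformly spaced nodes (at least 2); the default gives
#'   `dt = 0.02`. An odd `n` keeps the number of intervals even, which the
#'   composite Simpson quadrature of the objectives uses at full order.
#' @param t0 Start time; the epidemic is seeded at `t0 = 0`.
#' @return An object of class `time_grid` with fields `t0`, `tf`, `n`, `dt`
#'   and the node vector `t`.
#' @examples
#' g <- time_grid(tf = 50, n = 2001)
#' g$dt
#' @export
time_grid <- function(tf = 100, n = 5001, t0 = 0) {
  stopifnot(is.numeric(tf), is.numeric(n), is.numeric(t0), length(tf) == 1L,
            length(n) == 1L, n >= 2, tf > t0)
  n <- as.integer(n)
  dt <- (tf - t0) / (n - 1)
  structure(list(t0 = t0, tf = tf, n = n, dt = dt,
                 t = t0 + dt * (seq_len(n) - 1)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> [%g, %g], n = %d, dt = %g\n",
              x$t0, x$tf, x$n, x$dt))
  invisible(x)
}

#' Epidemic parameters
#'
#' Parameters of the rescaled SIR model (recovery rate 1). `kappa_star` is the
#' baseline infectiousness adopted in the absence of any behavioural change,
#' i.e. the basic reproduction number R0.
#'
#' @param kappa_star Baseline infectiousness (R0), must exceed 1.
#' @param i0 Initial infected fraction; the susceptible fraction starts at
#'   `1 - i0`.
#' @return An object of class `epidemic_params`.
#' @export
epidemic_params <- function(kappa_star = 4, i0 = 3e-8) {
  stopifnot(kappa_star > 1, i0 > 0, i0 < 1)
  structure(list(kappa_star = kappa_star, i0 = i0, s0 = 1 - i0),
            class = "epidemic_params")
}

#' Infection-cost function parameters
#'
#' The cost per infection either is constant (`constant = TRUE`, value
#' `alpha0`) or rises smoothly from `alpha0` to `alpha1` around a healthcare
#' capacity threshold `i_hc`:
#' `alpha(i) = alpha0 + (alpha1 - alpha0)/2 * (tanh((i - i_hc) * sigma) + 1)`.
#' The step models the deterioration of average treatment quality once the
#' infected fraction saturates care capacity.
#'
#' @param alpha0 Minimum cost per infection (below-threshold cost).
#' @param alpha1 Maximum cost per infection (above-threshold cost); ignored in
#'   the constant variant.
#' @param i_hc Healthcare threshold, as a fraction of the population infected.
#' @param sigma Steepness of the transition, per unit of `i`.
#' @param constant If `TRUE` the cost is `alpha0` for every `i`.
#' @return An object of class `infection_cost_params`.
#' @seealso [infection_cost()], [constant_cost()]
#' @export
infection_cost_params <- function(alpha0 = 100, alpha1 = 400, i_hc = 0.1,
                                  sigma = 300, constant = FALSE) {
  stopifnot(alpha0 >= 0, i_hc > 0, sigma > 0)
  if (!constant) stopifnot(alpha1 >= alpha0)
  structure(list(alpha0 = alpha0, alpha1 = if (constant) alpha0 else alpha1,
                 i_hc = i_hc, sigma = sigma, constant = constant),
            class = "infection_cost_params")
}

#' Constant infection cost
#'
#' Convenience constructor for the constant-cost variant `alpha(i) = alpha`.
#'
#' @param alpha Cost per infection.
#' @return An `infection_cost_params` object with `constant = TRUE`.
#' @export
constant_cost <- function(alpha) {
  infection_cost_params(alpha0 = alpha, alpha1 = alpha, i_hc = 0.1,
                        sigma = 300, constant = TRUE)
}

#' Individual utility parameters
#'
#' Parameters of the representative individual's discounted utility: discount
#' rate `f` (discount time `1/log(f)`; `f = 1` means no discounting), social
#' distancing cost coefficient `beta` (units are chosen so `beta = 1`), and an
#' infection-cost function.
#'
#' @param f Discount rate, `f >= 1`.
#' @param beta Quadratic distancing-cost coefficient, positive.
#' @param cost An [infection_cost_params()] object.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(f = 1, beta = 1, cost = constant_cost(400)) {
  stopifnot(f >= 1, beta > 0, inherits(cost, "infection_cost_params"))
  structure(list(f = f, lnf = log(f), beta = beta, cost = cost),
            class = "utility_params")
}

#' Government objective parameters
#'
#' The government's objective mirrors the population's but with its own
#' discount rate `f_g`, distancing-cost weight `beta_g`, infection-cost
#' function `cost_g`, and an intervention-cost coefficient `gamma_g`
#' (the shadow cost of public funds: `gamma_g = 0` means incentives are free
#' to operate, `gamma_g > 0` makes the intervention process itself costly).
#'
#' @param f_g Government discount rate, `f_g >= 1`.
#' @param beta_g Distancing-cost coefficient, positive.
#' @param gamma_g Intervention (shadow) cost coefficient, non-negative.
#' @param cost_g An [infection_cost_params()] object with bounds
#'   `alpha_g0`, `alpha_g1`.
#' @return An object of class `government_params`.
#' @export
government_params <- function(f_g = 1, beta_g = 1, gamma_g = 0,
                              cost_g = constant_cost(400)) {
  stopifnot(f_g >= 1, beta_g > 0, gamma_g >= 0,
            inherits(cost_g, "infection_cost_params"))
  structure(list(f_g = f_g, lnfg = log(f_g), beta_g = beta_g,
                 gamma_g = gamma_g, cost = cost_g),
            class = "government_params")
}

#' Full scenario parameter bundle
#'
#' @param epidemic An [epidemic_params()] object.
#' @param utility A [utility_params()] object.
#' @param government A [government_params()] object, or `NULL` when no
#'   government layer is used.
#' @return An object of class `model_params`.
#' @export
model_params <- function(epidemic = epidemic_params(),
                         utility = utility_params(),
                         government = NULL) {
  stopifnot(inherits(epidemic, "epidemic_params"),
            inherits(utility, "utility_params"))
  if (!is.null(government)) stopifnot(inherits(government, "government_params"))
  structure(list(epidemic = epidemic, utility = utility,
                 government = government),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  ep <- x$epidemic; up <- x$utility
  cat(sprintf("<model_params> kappa* = %g, i0 = %g, f = %g, beta = %g\n",
              ep$kappa_star, ep$i0, up$f, up$beta))
  a <- up$cost
  if (a$constant) {
    cat(sprintf("  infection cost: constant alpha = %g\n", a$alpha0))
  } else {
    cat(sprintf("  infection cost: alpha0 = %g, alpha1 = %g, i_hc = %g, sigma = %g\n",
                a$alpha0, a$alpha1, a$i_hc, a$sigma))
  }
  if (!is.null(x$government)) {
    g <- x$government
    cat(sprintf("  government: f_g = %g, beta_g = %g, gamma_g = %g, alpha_g in [%g, %g]\n",
                g$f_g, g$beta_g, g$gamma_g, g$cost$alpha0, g$cost$alpha1))
  }
  invisible(x)
}
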