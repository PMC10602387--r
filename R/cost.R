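#' Cost per infection
#'
#' Evaluates the infection-cost function
#' `alpha(i) = alpha0 + (alpha1 - alpha0)/2 * (tanh((i - i_hc) * sigma) + 1)`
#' (or the constant `alpha0` in the constant-cost variant). The function is
#' monotone non-decreasing in `i` and strictly inside `(alpha0, alpha1)` for
#' finite `i` in the threshold variant; in particular the cost at `i = 0`
#' slightly exceeds `alpha0` when the threshold is close to zero.
#'
#' @param i Infected fraction(s), non-negative.
#' @param p An [infection_cost_params()] object.
#' @return `alpha(i)`, vectorised over `i`.
#' @examples
#' p <- infection_cost_params(100, 400, i_hc = 0.01, sigma = 300)
#' infection_cost(0, p)   # slightly above alpha0
#' infection_cost(p$i_hc, p)  # midpoint (alpha0 + alpha1)/2
#' @export
infection_cost <- function(i, p) {
  stopifnot(inherits(p, "infection_cost_params"), all(i >= 0))
  if (p$constant) return(rep(p$alpha0, length(i)))
  p$alpha0 + 0.5 * (p$alpha1 - p$alpha0) * (tanh((i - p$i_hc) * p$sigma) + 1)
}

#' Derivative of the infection cost
#'
#' `d alpha / d i = (alpha1 - alpha0) * sigma / 2 * sech((i - i_hc) sigma)^2`,
#' or 0 in the constant variant. Enters the population and government costate
#' equations through the term `alpha'(i) * i`.
#'
#' @inheritParams infection_cost
#' @return `alpha'(i)`, vectorised over `i`.
#' @export
infection_cost_deriv <- function(i, p) {
  stopifnot(inherits(p, "infection_cost_params"), all(i >= 0))
  if (p$constant) return(rep(0, length(i)))
  0.5 * (p$alpha1 - p$alpha0) * p$sigma / cosh((i - p$i_hc) * p$sigma)^2
}

#' Salvage utility of the epidemic tail
#'
#' Closed-form approximation of the post-horizon utility contribution,
#' assuming a perfect vaccine arrives at `tf` (susceptibles drop to zero, the
#' remaining infections decay as `exp(-(t - tf))`):
#' `U_f = -f^(-tf) * alpha(0) * i_f / (1 + log f)` with the natural
#' logarithm, so the undiscounted limit `f = 1` gives `-alpha(0) * i_f`.
#' The horizon is always chosen long enough that `i_f` is tiny (typically
#' below 1e-8) and the term is a small correction.
#'
#' @param i_f Infected fraction at the horizon `tf`.
#' @param f Discount rate, `f >= 1`.
#' @param tf Horizon time.
#' @param p An [infection_cost_params()] object; the tail uses `alpha(0)`.
#' @return The salvage utility (non-positive).
#' @export
salvage_value <- function(i_f, f, tf, p) {
  stopifnot(i_f >= 0, f >= 1)
  -f^(-tf) * infection_cost(0, p) * i_f / (1 + log(f))
}

# Composite Simpson quadrature on the uniform grid; falls back to a
# trapezoid on the last interval when the number of intervals is odd.
quad_grid <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  m <- if ((n - 1) %% 2 == 0) n else n - 1  # m nodes span an even # intervals
  total <- 0
  if (m >= 3) {
    w4 <- seq.int(2, m - 1, by = 2)
    w2 <- if (m >= 5) seq.int(3, m - 2, by = 2) else integer(0)
    total <- dt / 3 * (y[1] + y[m] + 4 * sum(y[w4]) + 2 * sum(y[w2]))
  } else {
    m <- 1  # n == 2: whole range handled by the trapezoid below
  }
  if (m < n) total <- total + dt / 2 * (y[n - 1] + y[n])
  total
}

#' Evaluate an objective functional on a trajectory
#'
#' Quadrature of the discounted running utility over the grid plus the
#' matching salvage term. Three objectives share the machinery:
#' \describe{
#'   \item{individual}{the representative individual's utility evaluated at
#'     equilibrium (`psi_s = s`, `psi_i = i`):
#'     `u = f^-t [-alpha(i) i - beta (k - kappa*)^2 + (k - kappa*) eps]`.}
#'   \item{population}{the utilitarian per-capita utility `u_p`, which in the
#'     chosen units (`beta = 1`) has the same integrand.}
#'   \item{government}{`v = f_g^-t [-alpha_g(i) i - beta_g (k - kappa*)^2
#'     - gamma_g eps (k - kappa*)]`: the intervention term changes sign, so
#'     running the incentive scheme is costly when `gamma_g > 0`.}
#' }
#' Sign convention: the return value is a utility (higher is better); the
#' total epidemic cost is its negative.
#'
#' @param traj An `epi_trajectory` (with its `k` and `eps` paths).
#' @param which One of `"individual"`, `"population"`, `"government"`.
#' @param params A [model_params()] bundle (must carry a `government`
#'   component for the government objective).
#' @return The objective value (scalar).
#' @export
evaluate_objective <- function(traj,
                               which = c("individual", "population",
                                         "government"),
                               params) {
  stopifnot(inherits(traj, "epi_trajectory"), inherits(params, "model_params"))
  which <- match.arg(which)
  g <- traj$grid
  ks <- params$epidemic$kappa_star
  dk <- traj$k - ks
  if (which == "government") {
    gp <- params$government
    if (is.null(gp)) stop("government objective requires government params")
    disc <- exp(-g$t * gp$lnfg)
    u <- disc * (-infection_cost(traj$i, gp$cost) * traj$i -
                   gp$beta_g * dk^2 - gp$gamma_g * traj$eps * dk)
    quad_grid(u, g$dt) +
      salvage_value(traj$i[g$n], gp$f_g, g$tf, gp$cost)
  } else {
    up <- params$utility
    disc <- exp(-g$t * up$lnf)
    u <- disc * (-infection_cost(traj$i, up$cost) * traj$i -
                   up$beta * dk^2 + traj$eps * dk)
    quad_grid(u, g$dt) +
      salvage_value(traj$i[g$n], up$f, g$tf, up$cost)
  }
}

# Individual utility for an arbitrary (possibly defecting) behaviour kappa,
# evaluated with the individual's own compartment probabilities against the
# exogenous population infection path.
individual_objective_psi <- function(psi_s, psi_i, kappa, i_pop, eps, grid,
                                     up, kappa_star) {
  disc <- exp(-grid$t * up$lnf)
  dk <- kappa - kappa_star
  u <- disc * (-infection_cost(i_pop, up$cost) * psi_i -
                 up$beta * dk^2 + eps * dk)
  quad_grid(u, grid$dt) +
    salvage_value(psi_i[grid$n], up$f, grid$tf, up$cost)
}
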