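#' Direct-transcription optimization (independent oracle)
#'
#' Independent cross-check on the sweep solvers: parameterises the control by
#' its values at a coarse set of nodes (piecewise-linear in between,
#' interpolated onto the fine grid), evaluates the objective by
#' simulate-then-quadrature, and maximises over the node values with a
#' bounded quasi-Newton optimizer (`optim`, L-BFGS-B) from multiple seeded
#' restarts. No costate equations are used anywhere, so agreement with the
#' forward-backward sweep is evidence both are correct. Because the coarse
#' control cannot match fine-grid paths pointwise, agreement is asserted on
#' objective values.
#'
#' @param objective One of `"individual"` (optimise a defecting individual's
#'   `kappa` against fixed population paths), `"population"` (optimise the
#'   coordinated behaviour `k`), or `"government"` (optimise `eps`; each
#'   evaluation re-solves the inner Nash equilibrium).
#' @param params A [model_params()] bundle.
#' @param grid The fine [time_grid()] used for simulation and quadrature.
#' @param n_nodes Number of coarse control nodes (>= 4).
#' @param fixed Exogenous paths: for `"individual"`, a list with the
#'   population behaviour `k` (and optionally `eps`); for the other
#'   objectives, optionally `eps` (ignored for `"government"`).
#' @param init Optional control path on the fine grid used as the primary
#'   start (sampled at the coarse nodes); defaults to the baseline control.
#' @param restarts Number of seeded random restarts in addition to the
#'   baseline start.
#' @param seed Integer seed for the restarts.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param factr L-BFGS-B convergence factor (see [stats::optim()]); loose
#'   values suffice when the result only seeds a Newton polish.
#' @param opts_inner [sweep_options()] for the inner Nash solves of the
#'   government objective.
#' @return A list with the best coarse `control`, its interpolation
#'   `control_fine`, the achieved `objective`, and `convergence` info per
#'   start (oracle failures are flagged, not hidden).
#' @export
direct_transcription <- function(objective = c("individual", "population",
                                               "government"),
                                 params, grid = time_grid(),
                                 n_nodes = 40, fixed = list(), init = NULL,
                                 restarts = 3, seed = 1, maxit = 200,
                                 factr = 1e4, opts_inner = sweep_options()) {
  objective <- match.arg(objective)
  stopifnot(n_nodes >= 4, inherits(params, "model_params"))
  ep <- params$epidemic
  up <- params$utility
  tc <- seq(grid$t0, grid$tf, length.out = n_nodes)
  interp <- function(z) stats::approx(tc, z, xout = grid$t, rule = 2)$y

  if (objective == "individual") {
    k_pop <- expand_path(fixed$k %||% ep$kappa_star, grid, "k")
    eps <- expand_path(fixed$eps %||% 0, grid, "eps")
    pop <- integrate_sir(k_pop, ep, grid, eps)
    fn <- function(z) {
      kap <- interp(z)
      st <- cpp_psi_rk4(ep$s0, ep$i0, kap, pop$i, grid$dt)
      -individual_objective_psi(st$s, st$i, kap, pop$i, eps, grid, up,
                                ep$kappa_star)
    }
    lower <- rep(0, n_nodes)
    start0 <- rep(ep$kappa_star, n_nodes)
  } else if (objective == "population") {
    eps <- expand_path(fixed$eps %||% 0, grid, "eps")
    fn <- function(z) {
      traj <- suppressWarnings(integrate_sir(interp(z), ep, grid, eps))
      -evaluate_objective(traj, "population", params)
    }
    lower <- rep(0, n_nodes)
    start0 <- rep(ep$kappa_star, n_nodes)
  } else {
    if (is.null(params$government)) stop("government objective needs params")
    k_warm <- NULL
    fn <- function(z) {
      sol <- tryCatch(
        solve_nash(params, grid, eps = interp(z), opts = opts_inner,
                   k_init = k_warm, extend = FALSE),
        error = function(e) NULL)
      if (is.null(sol) || !sol$converged) return(1e10)
      k_warm <<- sol$traj$k
      -evaluate_objective(sol$traj, "government", params)
    }
    lower <- rep(-Inf, n_nodes)
    start0 <- rep(0, n_nodes)
  }

  if (!is.null(init)) {
    init <- expand_path(init, grid, "init")
    start0 <- stats::approx(grid$t, init, xout = tc)$y
  }
  set.seed(seed)
  starts <- c(list(start0),
              lapply(seq_len(restarts), function(j)
                start0 + stats::runif(n_nodes, -0.5, 0.5) * ep$kappa_star))
  if (objective != "government")
    starts <- lapply(starts, function(z) pmax(z, 0))
  fits <- lapply(starts, function(z0)
    tryCatch(stats::optim(z0, fn, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = maxit, factr = factr)),
             error = function(e) list(value = Inf, convergence = 99L,
                                      message = conditionMessage(e))))
  vals <- vapply(fits, function(f) f$value, 0)
  best <- fits[[which.min(vals)]]
  if (!is.finite(best$value))
    warning("direct transcription failed on every start")
  list(control = best$par, control_fine = interp(best$par),
       objective = -best$value, nodes = tc,
       convergence = lapply(fits, function(f)
         list(value = -f$value, code = f$convergence)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pontryagin stationarity residual
#'
#' Maximum scaled violation of the first-order condition along a converged
#' solution: the relevant Hamiltonian's derivative with respect to the
#' control, evaluated by central finite difference, over the interior nodes
#' where the control bound is inactive (`dH/dcontrol <= 0` is allowed, and
#' checked, where the behaviour is clipped at 0). The residual is scaled by
#' `2 beta kappa* f^-t` (resp. `(beta_g/2 + gamma_g) kappa* f_g^-t` for the
#' government) so it is a dimensionless measure comparable across scenarios.
#'
#' @param sol A `ctrl_solution` (Nash or utilitarian) or `gov_solution`.
#' @param params The [model_params()] bundle used to produce it.
#' @param h Relative finite-difference step (times `kappa*`).
#' @return The maximum scaled residual (scalar); also returns, as attribute
#'   `"bound_ok"`, whether `dH/dkappa <= 0` wherever the bound is active.
#' @export
pontryagin_residual <- function(sol, params, h = 1e-5) {
  ep <- params$epidemic
  up <- params$utility
  ks <- ep$kappa_star
  step <- h * ks
  if (inherits(sol, "gov_solution")) {
    gp <- params$government
    traj <- sol$solution$traj
    g <- traj$grid
    vs <- sol$inner_costates$v_s
    vi <- sol$inner_costates$v_i
    ls <- sol$gov_costates$lambda_s
    li <- sol$gov_costates$lambda_i
    ft <- exp(g$t * up$lnf)
    fgt <- exp(g$t * gp$lnfg)
    Hg <- function(e) {
      k <- pmax(0, ks + (e - ft * (vs - vi) * traj$s * traj$i) /
                  (2 * up$beta))
      dk <- k - ks
      -(1 / fgt) * (infection_cost(traj$i, gp$cost) * traj$i +
                      gp$beta_g * dk^2 + gp$gamma_g * e * dk) -
        (ls - li) * k * traj$s * traj$i - li * traj$i
    }
    dH <- (Hg(traj$eps + step) - Hg(traj$eps - step)) / (2 * step)
    scale <- (gp$beta_g / 2 + gp$gamma_g) * ks / fgt
    r <- abs(dH) / scale
    # the eps rule is an interior-behaviour condition: where the kappa >= 0
    # bound binds, eps stationarity is not required (see solve_government)
    interior <- traj$k > 1e-10
    interior[c(1, g$n)] <- FALSE
    res <- if (any(interior)) max(r[interior]) else 0
    attr(res, "bound_ok") <- TRUE
    return(res)
  }
  stopifnot(inherits(sol, "ctrl_solution"))
  traj <- sol$traj
  g <- traj$grid
  vs <- sol$costates$v_s
  vi <- sol$costates$v_i
  ft <- exp(g$t * up$lnf)
  H <- function(k) {
    dk <- k - ks
    (1 / ft) * (-infection_cost(traj$i, up$cost) * traj$i -
                  up$beta * dk^2 + traj$eps * dk) -
      (vs - vi) * k * traj$s * traj$i - vi * traj$i
  }
  dH <- (H(traj$k + step) - H(traj$k - step)) / (2 * step)
  scale <- 2 * up$beta * ks / ft
  r <- dH / scale
  interior <- traj$k > step
  interior[c(1, g$n)] <- FALSE
  res <- if (any(interior)) max(abs(r[interior])) else 0
  at_bound <- !interior
  at_bound[c(1, g$n)] <- FALSE
  attr(res, "bound_ok") <- all(r[at_bound] <= h)
  res
}

#' Verify the Nash fixed-point property
#'
#' Computes the individual best response against a solution's population
#' behaviour and returns the sup-norm defection gap `sup|kappa - k|`,
#' together with the utility gain from defecting. At a true Nash
#' equilibrium both are (numerically) zero; feeding a non-equilibrium
#' solution (e.g. the utilitarian optimum) exposes a profitable defection.
#'
#' @param sol A `ctrl_solution`.
#' @param params The [model_params()] bundle used to produce it.
#' @param opts [sweep_options()] for the best-response sweep.
#' @return A list with `gap` (sup-norm control distance), `utility_gain`
#'   (best-response utility minus the utility of conforming), and the
#'   `best_response` result.
#' @export
verify_nash_fixed_point <- function(sol, params, opts = sweep_options()) {
  stopifnot(inherits(sol, "ctrl_solution"))
  br <- best_response(sol$traj$k, params, sol$traj$grid, sol$traj$eps, opts)
  list(gap = max(abs(br$kappa - sol$traj$k)),
       utility_gain = br$objective - br$objective_conform,
       best_response = br)
}
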