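#' Government costates along an equilibrium trajectory
#'
#' Backward integration of the Lagrange multipliers of the government's
#' (outer, Stackelberg) problem, in which the intervention field `eps(t)` is
#' the control and the population's Nash-equilibrium behaviour is embedded
#' through its optimality rule:
#' `lambda_s' = i Lambda`,
#' `lambda_i' = s Lambda + f_g^-t [alpha_g(i) + alpha_g'(i) i] + lambda_i`,
#' with the auxiliary integrand
#' `Lambda = -(lambda_i - lambda_s)(kappa* + eps/2) + f_g^-t f^t / 2
#' (v_i - v_s) (i s [beta_g f^t (v_i - v_s) - 2 f_g^t (lambda_i - lambda_s)]
#' + eps (gamma_g + beta_g))`
#' and terminal conditions `lambda_s(tf) = 0`,
#' `lambda_i(tf) = -f_g^-tf alpha_g(0) / (1 + log f_g)`.
#'
#' @param traj The converged inner-equilibrium `epi_trajectory` (carrying the
#'   induced `k` and the current `eps`).
#' @param inner_costates The individual `costate_trajectory` (`v_s`, `v_i`)
#'   from the converged inner Nash solve, on the same grid.
#' @param gp A [government_params()] object.
#' @param up A [utility_params()] object (for the individual discount rate
#'   entering `Lambda`).
#' @param kappa_star Baseline infectiousness.
#' @return An object of class `gov_costates` with paths `lambda_s`,
#'   `lambda_i` and the diagnostic `Lambda`.
#' @export
government_costates <- function(traj, inner_costates, gp, up, kappa_star) {
  stopifnot(inherits(traj, "epi_trajectory"),
            inherits(inner_costates, "costate_trajectory"),
            inherits(gp, "government_params"),
            inherits(up, "utility_params"))
  g <- traj$grid
  if (!identical(g$n, inner_costates$grid$n))
    stop("trajectory and inner costates are on different grids")
  term <- -gp$f_g^(-g$tf) * infection_cost(0, gp$cost) / (1 + gp$lnfg)
  out <- cpp_costates_government(traj$s, traj$i, traj$eps,
                                 inner_costates$v_s, inner_costates$v_i,
                                 g$dt, g$t0, up$lnf, gp$lnfg, kappa_star,
                                 gp$beta_g, gp$gamma_g, unclass(gp$cost),
                                 0, term)
  structure(list(grid = g, lambda_s = out$lambda_s, lambda_i = out$lambda_i,
                 Lambda = out$Lambda),
            class = "gov_costates")
}

#' @export
print.gov_costates <- function(x, ...) {
  cat(sprintf("<gov_costates> n = %d, lambda_s(0) = %.4g, lambda_i(0) = %.4g\n",
              x$grid$n, x$lambda_s[1], x$lambda_i[1]))
  invisible(x)
}

#' Candidate intervention field from the government optimality rule
#'
#' Pointwise stationarity of the government Hamiltonian in `eps`:
#' `eps = i s [f^t (beta_g + gamma_g)(v_s - v_i) - f_g^t
#' (lambda_s - lambda_i)] / (beta_g + 2 gamma_g)`.
#'
#' @inheritParams government_costates
#' @param gov_costates A `gov_costates` object on the same grid.
#' @return The candidate `eps` path.
#' @export
epsilon_update <- function(traj, inner_costates, gov_costates, gp, up) {
  stopifnot(inherits(gov_costates, "gov_costates"))
  if (gp$beta_g + 2 * gp$gamma_g <= 0)
    stop("beta_g + 2 gamma_g must be positive")
  g <- traj$grid
  ft <- exp(g$t * up$lnf)
  fgt <- exp(g$t * gp$lnfg)
  traj$i * traj$s *
    (ft * (gp$beta_g + gp$gamma_g) * (inner_costates$v_s - inner_costates$v_i) -
       fgt * (gov_costates$lambda_s - gov_costates$lambda_i)) /
    (gp$beta_g + 2 * gp$gamma_g)
}

new_gov_solution <- function(solution, gov_costates, V, branch_label,
                             converged, iterations, residual,
                             all_local_optima = list()) {
  structure(list(solution = solution, gov_costates = gov_costates,
                 inner_costates = solution$costates, V = V,
                 branch_label = branch_label, converged = converged,
                 iterations = iterations, residual = residual,
                 all_local_optima = all_local_optima),
            class = "gov_solution")
}

#' @export
print.gov_solution <- function(x, ...) {
  cat(sprintf("<gov_solution> %s in %d outer iterations (residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat(sprintf("  V = %.8g, branch = %s, peak i = %.4g\n",
              x$V, x$branch_label, max(x$solution$traj$i)))
  if (length(x$all_local_optima) > 1)
    cat(sprintf("  %d distinct local optima recorded\n",
                length(x$all_local_optima)))
  invisible(x)
}

# Coordinated optimum of the government objective over the behaviour
# itself (what the government would impose if it could dictate k), and the
# intervention field that decentralizes that behaviour through the
# individuals' optimality rule. Used as the default outer starting point:
# for cost-free intervention it already is the optimum, and in general it
# seeds the outer sweep (and the inner warm-start chain) on the
# interventionist branch.

# Behaviour path that lets the epidemic grow freely to the healthcare
# threshold, then holds the infected fraction there (k = 1/s while herd
# immunity has not been reached), then relaxes to baseline. Used only as a
# seed placing the non-convex coordinated problem in the basin of its
# threshold-tracking local optimum.
tracking_path <- function(ep, i_hc, grid) {
  ks <- ep$kappa_star
  k <- rep(ks, grid$n)
  s <- ep$s0
  i <- ep$i0
  holding <- FALSE
  for (j in seq_len(grid$n - 1)) {
    if (!holding && i >= i_hc) holding <- TRUE
    k[j] <- if (holding && s > 1 / ks) min(ks, 1 / s) else ks
    ds <- -k[j] * s * i
    di <- k[j] * s * i - i
    s <- s + grid$dt * ds
    i <- max(i + grid$dt * di, 0)
  }
  k[grid$n] <- k[grid$n - 1]
  k
}

decentralize_target <- function(params, grid, opts, seed = "natural") {
  gp <- params$government
  up <- params$utility
  ep <- params$epidemic
  gov_pref <- model_params(ep, utility_params(f = gp$f_g, beta = gp$beta_g,
                                              cost = gp$cost))
  k_seed <- NULL
  if (!gp$cost$constant) {
    # the coordinated problem is non-convex under a threshold cost and the
    # sweep map is stiff around it; a coarse direct transcription placed in
    # the requested basin provides a reliable warm start for the sweep
    tr_grid <- time_grid(tf = grid$tf, n = 1001, t0 = grid$t0)
    k_seed <- if (identical(seed, "tracking"))
      tracking_path(ep, gp$cost$i_hc, tr_grid) else NULL
    tr <- direct_transcription("population", gov_pref, tr_grid, n_nodes = 61,
                               init = k_seed, restarts = 0, maxit = 150,
                               factr = 1e6)
    k_seed <- pmax(stats::approx(tr_grid$t, tr$control_fine,
                                 xout = grid$t, rule = 2)$y, 0)
  }
  sol <- solve_utilitarian(gov_pref, grid, opts = opts, k_init = k_seed,
                           method = if (is.null(k_seed)) "auto" else "newton")
  g2 <- sol$traj$grid
  vind <- individual_costates(sol$traj, up)
  ft <- exp(g2$t * up$lnf)
  eps0 <- 2 * up$beta * (sol$traj$k - ep$kappa_star) +
    ft * (vind$v_s - vind$v_i) * sol$traj$s * sol$traj$i
  list(eps0 = eps0, k = sol$traj$k, grid = g2)
}

#' Optimal government intervention via nested forward-backward sweep
#'
#' Stackelberg optimization of the intervention field `eps(t)`: the outer
#' sweep updates `eps` from the government optimality rule, and each outer
#' iteration recomputes the population's Nash-equilibrium response to the
#' current `eps` (the inner sweep, warm-started from the previous outer
#' iterate) as the forward pass, followed by a backward pass of the
#' government costates.
#'
#' Because the incentivised equilibrium can be non-unique, the starting
#' point selects the branch the nested solver tracks. The default start
#' (`init = "decentralize"`) first computes the behaviour the government
#' would impose if it could dictate `k` directly, and the intervention that
#' decentralizes it; `init = "zero"` starts from no intervention. Scans use
#' both plus continuation to expose the distinct local optima.
#'
#' @param params A [model_params()] bundle with a `government` component.
#' @param grid A [time_grid()].
#' @param opts_inner [sweep_options()] for the inner Nash solves.
#' @param opts_outer [sweep_options()] for the outer `eps` sweep; the
#'   default relaxation is smaller than the inner one because each outer
#'   step re-equilibrates the whole population, and accelerated steps are
#'   accepted only when they do not increase the residual.
#' @param init_eps Optional explicit starting intervention path (overrides
#'   `init`); used for continuation across parameter scans.
#' @param k_init Optional behaviour path seeding the inner warm-start chain
#'   (used together with `init_eps` to stay on a chosen branch).
#' @param init Starting-point rule when `init_eps` is not given.
#' @param bound_handling How to apply the `eps` optimality rule where the
#'   behaviour bound `kappa >= 0` is active: `"printed"` applies it
#'   pointwise everywhere (the rule as derived, assuming interior
#'   behaviour), `"project"` freezes `eps` at bound-active nodes, which is
#'   what allows the outer residual to vanish when the optimal behaviour
#'   saturates the bound. Scans use `"project"`.
#' @param extend Extend the horizon while the terminal infected fraction
#'   exceeds 1e-8, as in [solve_nash()].
#' @param branch_factor Peak infections below `branch_factor * i_hc` label
#'   the solution `"threshold-tracking"`, otherwise `"high-peak"`.
#' @return A `gov_solution`: converged inner solution (trajectory + inner
#'   costates), government costates, objective `V`, branch label, and a
#'   convergence report. Inner non-convergence aborts the outer iteration
#'   with a diagnostic; outer non-convergence is flagged.
#' @export
solve_government <- function(params, grid = time_grid(),
                             opts_inner = sweep_options(stall = 200),
                             opts_outer = sweep_options(relaxation = 0.05, omega_max = 0.2, accept_factor = 1, cooldown = 25, stall = 150),
                             init_eps = NULL, k_init = NULL,
                             init = c("decentralize",
                                      "decentralize_tracking", "zero"),
                             bound_handling = c("printed", "project"),
                             extend = TRUE,
                             branch_factor = 2) {
  stopifnot(inherits(params, "model_params"))
  init <- match.arg(init)
  bound_handling <- match.arg(bound_handling)
  gp <- params$government
  if (is.null(gp)) stop("solve_government requires government params")
  ep <- params$epidemic
  up <- params$utility
  # the inner equilibrium is resolved an order tighter than the default so
  # that finite differences of the outer map (Newton fallback) see signal,
  # not inner-solve noise; the outer tolerance sits a little above it
  if (is.null(opts_inner$tol)) opts_inner$tol <- 1e-7 * ep$kappa_star
  tol <- if (is.null(opts_outer$tol)) 5e-6 * ep$kappa_star else opts_outer$tol
  gamma_target <- gp$gamma_g
  gamma_path <- NULL
  if (is.null(init_eps) && init != "zero") {
    tgt <- decentralize_target(params, grid, opts_inner,
                               seed = if (init == "decentralize") "natural"
                                      else "tracking")
    grid <- tgt$grid
    init_eps <- tgt$eps0
    k_init <- tgt$k
    # the decentralization start is exact for cost-free intervention; for
    # costly intervention the optimum is reached by numerical continuation
    # in gamma_g from that exactly-solvable case
    if (gamma_target > 0)
      gamma_path <- gamma_target * c(0, 0.25, 0.5, 0.75, 1)
  }
  eps <- expand_path(if (is.null(init_eps)) 0 else init_eps, grid, "eps")
  k_warm <- if (is.null(k_init)) NULL else expand_path(k_init, grid, "k_init")

  solve_once <- function(g, eps) {
    # While the outer iterate is in transit, the warm-started inner
    # equilibrium may sit close to a fold of the equilibrium branch and
    # stall short of full convergence. A mildly unconverged inner solve
    # (soft tolerance) is still a fine forward pass for the outer update;
    # a badly failed one rejects the outer step so the driver backtracks
    # rather than jumping to another equilibrium branch via a cold restart.
    soft_tol <- 0.01 * ep$kappa_star
    n_soft <- 0L
    map <- function(e) {
      inner <- suppressWarnings(
        solve_nash(params, g, e, opts_inner, k_init = k_warm,
                   extend = FALSE))
      if (!inner$converged) {
        if (inner$residual > soft_tol) return(list(reject = TRUE))
        n_soft <<- n_soft + 1L
      }
      # reject steps whose equilibrium leaps away from the tracked branch
      if (!is.null(k_warm) &&
          max(abs(inner$traj$k - k_warm)) > 0.5 * ep$kappa_star)
        return(list(reject = TRUE))
      gc <- government_costates(inner$traj, inner$costates, gp, up,
                                ep$kappa_star)
      cand <- epsilon_update(inner$traj, inner$costates, gc, gp, up)
      if (bound_handling == "project") {
        # the pointwise optimality rule for eps was derived assuming the
        # behaviour is interior; where the kappa >= 0 bound binds it need
        # not vanish at the optimum, so the update is projected out there
        at_bound <- inner$traj$k <= 1e-10
        cand[at_bound] <- e[at_bound]
      }
      list(cand = cand, payload = list(inner = inner, gc = gc))
    }
    # the inner warm start is committed only for accepted outer steps, so a
    # rejected trial evaluation cannot drag the warm-start chain onto a
    # different equilibrium branch
    commit <- function(m) k_warm <<- m$payload$inner$traj$k
    res <- fixed_point_solve(eps, map, opts_outer, tol, on_accept = commit)
    if (!res$converged) {
      # the outer fixed-point map can be expansive around the
      # decentralization start; switch to Newton-Krylov, which handles
      # eigenvalues beyond the unit circle
      np <- newton_polish(res$x, map, tol, max_newton = 40L,
                          gmres_m = 25L, fd_h = 1e-6, nfev_cap = 900L,
                          on_accept = commit,
                          verbose = opts_outer$verbose > 0)
      if (!is.null(np$payload)) {
        np$iterations <- res$iterations + np$nfev
        res <- np
      }
      res$converged <- res$residual < tol
    }
    inner <- res$payload$inner
    gc <- res$payload$gc
    converged <- res$converged
    if (!inner$converged) {
      # final iterate must carry a strictly converged equilibrium
      inner <- suppressWarnings(
        solve_nash(params, g, res$x, opts_inner, k_init = k_warm,
                   extend = FALSE))
      if (!inner$converged) {
        warning(sprintf(
          "final inner equilibrium not fully converged (residual %.3e)",
          inner$residual))
        converged <- FALSE
      }
      gc <- government_costates(inner$traj, inner$costates, gp, up,
                                ep$kappa_star)
    }
    if (n_soft > 0L && opts_outer$verbose > 0)
      message(sprintf("  %d outer iterations used softly-converged inner solves",
                      n_soft))
    list(inner = inner, gc = gc, eps = res$x,
         iterations = res$iterations, residual = res$residual,
         converged = converged)
  }

  if (!is.null(gamma_path)) {
    # continuation: walk gamma_g up to its target, warm-starting eps and the
    # inner equilibrium; halve a step that fails to converge (up to 4 times)
    gcur <- 0
    j <- 2L
    splits <- 0L
    gam <- gamma_path[-1]
    while (gcur < gamma_target) {
      gnext <- if (length(gam)) gam[1] else gamma_target
      gp$gamma_g <- gnext
      params$government <- gp
      step_res <- tryCatch(solve_once(grid, eps),
                           error = function(e) NULL)
      if (!is.null(step_res) && step_res$converged) {
        eps <- step_res$eps
        gcur <- gnext
        gam <- gam[-1]
        splits <- 0L
      } else {
        splits <- splits + 1L
        if (splits > 4L)
          stop(sprintf(
            "gamma continuation failed near gamma_g = %.4g", gnext))
        gam <- c((gcur + gnext) / 2, gam)
        gam[2] <- gnext
      }
    }
    gp$gamma_g <- gamma_target
    params$government <- gp
  }
  res <- if (extend) {
    extend_gov(solve_once, grid, eps, env = environment())
  } else {
    solve_once(grid, eps)
  }
  if (!res$converged)
    warning(sprintf(
      "outer sweep did not converge: residual %.3e after %d iterations",
      res$residual, res$iterations))
  V <- evaluate_objective(res$inner$traj, "government", params)
  peak <- max(res$inner$traj$i)
  label <- if (!gp$cost$constant && peak < branch_factor * gp$cost$i_hc)
    "threshold-tracking" else "high-peak"
  new_gov_solution(res$inner, res$gc, V, label, res$converged,
                   res$iterations, res$residual)
}

extend_gov <- function(solve_once, grid, eps, env, itol = 1e-8,
                       max_extend = 4) {
  res <- solve_once(grid, eps)
  rounds <- 0
  while (res$inner$traj$i[res$inner$traj$grid$n] > itol &&
         rounds < max_extend) {
    g <- res$inner$traj$grid
    n_new <- as.integer(round((g$tf * 1.5 - g$t0) / g$dt)) + 1L
    if (n_new %% 2L == 0L) n_new <- n_new + 1L
    grid <- time_grid(tf = g$t0 + (n_new - 1L) * g$dt, n = n_new, t0 = g$t0)
    pad <- grid$n - g$n
    eps <- c(res$eps, rep(0, pad))
    assign("k_warm", c(get("k_warm", envir = env),
                       rep(utils::tail(get("k_warm", envir = env), 1), pad)),
           envir = env)
    res <- solve_once(grid, eps)
    rounds <- rounds + 1
  }
  if (res$inner$traj$i[res$inner$traj$grid$n] > itol)
    warning("terminal infected fraction still above 1e-8 after extensions")
  res
}

#' Scan the government's maximum infection cost across the policy switch
#'
#' Runs [solve_government()] for an increasing list of `alpha_g1` values
#' (threshold cost variant), from multiple starting interventions: a cold
#' start (`eps = 0`) plus bidirectional continuation from the neighbouring
#' `alpha_g1` solutions. Because the government objective is non-convex in
#' the threshold variant, distinct local optima appear; they are deduplicated
#' by sup-norm distance of their `eps` paths and the maximiser of `V` is
#' selected per `alpha_g1`. The switch is located where the selected branch
#' changes: the peak of infections jumps discontinuously there while the
#' objective itself crosses continuously.
#'
#' @param params A [model_params()] bundle with a government component whose
#'   infection cost is the threshold variant.
#' @param alpha_g1_values Increasing vector of maximum government infection
#'   costs.
#' @param grid,opts_inner,opts_outer As in [solve_government()].
#' @param distinct_tol Sup-norm `eps` distance above which two converged
#'   optima count as distinct (default 1e-2).
#' @param extend Passed to [solve_government()]; scans usually fix a long
#'   horizon instead.
#' @param match_individual Vary the individual's maximum infection cost
#'   together with the government's (matched preferences; at `gamma_g = 0`
#'   the epidemic outcome is independent of the individual preferences, so
#'   this only conditions the solver).
#' @return A list with `runs` (per-`alpha_g1` list of all local optima and
#'   the selected one), `table` (data frame: `alpha_g1`, `peak_i`,
#'   `total_cases`, `duration`, `V`, `branch`), and `switch_alpha_g1`
#'   (smallest scanned `alpha_g1` on the threshold-tracking side, `NA` if the
#'   argmax branch never changes).
#' @export
branch_scan <- function(params, alpha_g1_values, grid = time_grid(),
                        opts_inner = sweep_options(stall = 200),
                        opts_outer = sweep_options(relaxation = 0.05, omega_max = 0.2, accept_factor = 1, cooldown = 25, stall = 150),
                        distinct_tol = 1e-2, extend = TRUE,
                        match_individual = TRUE) {
  stopifnot(inherits(params, "model_params"), !is.null(params$government))
  av <- sort(alpha_g1_values)
  with_a1 <- function(a1) {
    g <- params$government
    g$cost$alpha1 <- a1
    params$government <- g
    if (match_individual && !params$utility$cost$constant)
      params$utility$cost$alpha1 <- a1
    params
  }
  n_a <- length(av)
  sols <- vector("list", n_a)  # list of lists of gov_solution per alpha_g1
  run_start <- function(p, init_eps = NULL, k_init = NULL, init = "zero") {
    tryCatch(suppressWarnings(
      solve_government(p, grid, opts_inner, opts_outer,
                       init_eps = init_eps, k_init = k_init, init = init,
                       bound_handling = "project", extend = extend)),
      error = function(e) {
        warning(sprintf("government solve failed: %s", conditionMessage(e)))
        NULL
      })
  }
  align <- function(path, g, fill) {
    n <- length(path)
    if (n >= g$n) path[seq_len(g$n)] else c(path, rep(fill, g$n - n))
  }
  cont_args <- function(sol, g)
    list(init_eps = align(sol$solution$traj$eps, g, 0),
         k_init = align(sol$solution$traj$k, g,
                        utils::tail(sol$solution$traj$k, 1)))
  # multi-start layout: the natural decentralization seed at every cost
  # level (it reaches the high-peak coordinated optimum reliably), the
  # hold-at-threshold seed at the top of the scan (deep in the tracking
  # basin), and downward continuation to carry the tracking branch across
  # the scan; upward continuation fills high-peak candidates where the
  # cold start stalls
  prev <- NULL
  natural_alive <- TRUE  # stop cold high-peak starts past their fold
  for (j in seq_len(n_a)) {
    p <- with_a1(av[j])
    cand <- list()
    if (natural_alive) {
      s1 <- run_start(p, init = "decentralize")
      if (is.null(s1) || !s1$converged) natural_alive <- FALSE
      cand <- c(cand, list(s1))
    }
    if (j == n_a)
      cand <- c(cand, list(run_start(p, init = "decentralize_tracking")))
    if (!is.null(prev) && !any(vapply(cand, function(s)
          !is.null(s) && s$converged, TRUE))) {
      ca <- cont_args(prev, grid)
      cand <- c(cand, list(run_start(p, ca$init_eps, ca$k_init)))
    }
    cand <- Filter(Negate(is.null), cand)
    sols[[j]] <- cand
    keep <- Filter(function(s) s$converged, cand)
    if (length(keep) > 0)
      prev <- keep[[which.max(vapply(keep, function(s) s$V, 0))]]
  }
  # downward continuation pass (tracking branch); stops once the branch
  # fails to continue, i.e. below its fold
  nxt <- NULL
  for (j in rev(seq_len(n_a))) {
    p <- with_a1(av[j])
    if (j == n_a) {
      keep <- Filter(function(s) s$converged, sols[[j]])
      if (length(keep) > 0)
        nxt <- keep[[which.max(vapply(keep, function(s) s$V, 0))]]
    } else if (!is.null(nxt)) {
      ca <- cont_args(nxt, grid)
      s2 <- run_start(p, ca$init_eps, ca$k_init)
      if (!is.null(s2)) sols[[j]] <- c(sols[[j]], list(s2))
      # once the branch fails to continue it has hit its fold: stop
      nxt <- if (!is.null(s2) && s2$converged) s2 else NULL
    }
    if (length(sols[[j]]) == 0)
      warning(sprintf("no solution at alpha_g1 = %g", av[j]))
  }
  runs <- vector("list", n_a)
  rows <- vector("list", n_a)
  for (j in seq_len(n_a)) {
    distinct <- dedupe_optima(sols[[j]], distinct_tol)
    if (length(distinct) == 0) next
    if (length(distinct) > 2)
      warning(sprintf(
        "alpha_g1 = %g: %d distinct local optima found (expected at most 2)",
        av[j], length(distinct)))
    Vs <- vapply(distinct, function(s) s$V, 0)
    sel <- distinct[[which.max(Vs)]]
    runs[[j]] <- list(alpha_g1 = av[j], selected = sel,
                      all_local_optima = distinct)
    sm <- summarize_epidemic(sel$solution$traj, total_cost = -sel$V)
    rows[[j]] <- data.frame(alpha_g1 = av[j], peak_i = sm$peak_i,
                            total_cases = sm$total_cases,
                            duration = sm$duration, V = sel$V,
                            branch = sel$branch_label,
                            n_optima = length(distinct))
  }
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  sw <- NA_real_
  tracking <- tab$branch == "threshold-tracking"
  if (any(tracking) && !all(tracking)) sw <- min(tab$alpha_g1[tracking])
  list(runs = runs, table = tab, switch_alpha_g1 = sw)
}

dedupe_optima <- function(sol_list, distinct_tol) {
  out <- list()
  for (s in sol_list) {
    if (is.null(s) || !s$converged) next
    dup <- FALSE
    for (o in out) {
      n <- min(length(o$solution$traj$eps), length(s$solution$traj$eps))
      if (max(abs(o$solution$traj$eps[seq_len(n)] -
                    s$solution$traj$eps[seq_len(n)])) <= distinct_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) out <- c(out, list(s))
  }
  out
}
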