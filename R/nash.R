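#' Forward-backward sweep options
#'
#' @param relaxation Mixing weight `omega` in `(0, 1]` for plain damped
#'   steps (the warm-up iterations, and the fallback when an accelerated
#'   step is rejected by the safeguard).
#' @param tol Convergence tolerance on the sup-norm distance between the
#'   current control and the (clipped) candidate from the optimality rule.
#'   `NULL` means `1e-6 * kappa_star`, resolved by the solver.
#' @param max_iter Iteration cap.
#' @param adapt Use safeguarded Anderson acceleration over a short residual
#'   history (default); `FALSE` gives plain damped Picard iteration.
#' @param omega_max Cap for the adaptive damped step size.
#' @param accept_factor An accelerated step is kept only if it does not grow
#'   the residual by more than this factor (1 forces monotone residuals in
#'   the accelerated steps; the outer government sweep uses a strict value,
#'   the inner equilibrium sweeps a lenient one).
#' @param cooldown Number of plain damped iterations after a rejected
#'   accelerated step before acceleration is attempted again.
#' @param stall Abort (flagged, not silent) after this many iterations
#'   without at least a 10% improvement of the best residual; keeps
#'   genuinely stuck solves (e.g. past a fold of the equilibrium branch)
#'   from burning the full `max_iter`.
#' @param verbose Print the residual every `verbose` iterations (0 = silent).
#' @return An object of class `sweep_options`.
#' @export
sweep_options <- function(relaxation = 0.1, tol = NULL, max_iter = 20000,
                          adapt = TRUE, omega_max = 0.5, accept_factor = 3,
                          cooldown = 5, stall = 400, verbose = 0) {
  stopifnot(relaxation > 0, relaxation <= 1, max_iter >= 0,
            accept_factor > 0, cooldown >= 0, stall > 0)
  if (!is.null(tol)) stopifnot(tol > 0)
  structure(list(relaxation = relaxation, tol = tol, max_iter = max_iter,
                 adapt = adapt, omega_max = omega_max,
                 accept_factor = accept_factor,
                 cooldown = as.integer(cooldown),
                 stall = as.integer(stall),
                 verbose = as.integer(verbose)),
            class = "sweep_options")
}

costate_terminal <- function(grid, f, lnf, cost) {
  c(v_s = 0, v_i = -f^(-grid$tf) * infection_cost(0, cost) / (1 + lnf))
}

new_costates <- function(grid, v_s, v_i) {
  structure(list(grid = grid, v_s = v_s, v_i = v_i),
            class = "costate_trajectory")
}

#' @export
print.costate_trajectory <- function(x, ...) {
  cat(sprintf("<costate_trajectory> n = %d, v_s(0) = %.4g, v_i(0) = %.4g\n",
              x$grid$n, x$v_s[1], x$v_i[1]))
  invisible(x)
}

#' Individual costates along a trajectory
#'
#' Backward integration (same fixed-step RK4 scheme as the forward pass, run
#' in reverse) of the individual's value equations
#' `v_s' = (v_s - v_i) kappa i`, `v_i' = f^-t alpha(i) + v_i`
#' with terminal conditions `v_s(tf) = 0`,
#' `v_i(tf) = -f^-tf alpha(0) / (1 + log f)`. `v_s` and `v_i` are the
#' expected values of being susceptible/infectious. At equilibrium the
#' individual behaviour equals the population behaviour, so `kappa = traj$k`
#' and `i` is the population path.
#'
#' @param traj An `epi_trajectory` (carrying `i` and `k = kappa`).
#' @param up A [utility_params()] object.
#' @param kappa Optional individual behaviour path distinct from `traj$k`
#'   (used when verifying best responses).
#' @return A `costate_trajectory` with paths `v_s`, `v_i`.
#' @export
individual_costates <- function(traj, up, kappa = NULL) {
  stopifnot(inherits(traj, "epi_trajectory"), inherits(up, "utility_params"))
  g <- traj$grid
  if (is.null(kappa)) kappa <- traj$k
  if (length(kappa) != g$n) stop("kappa path does not match the grid")
  tc <- costate_terminal(g, up$f, up$lnf, up$cost)
  out <- cpp_costates_individual(traj$i, kappa, g$dt, g$t0, up$lnf,
                                 unclass(up$cost), tc[["v_s"]], tc[["v_i"]])
  new_costates(g, out$v_s, out$v_i)
}

#' Population (utilitarian) costates along a trajectory
#'
#' Backward integration of the Lagrange multipliers of the coordinated
#' population problem:
#' `v_s' = (v_s - v_i) k i`,
#' `v_i' = f^-t [alpha(i) + alpha'(i) i] + (v_s - v_i) k s + v_i`,
#' with the same terminal conditions as [individual_costates()]. Relative to
#' the individual's equations, `v_i'` gains the term `(v_s - v_i) k s`,
#' the cost of an infection causing further infections, which a
#' self-interested individual ignores.
#'
#' @inheritParams individual_costates
#' @return A `costate_trajectory`.
#' @export
population_costates <- function(traj, up) {
  stopifnot(inherits(traj, "epi_trajectory"), inherits(up, "utility_params"))
  g <- traj$grid
  tc <- costate_terminal(g, up$f, up$lnf, up$cost)
  out <- cpp_costates_population(traj$s, traj$i, traj$k, g$dt, g$t0, up$lnf,
                                 unclass(up$cost), tc[["v_s"]], tc[["v_i"]])
  new_costates(g, out$v_s, out$v_i)
}

# Pointwise optimality rule for the behaviour, clipped at kappa >= 0:
#   kappa = max(0, kappa* + (eps - f^t (v_s - v_i) s i) / (2 beta)).
# `s` is the susceptible probability of the optimising agent (the population
# s at equilibrium, psi_s for a defecting individual), `i` the population
# infection path.
control_rule <- function(s, i, v_s, v_i, eps, tgrid, up, kappa_star) {
  ft <- exp(tgrid * up$lnf)
  pmax(0, kappa_star + (eps - ft * (v_s - v_i) * s * i) / (2 * up$beta))
}

#' Candidate behaviour from the optimality rule
#'
#' Evaluates the stationarity condition of the individual Hamiltonian,
#' `kappa = max(0, kappa* - f^t/2 (v_s - v_i) s i + eps/2)` (for `beta = 1`),
#' pointwise along a trajectory. Clipping at the lower bound is applied
#' before any relaxation mixing, so sweep iterates stay feasible.
#'
#' @param traj An `epi_trajectory`.
#' @param costates A `costate_trajectory` on the same grid.
#' @param up A [utility_params()] object.
#' @param kappa_star Baseline infectiousness.
#' @return The candidate behaviour path (length `n`).
#' @export
control_update <- function(traj, costates, up, kappa_star) {
  stopifnot(inherits(traj, "epi_trajectory"),
            inherits(costates, "costate_trajectory"))
  if (!identical(traj$grid$n, costates$grid$n))
    stop("trajectory and costates are on different grids")
  control_rule(traj$s, traj$i, costates$v_s, costates$v_i, traj$eps,
               traj$grid$t, up, kappa_star)
}

new_solution <- function(traj, costates, objective, converged, iterations,
                         residual, kind) {
  structure(list(traj = traj, costates = costates, objective = objective,
                 converged = converged, iterations = iterations,
                 residual = residual, kind = kind),
            class = "ctrl_solution")
}

#' @export
print.ctrl_solution <- function(x, ...) {
  cat(sprintf("<ctrl_solution: %s> %s in %d iterations (residual %.3g)\n",
              x$kind, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat(sprintf("  objective = %.8g, peak i = %.4g, s(tf) = %.4g\n",
              x$objective, max(x$traj$i), x$traj$s[x$traj$grid$n]))
  invisible(x)
}

# Core damped fixed-point loop shared by the Nash and utilitarian solvers
# and by the individual best-response solver. `forward` maps a control path
# to a trajectory-like list, `backward` maps it to costates, `candidate`
# applies the optimality rule.
# Safeguarded Anderson-accelerated fixed-point driver used by every sweep
# (inner Nash, utilitarian, best response, and the outer government loop).
# `map` takes the current iterate and returns list(cand = <clipped candidate
# from the optimality rule>, payload = <anything the caller wants back>).
#
# Plain damped Picard iteration can stall (or diverge) when the sweep map
# has eigenvalues near or beyond the unit circle, which happens near the
# point where the incentivised equilibrium becomes non-unique. Anderson
# mixing over a short residual history handles those modes; a safeguard
# rejects accelerated steps whose residual blows up (falling back to a
# damped step and clearing the history), and `lower` keeps iterates
# feasible (kappa >= 0) at all times.
fixed_point_solve <- function(x0, map, opts, tol, lower = NULL,
                              memory = 5L, on_accept = NULL) {
  clamp <- function(z) {
    z <- as.numeric(z)
    if (is.null(lower)) z else pmax(z, lower)
  }
  x <- clamp(x0)
  m <- map(x)
  if (isTRUE(m$reject))
    stop("fixed-point map rejected the starting iterate")
  if (!is.null(on_accept)) on_accept(m)
  f <- m$cand - x
  resid <- max(abs(f))
  omega <- opts$relaxation
  accept <- opts$accept_factor
  n <- length(x)
  Xd <- matrix(0, n, 0)  # iterate differences
  Fd <- matrix(0, n, 0)  # residual differences
  aa_block <- 0L         # iterations left with acceleration disabled
  improved <- 0L         # consecutive damped steps that reduced the residual
  rises <- 0L            # consecutive damped steps that increased it
  best_resid <- resid
  since_improve <- 0L
  iter <- 0L
  while (resid >= tol && iter < opts$max_iter) {
    if (opts$verbose > 0 && iter %% opts$verbose == 0)
      message(sprintf("  sweep iter %5d: residual %.3e (memory %d, omega %.3g)",
                      iter, resid, ncol(Xd), omega))
    if (since_improve > opts$stall) break  # stagnating: give up early
    accel <- FALSE
    tries <- 0L
    om_try <- omega
    repeat {
      x_new <- NULL
      if (tries == 0L && opts$adapt && aa_block == 0L && ncol(Xd) > 0) {
        theta <- tryCatch(qr.solve(Fd, f), error = function(e) NULL)
        if (!is.null(theta) && all(is.finite(theta)) &&
            sum(abs(theta)) < 1e4) {
          x_new <- clamp(x + f - (Xd + Fd) %*% theta)
          accel <- TRUE
        }
      }
      if (is.null(x_new)) x_new <- clamp(x + om_try * f)
      m_new <- map(x_new)
      bad <- isTRUE(m_new$reject)
      if (!bad) {
        f_new <- m_new$cand - x_new
        r_new <- max(abs(f_new))
        bad <- !is.finite(r_new) || (accel && r_new > accept * resid)
      }
      if (!bad) break
      # step rejected: drop the acceleration history and back off
      if (accel) {
        Xd <- matrix(0, n, 0)
        Fd <- matrix(0, n, 0)
        aa_block <- opts$cooldown
        accel <- FALSE
        if (opts$verbose > 0)
          message("  accelerated step rejected; trying damped step")
      } else {
        om_try <- om_try / 2
        omega <- max(om_try, 1e-4)
      }
      tries <- tries + 1L
      if (tries > 10L)
        stop("fixed-point iteration cannot advance: every step was rejected")
    }
    if (aa_block > 0L && !accel) aa_block <- aa_block - 1L
    if (!accel) {
      # adapt the damped step size toward the stability edge; brief rises
      # are normal transients, so damping waits for a sustained rise
      if (r_new < resid) {
        improved <- improved + 1L
        rises <- 0L
        if (improved >= 10L && omega < opts$omega_max) {
          omega <- min(opts$omega_max, omega * 1.25)
          improved <- 0L
        }
      } else {
        improved <- 0L
        rises <- rises + 1L
        if (rises >= 3L && omega > 1e-3) {
          omega <- omega / 2
          rises <- 0L
        }
      }
    }
    if (r_new < 0.9 * best_resid) {
      best_resid <- r_new
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    Xd <- cbind(Xd, x_new - x)
    Fd <- cbind(Fd, f_new - f)
    if (ncol(Xd) > memory) {
      Xd <- Xd[, -1, drop = FALSE]
      Fd <- Fd[, -1, drop = FALSE]
    }
    if (!is.null(on_accept)) on_accept(m_new)
    x <- x_new; f <- f_new; resid <- r_new; m <- m_new
    iter <- iter + 1L
  }
  list(x = x, payload = m$payload, cand = m$cand, iterations = iter,
       residual = resid, converged = resid < tol)
}

# Plain (unrestarted) GMRES with a matrix-free operator; used by the
# Newton fallback below. Solves A d = b approximately.
gmres_solve <- function(Aop, b, m = 30L, rtol = 0.1) {
  n <- length(b)
  beta <- sqrt(sum(b^2))
  if (beta == 0) return(rep(0, n))
  V <- matrix(0, n, m + 1)
  H <- matrix(0, m + 1, m)
  V[, 1] <- b / beta
  y <- 0
  jmax <- 0L
  for (j in seq_len(m)) {
    w <- Aop(V[, j])
    for (i in seq_len(j)) {
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1, j] <- sqrt(sum(w^2))
    e1 <- c(beta, rep(0, j))
    Hj <- H[seq_len(j + 1), seq_len(j), drop = FALSE]
    y <- tryCatch(qr.solve(Hj, e1), error = function(e) NULL)
    jmax <- j
    if (is.null(y)) { jmax <- j - 1L; break }
    res <- sqrt(sum((e1 - Hj %*% y)^2))
    if (H[j + 1, j] < 1e-14 || res < rtol * beta) break
    V[, j + 1] <- w / H[j + 1, j]
  }
  if (jmax == 0L || is.null(y)) return(b)  # fall back to the residual itself
  as.numeric(V[, seq_len(jmax), drop = FALSE] %*% y)
}

# Jacobian-free Newton-Krylov polish for a fixed point x = G(x): solves
# (I - G'(x)) d = G(x) - x with matrix-free GMRES on finite-difference
# directional derivatives, with a residual-decrease line search. Used when
# the accelerated sweep stalls, which happens close to a fold of the
# equilibrium branch where the sweep map's Jacobian has an eigenvalue
# near +1 (Picard/Anderson lose their grip there, Newton does not).
newton_polish <- function(x0, map, tol, lower = NULL, max_newton = 30L,
                          gmres_m = 30L, fd_h = 1e-7, max_step = Inf,
                          nfev_cap = Inf, on_accept = NULL,
                          verbose = FALSE) {
  clamp <- function(z) {
    z <- as.numeric(z)
    if (is.null(lower)) z else pmax(z, lower)
  }
  x <- clamp(x0)
  m <- map(x)
  if (isTRUE(m$reject))
    return(list(x = x, payload = NULL, cand = NULL, residual = Inf,
                converged = FALSE, nfev = 1L))
  if (!is.null(on_accept)) on_accept(m)
  Fx <- m$cand - x
  r <- max(abs(Fx))
  nfev <- 1L
  for (it in seq_len(max_newton)) {
    if (verbose)
      message(sprintf("  newton iter %3d: residual %.3e (%d map evals)",
                      it, r, nfev))
    if (r < tol || nfev >= nfev_cap) break
    scale_x <- 1 + sqrt(sum(x^2))
    Aop <- function(v) {
      nv <- sqrt(sum(v^2))
      h <- fd_h * scale_x / nv
      mp <- map(clamp(x + h * v))
      nfev <<- nfev + 1L
      if (isTRUE(mp$reject)) return(v)  # act like identity where unprobeable
      Fv <- (mp$cand - (x + h * v) - Fx) / h
      v - (Fv + v)  # A v = (I - J) v with J v = Fv + v
    }
    d <- gmres_solve(Aop, Fx, m = gmres_m)
    # trust region: an ill-conditioned Krylov solve can return a huge step,
    # and near a fold an unbounded step can hop to a different equilibrium
    # branch; `max_step` keeps the iteration local to the tracked branch
    dmax <- max(abs(d))
    cap <- min(8 * max(1, r), max_step)
    if (dmax > cap) d <- d * (cap / dmax)
    step <- 1
    ok <- FALSE
    best <- list(rn = r)
    while (step >= 2^-12) {
      xn_try <- clamp(x + step * d)
      mn_try <- map(xn_try)
      nfev <- nfev + 1L
      if (!isTRUE(mn_try$reject)) {
        Fn_try <- mn_try$cand - xn_try
        rn_try <- max(abs(Fn_try))
        if (is.finite(rn_try) && rn_try < best$rn) {
          best <- list(rn = rn_try, xn = xn_try, mn = mn_try, Fn = Fn_try)
          ok <- TRUE
          # quadratic-basin steps get accepted immediately; otherwise probe
          # a couple more step sizes and keep the best
          if (rn_try < 0.5 * r) break
        } else if (ok) break  # past the sweet spot: stop probing
      }
      step <- step / 2
    }
    if (!ok) break  # no descent direction: give up, stay at best point
    xn <- best$xn; mn <- best$mn; Fn <- best$Fn; rn <- best$rn
    if (!is.null(on_accept)) on_accept(mn)
    x <- xn; Fx <- Fn; r <- rn; m <- mn
  }
  list(x = x, payload = m$payload, cand = m$cand, residual = r,
       converged = r < tol, nfev = nfev)
}

sweep_loop <- function(k0, forward, backward, candidate, opts, tol,
                       step_cap = Inf, method = "auto") {
  map <- function(k) {
    traj <- forward(k)
    cost <- backward(traj)
    list(cand = candidate(traj, cost),
         payload = list(traj = traj, costates = cost))
  }
  if (method == "newton") {
    # straight Newton-Krylov from the supplied start; used when a good
    # warm start exists but the sweep map itself is expansive (stiff
    # threshold costs make the coordinated problem behave this way)
    res <- newton_polish(k0, map, tol, lower = 0, max_newton = 60L,
                         gmres_m = 80L, fd_h = 1e-8, max_step = step_cap)
    return(list(k = res$x, traj = res$payload$traj,
                costates = res$payload$costates, iterations = res$nfev,
                residual = res$residual, converged = res$converged))
  }
  res <- fixed_point_solve(k0, map, opts, tol, lower = 0)
  iters <- res$iterations
  if (!res$converged) {
    np <- newton_polish(res$x, map, tol, lower = 0, max_step = step_cap)
    iters <- iters + np$nfev
    if (!is.null(np$payload)) res <- np
  }
  list(k = res$x, traj = res$payload$traj, costates = res$payload$costates,
       iterations = iters, residual = res$residual,
       converged = res$converged)
}

resolve_tol <- function(opts, kappa_star) {
  if (is.null(opts$tol)) 1e-6 * kappa_star else opts$tol
}

# Extend the horizon by 50% (same dt) until the terminal infected fraction
# is below `itol`, re-solving warm-started each time.
extend_until_quiet <- function(solve_once, grid, k, eps, itol = 1e-8,
                               max_extend = 4) {
  sol <- solve_once(grid, k, eps)
  rounds <- 0
  while (sol$traj$i[sol$traj$grid$n] > itol && rounds < max_extend) {
    g <- sol$traj$grid
    n_new <- as.integer(round((g$tf * 1.5 - g$t0) / g$dt)) + 1L
    if (n_new %% 2L == 0L) n_new <- n_new + 1L
    grid <- time_grid(tf = g$t0 + (n_new - 1L) * g$dt, n = n_new, t0 = g$t0)
    pad <- grid$n - g$n
    k <- c(sol$traj$k, rep(sol$traj$k[g$n], pad))
    eps <- c(sol$traj$eps, rep(0, pad))
    sol <- solve_once(grid, k, eps)
    rounds <- rounds + 1
  }
  if (sol$traj$i[sol$traj$grid$n] > itol)
    warning("terminal infected fraction still above 1e-8 after extensions")
  sol
}

#' Nash equilibrium behaviour via forward-backward sweep
#'
#' Computes the mean-field Nash equilibrium of rational social distancing
#' against an exogenous government intervention path. Starting from the
#' disease-free equilibrium `k = kappa*`, each iteration integrates the SIR
#' states forward under the current behaviour, the individual costates
#' backward, evaluates the optimality rule, and mixes the clipped candidate
#' into the current behaviour with a damped relaxation. At the fixed point
#' the individual best response reproduces the population behaviour
#' (`psi_s = s`, `psi_i = i`), i.e. no individual can profitably defect.
#'
#' @param params A [model_params()] bundle.
#' @param grid A [time_grid()].
#' @param eps Intervention path (single number or length-`n`), default 0.
#' @param opts A [sweep_options()] object.
#' @param k_init Optional warm-start behaviour path.
#' @param extend If `TRUE`, extend the horizon by 50% (same step) and
#'   re-solve while the terminal infected fraction exceeds 1e-8, so the
#'   salvage approximation stays accurate.
#' @param method `"auto"` runs the damped/accelerated sweep with a
#'   Newton-Krylov fallback; `"newton"` goes straight to Newton-Krylov from
#'   `k_init` (for warm starts near stiff threshold optima).
#' @return A `ctrl_solution` with the equilibrium trajectory, costates,
#'   utility, and a convergence report. Non-convergence at `max_iter` is
#'   flagged (`converged = FALSE`) with a warning, never silent.
#' @export
solve_nash <- function(params, grid = time_grid(), eps = NULL,
                       opts = sweep_options(), k_init = NULL, extend = TRUE,
                       method = c("auto", "newton")) {
  solve_behaviour(params, grid, eps, opts, k_init, extend, nash = TRUE,
                  method = match.arg(method))
}

solve_behaviour <- function(params, grid, eps, opts, k_init, extend, nash,
                            method = "auto") {
  stopifnot(inherits(params, "model_params"), inherits(grid, "time_grid"))
  ep <- params$epidemic
  up <- params$utility
  tol <- resolve_tol(opts, ep$kappa_star)
  eps <- expand_path(if (is.null(eps)) 0 else eps, grid, "eps")
  k0 <- if (is.null(k_init)) rep(ep$kappa_star, grid$n)
        else expand_path(k_init, grid, "k_init")
  backward <- if (nash) function(traj) individual_costates(traj, up)
              else function(traj) population_costates(traj, up)
  solve_with <- function(mth) function(g, k, e) {
    sweep_loop(
      k0 = k,
      forward = function(kk) integrate_sir(kk, ep, g, e),
      backward = backward,
      candidate = function(traj, cost)
        control_update(traj, cost, up, ep$kappa_star),
      opts = opts, tol = tol, step_cap = 0.3 * ep$kappa_star,
      method = mth)
  }
  solve_once <- solve_with(method)
  res <- if (extend) extend_until_quiet(solve_once, grid, k0, eps)
         else solve_once(grid, k0, eps)
  if (!res$converged && !nash && !up$cost$constant && is.null(k_init) &&
      method == "auto") {
    # the coordinated problem under a sharp threshold cost has a stiff,
    # sometimes expansive sweep map; re-seed it from a coarse direct
    # transcription and finish with Newton
    tr_grid <- time_grid(tf = grid$tf, n = 1001, t0 = grid$t0)
    tr <- direct_transcription("population", params, tr_grid, n_nodes = 61,
                               fixed = list(eps = stats::approx(
                                 grid$t, eps, xout = tr_grid$t)$y),
                               restarts = 0, maxit = 150, factr = 1e6)
    k_tr <- pmax(stats::approx(tr_grid$t, tr$control_fine, xout = grid$t,
                               rule = 2)$y, 0)
    newton_once <- solve_with("newton")
    res2 <- if (extend) extend_until_quiet(newton_once, grid, k_tr, eps)
            else newton_once(grid, k_tr, eps)
    if (res2$converged || res2$residual < res$residual) res <- res2
  }
  if (!res$converged)
    warning(sprintf("sweep did not converge: residual %.3e after %d iterations",
                    res$residual, res$iterations))
  obj <- evaluate_objective(res$traj, if (nash) "individual" else "population",
                            params)
  new_solution(res$traj, res$costates, obj, res$converged, res$iterations,
               res$residual, if (nash) "nash" else "utilitarian")
}

#' Individual best response to a fixed population behaviour
#'
#' Solves the representative individual's optimal-control problem against a
#' frozen population trajectory (generated by `k`): the individual's
#' compartment probabilities `psi_s, psi_i` evolve against the population
#' infection path, and the individual's behaviour `kappa` is optimised by its
#' own forward-backward sweep. Used to verify the Nash fixed-point property
#' and to quantify the profitability of defection from non-equilibrium
#' strategies.
#'
#' @param k Population behaviour path (single number or length-`n`).
#' @param params A [model_params()] bundle.
#' @param grid A [time_grid()].
#' @param eps Intervention path, default 0.
#' @param opts A [sweep_options()] object.
#' @return A list with the optimal `kappa` path, the individual's state paths
#'   `psi_s`, `psi_i`, its costates, its utility `objective`, the utility
#'   `objective_conform` of adopting the population behaviour instead, and a
#'   convergence report.
#' @export
best_response <- function(k, params, grid = time_grid(), eps = NULL,
                          opts = sweep_options()) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "time_grid"))
  ep <- params$epidemic
  up <- params$utility
  tol <- resolve_tol(opts, ep$kappa_star)
  eps <- expand_path(if (is.null(eps)) 0 else eps, grid, "eps")
  k <- expand_path(k, grid, "k")
  pop <- integrate_sir(k, ep, grid, eps)
  tc <- costate_terminal(grid, up$f, up$lnf, up$cost)
  forward <- function(kap) {
    out <- cpp_psi_rk4(ep$s0, ep$i0, kap, pop$i, grid$dt)
    check_clamp(out, grid)
    list(grid = grid, psi_s = out$s, psi_i = out$i, k = kap, eps = eps)
  }
  backward <- function(st) {
    out <- cpp_costates_individual(pop$i, st$k, grid$dt, grid$t0, up$lnf,
                                   unclass(up$cost), tc[["v_s"]], tc[["v_i"]])
    new_costates(grid, out$v_s, out$v_i)
  }
  candidate <- function(st, cost)
    control_rule(st$psi_s, pop$i, cost$v_s, cost$v_i, eps, grid$t, up,
                 ep$kappa_star)
  res <- sweep_loop(k, forward, backward, candidate, opts, tol,
                    step_cap = 0.3 * ep$kappa_star)
  if (!res$converged)
    warning(sprintf("best-response sweep did not converge (residual %.3e)",
                    res$residual))
  obj <- individual_objective_psi(res$traj$psi_s, res$traj$psi_i, res$k,
                                  pop$i, eps, grid, up, ep$kappa_star)
  conform <- individual_objective_psi(pop$s, pop$i, k, pop$i, eps, grid, up,
                                      ep$kappa_star)
  list(kappa = res$k, psi_s = res$traj$psi_s, psi_i = res$traj$psi_i,
       costates = res$costates, objective = obj, objective_conform = conform,
       converged = res$converged, iterations = res$iterations,
       residual = res$residual)
}
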