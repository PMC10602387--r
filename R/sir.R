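#' Integrate the SIR model under a prescribed behaviour path
#'
#' Solves the rescaled SIR equations
#' `s' = -k s i`, `i' = k s i - i` (recovery rate 1; the recovered
#' fraction, 1 - s - i, is implicit) with a time-varying population behaviour
#' `k(t)` tabulated on the grid, using a fixed-step classical 4th-order
#' Runge-Kutta scheme. The fixed step makes results bit-reproducible for
#' identical inputs and keeps the forward and backward passes of the
#' forward-backward sweep on matching grids.
#'
#' @param k Behaviour (infectiousness) path: either a single non-negative
#'   number or a vector of length `grid$n`.
#' @param params An [epidemic_params()] object.
#' @param grid A [time_grid()].
#' @param eps Optional government intervention path carried along in the
#'   trajectory (single number or length-`n` vector); defaults to 0.
#' @return An object of class `epi_trajectory`: list with `grid` and the
#'   node paths `s`, `i`, `k`, `eps`.
#' @examples
#' tr <- integrate_sir(4, epidemic_params(), time_grid(tf = 60, n = 2401))
#' max(tr$i)
#' @export
integrate_sir <- function(k, params, grid, eps = 0) {
  stopifnot(inherits(params, "epidemic_params"), inherits(grid, "time_grid"))
  k <- expand_path(k, grid, "k")
  eps <- expand_path(eps, grid, "eps")
  if (anyNA(k)) stop("k contains NA/NaN")
  if (any(k < 0)) stop("k must be non-negative everywhere")
  out <- cpp_sir_rk4(params$s0, params$i0, k, grid$dt)
  check_clamp(out, grid)
  new_trajectory(grid, out$s, out$i, k, eps)
}

expand_path <- function(x, grid, name) {
  if (is.null(x)) x <- 0
  stopifnot(is.numeric(x))
  if (length(x) == 1L) x <- rep(as.numeric(x), grid$n)
  if (length(x) != grid$n)
    stop(sprintf("path '%s' has length %d; grid has %d nodes",
                 name, length(x), grid$n))
  as.numeric(x)
}

check_clamp <- function(out, grid) {
  if (out$worst < -1e-12)
    stop(sprintf("integration undershoot %.3e below -1e-12; refine the grid",
                 out$worst))
  if (out$nclamp > 0)
    warning(sprintf("%d negative undershoots (worst %.3e) clamped to 0",
                    out$nclamp, out$worst))
  invisible(out)
}

new_trajectory <- function(grid, s, i, k, eps) {
  structure(list(grid = grid, s = s, i = i, k = k, eps = eps),
            class = "epi_trajectory")
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("<epi_trajectory> n = %d nodes on [%g, %g]\n",
              x$grid$n, x$grid$t0, x$grid$tf))
  cat(sprintf("  peak i = %.4g, s(tf) = %.4g, k range [%.3g, %.3g]\n",
              max(x$i), x$s[x$grid$n], min(x$k), max(x$k)))
  invisible(x)
}

#' @export
as.data.frame.epi_trajectory <- function(x, ...) {
  data.frame(t = x$grid$t, s = x$s, i = x$i, k = x$k, eps = x$eps)
}

# Parabolic refinement of a grid-sampled maximum: fits a quadratic through
# the argmax node and its neighbours so the reported peak does not jitter
# with the node placement.
grid_peak <- function(y) {
  j <- which.max(y)
  n <- length(y)
  if (j == 1 || j == n) return(y[j])
  a <- y[j - 1]; b <- y[j]; c <- y[j + 1]
  den <- a - 2 * b + c
  if (den >= 0) return(b)  # flat or non-concave: keep the node value
  b - (a - c)^2 / (8 * den)
}

#' Summary metrics of an epidemic trajectory
#'
#' Computes the peak infected fraction, total cases `1 - s(tf)`, final
#' susceptible fraction, and epidemic duration, defined as the measure of the
#' set of times at which the infected fraction exceeds `threshold`
#' (sum of `dt` over nodes with `i > threshold`).
#'
#' @param traj An `epi_trajectory`.
#' @param total_cost Total cost of the epidemic (`-U`, `-U_p` or `-V`
#'   depending on context) to carry through into the summary; `NA` if not
#'   relevant.
#' @param threshold Duration threshold on `i`; defaults to `1e-4`.
#' @return An object of class `epidemic_summary` with fields `peak_i`,
#'   `total_cases`, `s_inf`, `duration`, `total_cost`. The peak is refined
#'   by a local quadratic fit around the argmax node so it does not jitter
#'   with node placement.
#' @export
summarize_epidemic <- function(traj, total_cost = NA_real_, threshold = 1e-4) {
  stopifnot(inherits(traj, "epi_trajectory"))
  structure(list(peak_i = grid_peak(traj$i),
                 total_cases = 1 - traj$s[traj$grid$n],
                 s_inf = traj$s[traj$grid$n],
                 duration = sum(traj$i > threshold) * traj$grid$dt,
                 total_cost = as.numeric(total_cost)),
            class = "epidemic_summary")
}

#' @export
print.epidemic_summary <- function(x, ...) {
  cat("<epidemic_summary>\n")
  cat(sprintf("  peak_i      = %.6g\n", x$peak_i))
  cat(sprintf("  total_cases = %.6g\n", x$total_cases))
  cat(sprintf("  s_inf       = %.6g\n", x$s_inf))
  cat(sprintf("  duration    = %.6g\n", x$duration))
  cat(sprintf("  total_cost  = %.6g\n", x$total_cost))
  invisible(x)
}

#' Final epidemic size for constant behaviour
#'
#' Root of the final-size relation `s_inf = s0 * exp(-R0 * (s0 + i0 - s_inf))`
#' for an SIR epidemic run at constant reproduction number `R0`, found by
#' bracketed root-finding to `1e-12` tolerance. Serves as an analytic check
#' on long constant-behaviour integrations.
#'
#' @param R0 Reproduction number (constant `k`), positive.
#' @param s0,i0 Initial susceptible and infected fractions.
#' @return The final susceptible fraction `s_inf` in `(0, s0]`.
#' @examples
#' final_size_root(4, 1 - 3e-8, 3e-8)
#' @export
final_size_root <- function(R0, s0 = 1 - 3e-8, i0 = 3e-8) {
  stopifnot(R0 > 0, s0 > 0, i0 >= 0, s0 + i0 <= 1)
  g <- function(s) s - s0 * exp(-R0 * (s0 + i0 - s))
  lo <- 1e-300
  hi <- s0
  if (g(hi) <= 0) return(s0)  # subcritical: no epidemic, root at s0
  if (g(lo) >= 0) stop("no sign change in bracket for final-size relation")
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}
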