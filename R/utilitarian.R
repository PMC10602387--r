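#' Utilitarian (fully coordinated) optimum
#'
#' Maximises the aggregate population utility `U_p` under full coordination,
#' i.e. the behaviour a benevolent planner with the population's own
#' preferences would prescribe. Same forward-backward sweep as
#' [solve_nash()], but with the population costates ([population_costates()]),
#' whose `v_i` equation carries the extra term `(v_s - v_i) k s` accounting
#' for onward transmission. The optimality rule for the control is identical
#' to the Nash rule, so the two solutions differ only through the costates.
#' The utilitarian optimum weakly dominates the Nash equilibrium in utility
#' but is susceptible to defection by individuals.
#'
#' @inheritParams solve_nash
#' @return A `ctrl_solution` (kind `"utilitarian"`).
#' @export
solve_utilitarian <- function(params, grid = time_grid(), eps = NULL,
                              opts = sweep_options(), k_init = NULL,
                              extend = TRUE,
                              method = c("auto", "newton")) {
  solve_behaviour(params, grid, eps, opts, k_init, extend, nash = FALSE,
                  method = match.arg(method))
}
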