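#' Read and validate a scenario configuration
#'
#' Scenario files are YAML (or JSON) with sections `epidemic`, `utility`,
#' optional `government`, `grid`, `sweep` / `sweep_outer`, a `mode`
#' (`baseline`, `nash`, `utilitarian`, `government`, or `scan`), an optional
#' `scan` block (`parameter`, `values`) and an optional `seed`. Unknown or
#' missing required keys produce a schema error listing the offending keys.
#'
#' @param path Path to a YAML/JSON scenario file.
#' @return A validated `scenario_config` object.
#' @seealso [scenario_preset()] for the bundled presets.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_scenario(raw, path)
}

#' Bundled scenario presets
#'
#' @param name Preset name; `NULL` lists available presets.
#' @return A `scenario_config` (or a character vector of names).
#' @export
scenario_preset <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "epictrl")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(avail, collapse = ", ")))
  read_scenario(file.path(dir, paste0(name, ".yaml")))
}

validate_scenario <- function(raw, path = "<config>") {
  problems <- character(0)
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  modes <- c("baseline", "nash", "utilitarian", "government", "scan")
  mode <- raw$mode %||% NA_character_
  need(is.character(mode) && mode %in% modes,
       sprintf("mode: must be one of %s", paste(modes, collapse = "|")))
  need(!is.null(raw$epidemic), "epidemic: section missing")
  need(!is.null(raw$utility), "utility: section missing")
  if (identical(mode, "government") || identical(mode, "scan"))
    need(!is.null(raw$government), "government: section required for this mode")
  if (identical(mode, "scan")) {
    need(!is.null(raw$scan$parameter), "scan.parameter: missing")
    need(!is.null(raw$scan$values), "scan.values: missing")
  }
  if (length(problems) > 0)
    stop(sprintf("invalid scenario '%s':\n  %s", path,
                 paste(problems, collapse = "\n  ")))
  cost_from <- function(x, what) {
    if (is.null(x)) stop(sprintf("%s.cost missing", what))
    if (isTRUE(x$constant)) constant_cost(x$alpha0 %||% x$alpha)
    else infection_cost_params(alpha0 = x$alpha0, alpha1 = x$alpha1,
                               i_hc = x$i_hc, sigma = x$sigma %||% 300)
  }
  ep <- epidemic_params(kappa_star = raw$epidemic$kappa_star %||% 4,
                        i0 = raw$epidemic$i0 %||% 3e-8)
  up <- utility_params(f = raw$utility$f %||% 1,
                       beta = raw$utility$beta %||% 1,
                       cost = cost_from(raw$utility$cost, "utility"))
  gp <- NULL
  if (!is.null(raw$government))
    gp <- government_params(f_g = raw$government$f_g %||% 1,
                            beta_g = raw$government$beta_g %||% 1,
                            gamma_g = raw$government$gamma_g %||% 0,
                            cost_g = cost_from(raw$government$cost,
                                               "government"))
  grid <- time_grid(tf = raw$grid$tf %||% 100, n = raw$grid$n %||% 5001)
  sw <- function(x, relax) {
    x <- x %||% list()
    sweep_options(relaxation = x$relaxation %||% relax,
                  tol = x$tol,
                  max_iter = x$max_iter %||% 20000,
                  verbose = x$verbose %||% 0)
  }
  structure(list(name = raw$name %||% "scenario", mode = mode,
                 params = model_params(ep, up, gp), grid = grid,
                 sweep = sw(raw$sweep, 0.1),
                 sweep_outer = sw(raw$sweep_outer, 0.05),
                 scan = raw$scan, seed = as.integer(raw$seed %||% 1L)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s', mode = %s\n", x$name, x$mode))
  print(x$params)
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Full-double-precision CSV with header `t,s,i,k,eps` plus costate columns
#' (`v_s,v_i` and `lambda_s,lambda_i`) when supplied.
#'
#' @param traj An `epi_trajectory`.
#' @param path Output file.
#' @param costates,gov_costates Optional costate objects on the same grid.
#' @return `path`, invisibly (writer); an `epi_trajectory` with any costate
#'   columns attached as attributes (reader).
#' @export
write_trajectory <- function(traj, path, costates = NULL,
                             gov_costates = NULL) {
  df <- as.data.frame(traj)
  if (!is.null(costates)) {
    df$v_s <- costates$v_s
    df$v_i <- costates$v_i
  }
  if (!is.null(gov_costates)) {
    df$lambda_s <- gov_costates$lambda_s
    df$lambda_i <- gov_costates$lambda_i
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  n <- nrow(df)
  grid <- time_grid(tf = df$t[n], n = n, t0 = df$t[1])
  traj <- new_trajectory(grid, df$s, df$i, df$k, df$eps)
  for (col in c("v_s", "v_i", "lambda_s", "lambda_i"))
    if (!is.null(df[[col]])) attr(traj, col) <- df[[col]]
  traj
}

write_summary_json <- function(summary, path, extra = list()) {
  x <- c(unclass(summary), extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a scenario and write its outputs
#'
#' Dispatches on the config's `mode`, runs the relevant solver, and writes a
#' trajectory CSV, a summary JSON (keys `peak_i`, `total_cases`, `s_inf`,
#' `duration`, `total_cost`) and a convergence report into `out_dir`.
#' Scan mode writes a `scan.csv` table instead of a single trajectory.
#' Outputs are deterministic given the config (including its seed).
#'
#' @param cfg A `scenario_config` (from [read_scenario()] or
#'   [scenario_preset()]).
#' @param out_dir Output directory (created if needed).
#' @return The summary (or scan table), invisibly.
#' @export
run_scenario <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  conv <- function(sol)
    list(converged = sol$converged, iterations = sol$iterations,
         residual = sol$residual)
  if (cfg$mode == "baseline") {
    traj <- integrate_sir(p$epidemic$kappa_star, p$epidemic, cfg$grid)
    obj <- evaluate_objective(traj, "individual", p)
    sm <- summarize_epidemic(traj, total_cost = -obj)
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    write_summary_json(sm, file.path(out_dir, "summary.json"),
                       list(mode = "baseline", objective = obj))
    return(invisible(sm))
  }
  if (cfg$mode %in% c("nash", "utilitarian")) {
    solver <- if (cfg$mode == "nash") solve_nash else solve_utilitarian
    sol <- solver(p, cfg$grid, opts = cfg$sweep)
    sm <- summarize_epidemic(sol$traj, total_cost = -sol$objective)
    write_trajectory(sol$traj, file.path(out_dir, "trajectory.csv"),
                     costates = sol$costates)
    write_summary_json(sm, file.path(out_dir, "summary.json"),
                       list(mode = cfg$mode, objective = sol$objective))
    jsonlite::write_json(conv(sol), file.path(out_dir, "convergence.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(sm))
  }
  if (cfg$mode == "government") {
    sol <- solve_government(p, cfg$grid, cfg$sweep, cfg$sweep_outer)
    sm <- summarize_epidemic(sol$solution$traj, total_cost = -sol$V)
    write_trajectory(sol$solution$traj,
                     file.path(out_dir, "trajectory.csv"),
                     costates = sol$inner_costates,
                     gov_costates = sol$gov_costates)
    write_summary_json(sm, file.path(out_dir, "summary.json"),
                       list(mode = "government", objective = sol$V,
                            branch_label = sol$branch_label))
    jsonlite::write_json(conv(sol), file.path(out_dir, "convergence.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(sm))
  }
  # scan mode
  par <- cfg$scan$parameter
  vals <- as.numeric(unlist(cfg$scan$values))
  if (identical(par, "alpha_g1")) {
    sc <- branch_scan(p, vals, cfg$grid, cfg$sweep, cfg$sweep_outer)
    utils::write.csv(sc$table, file.path(out_dir, "scan.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(switch_alpha_g1 = sc$switch_alpha_g1),
                         file.path(out_dir, "scan.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(sc$table))
  }
  if (identical(par, "alpha1")) {
    rows <- lapply(vals, function(a1) {
      q <- p
      q$utility$cost$alpha1 <- a1
      q$utility$cost$constant <- FALSE
      sol <- solve_nash(q, cfg$grid, opts = cfg$sweep)
      sm <- summarize_epidemic(sol$traj, total_cost = -sol$objective)
      data.frame(alpha1 = a1, peak_i = sm$peak_i,
                 total_cases = sm$total_cases, duration = sm$duration,
                 U = sol$objective, converged = sol$converged)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "scan.csv"), row.names = FALSE)
    return(invisible(tab))
  }
  stop(sprintf("scan.parameter: unsupported parameter '%s'", par))
}

#' Collate completed runs into tidy per-panel tables
#'
#' Reshapes the on-disk outputs of [run_scenario()] into analysis-ready
#' tables: a long trajectory table (`scenario, t, s, i, k, eps`) and a
#' summary table (one row per scenario). Scan outputs are passed through
#' with their scenario label attached. Missing runs are reported.
#'
#' @param outdirs Named character vector of run output directories; names
#'   label the scenarios.
#' @return A list with `trajectories`, `summaries`, and `scans` data frames
#'   (the latter possibly empty).
#' @export
make_figure_tables <- function(outdirs) {
  if (is.null(names(outdirs)) || any(names(outdirs) == ""))
    names(outdirs) <- basename(outdirs)
  missing <- outdirs[!file.exists(file.path(outdirs, "summary.json")) &
                       !file.exists(file.path(outdirs, "scan.csv"))]
  if (length(missing) > 0)
    stop(sprintf("missing runs: %s", paste(names(missing), collapse = ", ")))
  trajs <- list(); sums <- list(); scans <- list()
  for (nm in names(outdirs)) {
    d <- outdirs[[nm]]
    tp <- file.path(d, "trajectory.csv")
    if (file.exists(tp)) {
      df <- utils::read.csv(tp)
      df <- df[, intersect(c("t", "s", "i", "k", "eps"), names(df))]
      trajs[[nm]] <- cbind(scenario = nm, df)
    }
    sp <- file.path(d, "summary.json")
    if (file.exists(sp)) {
      s <- jsonlite::read_json(sp, simplifyVector = TRUE)
      sums[[nm]] <- data.frame(scenario = nm, peak_i = s$peak_i,
                               total_cases = s$total_cases, s_inf = s$s_inf,
                               duration = s$duration,
                               total_cost = s$total_cost)
    }
    cp <- file.path(d, "scan.csv")
    if (file.exists(cp))
      scans[[nm]] <- cbind(scenario = nm, utils::read.csv(cp))
  }
  bind <- function(x) if (length(x)) do.call(rbind, unname(x)) else NULL
  list(trajectories = bind(trajs), summaries = bind(sums),
       scans = bind(scans))
}
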