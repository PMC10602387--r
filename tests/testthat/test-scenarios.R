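test_that("bundled presets load and carry the documented defaults", {
  avail <- scenario_preset()
  expect_true(all(c("baseline", "fig2_constant_alpha400", "fig3_threshold",
                    "fig4_gov_threshold") %in% avail))
  cfg <- scenario_preset("fig2_constant_alpha400")
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$params$epidemic$kappa_star, 4)
  expect_equal(cfg$params$epidemic$i0, 3e-8)
  expect_equal(cfg$params$utility$f, 1)
  expect_true(cfg$params$utility$cost$constant)
  expect_equal(cfg$params$utility$cost$alpha0, 400)
  th <- scenario_preset("fig3_threshold")
  expect_equal(th$params$utility$cost$i_hc, 0.1)
  expect_equal(th$params$utility$cost$sigma, 300)
})

test_that("invalid configs produce a schema error listing offending keys", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: broken", "mode: government",
               "utility: {f: 1.0, cost: {constant: true, alpha0: 1.0}}"),
             bad)
  err <- tryCatch(read_scenario(bad), error = function(e) conditionMessage(e))
  expect_match(err, "epidemic")
  expect_match(err, "government")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mode: dance", bad2)
  err2 <- tryCatch(read_scenario(bad2), error = function(e) conditionMessage(e))
  expect_match(err2, "mode")
})

test_that("baseline runs write reproducible outputs with the expected keys", {
  cfg <- scenario_preset("baseline")
  cfg$grid <- time_grid(tf = 60, n = 2401)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sm <- run_scenario(cfg, d1)
  expect_s3_class(sm, "epidemic_summary")
  expect_close(sm$peak_i, 1 - (1 + log(4)) / 4, 0.01)
  js <- jsonlite::read_json(file.path(d1, "summary.json"),
                            simplifyVector = TRUE)
  expect_true(all(c("peak_i", "total_cases", "s_inf", "duration",
                    "total_cost") %in% names(js)))
  # identical config => byte-identical outputs
  run_scenario(cfg, d2)
  for (f in c("trajectory.csv", "summary.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("nash preset reduces cases relative to the uncontrolled baseline", {
  base <- scenario_preset("baseline")
  nash <- scenario_preset("fig2_constant_alpha400")
  g <- time_grid(tf = 100, n = 3001)
  base$grid <- g
  nash$grid <- g
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sb <- run_scenario(base, d1)
  sn <- run_scenario(nash, d2)
  expect_lt(sn$total_cases, sb$total_cases)
  expect_lt(sn$peak_i, sb$peak_i)
  # collation produces tidy per-run tables
  tabs <- make_figure_tables(c(baseline = d1, nash = d2))
  expect_equal(sort(unique(tabs$trajectories$scenario)),
               c("baseline", "nash"))
  expect_equal(nrow(tabs$summaries), 2)
  expect_true(all(c("t", "s", "i", "k", "eps") %in%
                    names(tabs$trajectories)))
  expect_error(make_figure_tables(c(x = file.path(d1, "missing"))),
               "missing")
})

test_that("the command-line entry point runs a scenario end to end", {
  exe <- system.file("exec", "epictrl", package = "epictrl")
  skip_if(exe == "", "exec script not installed")
  cfgf <- system.file("extdata", "scenarios", "baseline.yaml",
                      package = "epictrl")
  out <- withr::local_tempdir()
  res <- system2(exe, c("baseline", "--config", cfgf, "--out", out,
                        "--grid-n", "1201", "--tf", "60"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "summary.json")))
})
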