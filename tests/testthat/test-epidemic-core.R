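test_that("time grid invariants hold and bad grids are rejected", {
  g <- time_grid(tf = 10, n = 5)
  expect_equal(g$dt, 2.5)
  expect_equal(g$t, c(0, 2.5, 5, 7.5, 10))
  expect_true(all(diff(g$t) > 0))
  expect_error(time_grid(tf = 0, n = 10))
  expect_error(time_grid(tf = 10, n = 1))
})

test_that("no transmission means pure exponential recovery", {
  g <- grid_fast(tf = 20, n = 801)
  ep <- epidemic_params(i0 = 1e-3)
  tr <- integrate_sir(0, ep, g)
  expect_equal(tr$s, rep(1 - 1e-3, g$n), tolerance = 1e-12)
  expect_lt(max(abs(tr$i - 1e-3 * exp(-g$t))), 1e-10)
})

test_that("constant-behaviour run reproduces the analytic final size", {
  g <- grid_default()
  ep <- epidemic_params(kappa_star = 4, i0 = 3e-8)
  tr <- integrate_sir(4, ep, g)
  expect_lt(tr$i[g$n], 1e-8)
  s_inf <- final_size_root(4, ep$s0, ep$i0)
  expect_close(tr$s[g$n], s_inf, 1e-6)
  # peak infected fraction has the closed form 1 - (1 + log R0)/R0 for i0 -> 0
  expect_close(max(tr$i), 1 - (1 + log(4)) / 4, 1e-4)
})

test_that("final-size relation agrees with an independent bisection oracle", {
  bisect <- function(R0, s0, i0) {
    gfun <- function(s) s - s0 * exp(-R0 * (s0 + i0 - s))
    lo <- 1e-14; hi <- s0 - 1e-14
    for (j in 1:200) {
      mid <- (lo + hi) / 2
      if (gfun(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  for (R0 in c(1.5, 2, 4)) {
    expect_close(final_size_root(R0, 1 - 3e-8, 3e-8),
                 bisect(R0, 1 - 3e-8, 3e-8), 1e-9)
  }
  # frozen oracle values
  expect_close(final_size_root(4, 1 - 3e-8, 3e-8), 0.019830, 1e-5)
  expect_close(1 - final_size_root(2, 1 - 1e-9, 1e-9), 0.796812, 1e-5)
  # subcritical epidemic with vanishing seed leaves s essentially untouched
  expect_close(final_size_root(0.9, 1 - 1e-12, 1e-12), 1 - 1e-12, 1e-9)
})

test_that("SIR paths conserve probability and s is monotone for any k >= 0", {
  g <- grid_fast(tf = 40, n = 1601)
  ep <- epidemic_params()
  set.seed(42)
  for (rep in 1:5) {
    # random smooth non-negative behaviour path
    k <- pmax(0, 4 + cumsum(rnorm(g$n, 0, 0.05)))
    tr <- integrate_sir(k, ep, g)
    expect_true(all(diff(tr$s) <= 1e-14))
    expect_true(all(tr$s >= 0 & tr$i >= 0))
    expect_true(all(tr$s + tr$i <= 1 + 1e-9))
    # discrete conservation: d(s+i)/dt = -i up to the scheme's accuracy
    mid_i <- (tr$i[-1] + tr$i[-g$n]) / 2
    resid <- diff(tr$s + tr$i) / g$dt + mid_i
    expect_lt(max(abs(resid)), 1e-4)
  }
})

test_that("halving the step leaves the baseline peak essentially unchanged", {
  ep <- epidemic_params()
  p1 <- summarize_epidemic(integrate_sir(4, ep, time_grid(100, 5001)))$peak_i
  p2 <- summarize_epidemic(integrate_sir(4, ep, time_grid(100, 10001)))$peak_i
  expect_lt(abs(p1 - p2), 1e-6)
})

test_that("invalid behaviour paths are rejected", {
  g <- grid_fast(tf = 10, n = 401)
  ep <- epidemic_params()
  expect_error(integrate_sir(-1, ep, g), "non-negative")
  kbad <- rep(4, g$n); kbad[10] <- NaN
  expect_error(integrate_sir(kbad, ep, g), "NA")
  expect_error(integrate_sir(rep(4, g$n - 1), ep, g), "length")
})

test_that("summary metrics match direct node-count oracles", {
  g <- grid_fast(tf = 30, n = 1201)
  ep <- epidemic_params(i0 = 3e-8)
  # zero-infection path
  tr0 <- integrate_sir(0, ep, g)
  sm0 <- summarize_epidemic(tr0)
  expect_equal(sm0$duration, 0)  # i0 < 1e-4 never exceeds the threshold
  expect_lt(sm0$peak_i, 1e-4)
  # baseline run: duration equals brute-force node count times dt
  tr <- integrate_sir(4, ep, grid_default())
  sm <- summarize_epidemic(tr)
  expect_equal(sm$duration, sum(tr$i > 1e-4) * tr$grid$dt)
  expect_equal(sm$total_cases, 1 - tr$s[tr$grid$n])
  # quadratic peak refinement: at or just above the largest node value
  expect_gte(sm$peak_i, max(tr$i))
  expect_lt(sm$peak_i - max(tr$i), 1e-4)
  expect_gt(sm$duration, 0)
})

test_that("trajectory round-trips through CSV at full precision", {
  g <- grid_fast(tf = 20, n = 801)
  tr <- integrate_sir(4, epidemic_params(i0 = 1e-4), g, eps = sin(g$t))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$s, tr$s, tolerance = 1e-15)
  expect_equal(tr2$i, tr$i, tolerance = 1e-15)
  expect_equal(tr2$k, tr$k, tolerance = 1e-15)
  expect_equal(tr2$eps, tr$eps, tolerance = 1e-15)
})
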