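test_that("responses are any movement inside the post-stimulus window", {
  # 1-s bins over 200 s, tap at t = 100, movement at 102 s
  v <- matrix(0, 2, 200)
  v[1, 103] <- 1  # bin starting at 102 s
  act <- toy_activity(v, bin_width = 1)
  lg <- stimulus_log(data.frame(time = 100, kind = "tap", payload = 5))
  expect_equal(as.vector(score_responses(act, lg, 5)$responses), c(1, 0))
  expect_equal(as.vector(score_responses(act, lg, 1)$responses), c(0, 0))

  # all-quiet trace scores zero everywhere
  quiet <- toy_activity(matrix(0, 3, 200), bin_width = 1)
  expect_true(all(score_responses(quiet, lg, 5)$responses == 0))

  # overlapping windows and out-of-range events are rejected
  lg2 <- stimulus_log(data.frame(time = c(100, 103), kind = "tap",
                                 payload = 5))
  expect_error(score_responses(act, lg2, 5), "overlap")
  lg3 <- stimulus_log(data.frame(time = 199, kind = "tap", payload = 5))
  expect_error(score_responses(act, lg3, 5), "outside")
})

test_that("scoring equals a brute-force window scan on random traces", {
  set.seed(41)
  for (rep in 1:20) {
    n_s <- 600
    v <- matrix(rbinom(2 * n_s, 1, 0.05), nrow = 2)
    act <- toy_activity(v, bin_width = 1)
    taps <- seq(30, 570, by = 30)
    lg <- stimulus_log(data.frame(time = taps, kind = "tap", payload = 3))
    got <- score_responses(act, lg, 5)$responses
    want <- sapply(taps, function(t)
      apply(v[, (t + 1):(t + 5), drop = FALSE] > 0, 1, any))
    expect_equal(unname(got), unname(want) * 1L)
    bg <- background_probability(act, lg, 5)
    want_bg <- rowMeans(sapply(taps, function(t)
      apply(v[, (t - 4):t, drop = FALSE] > 0, 1, any)))
    expect_equal(unname(bg), unname(want_bg))
  }
})

test_that("background probability hits its analytic extremes", {
  taps <- seq(60, 60 * 420, by = 60)
  n_s <- max(taps) + 60
  quiet <- toy_activity(matrix(0, 1, n_s), bin_width = 1)
  busy <- toy_activity(matrix(1, 1, n_s), bin_width = 1)
  lg <- stimulus_log(data.frame(time = taps, kind = "tap", payload = 2))
  expect_equal(unname(background_probability(quiet, lg)), 0)
  expect_equal(unname(background_probability(busy, lg)), 1)

  # planted Bernoulli(0.1) movement over 420 events: within binomial CI
  sim <- simulate_tap_experiment(top = 0, background = 0.1, n_larvae = 20,
                                 seed = 43)
  bg <- background_probability(sim$activity, sim$log)
  ci <- qbinom(c(0.0005, 0.9995), 420 * 20, 0.1) / (420 * 20)
  expect_gt(mean(bg), ci[1])
  expect_lt(mean(bg), ci[2])
})

test_that("corrected response = raw response - mean background", {
  sim <- simulate_tap_experiment(n_larvae = 12, seed = 47)
  scored <- score_responses(sim$activity, sim$log)
  bg <- background_probability(sim$activity, sim$log)
  tab <- corrected_response_table(scored, bg)
  expect_s3_class(tab, "tap_response_table")
  expect_equal(tab$corrected, tab$raw - mean(bg))
  expect_true(all(diff(tab$power) > 0))
  expect_equal(tab$n_trials, rep(30, 14))

  # hand-computed aggregation oracle
  pw <- sim$log$payload[sim$log$kind == "tap"]
  for (p in unique(pw)[1:3])
    expect_equal(tab$raw[tab$power == p],
                 mean(scored$responses[, pw == p]))

  # r == b gives corrected 0 at every power
  null <- simulate_tap_experiment(top = 0, bottom = 0, background = 0,
                                  n_larvae = 5, seed = 48)
  s0 <- score_responses(null$activity, null$log)
  tab0 <- corrected_response_table(s0, rep(0, 5))
  expect_equal(tab0$corrected, rep(0, 14))
})

test_that("noiseless curves are recovered exactly by the OLS fit", {
  p <- default_tap_powers()
  tb <- data.frame(power = p,
                   corrected = logistic4(log10(p), 0, 0.4, log10(3), 2))
  fit <- fit_dose_response(tb)
  expect_lt(fit$ss_residual, 1e-10)
  expect_equal(unname(coef(fit)["top"]), 0.4, tolerance = 1e-4)
  expect_equal(fit$etp50, 3, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["hill_slope"]), 2, tolerance = 1e-3)
  expect_equal(fit$df, length(p) - 3)
  expect_true(fit$converged)

  # degenerate and undersized inputs are rejected
  expect_error(fit_dose_response(data.frame(power = p, corrected = 0.2)),
               "degenerate")
  expect_error(fit_dose_response(tb[1:4, ]), "5 distinct")
})

test_that("the fit matches a dense grid-search oracle on noisy data", {
  set.seed(51)
  p <- default_tap_powers()
  truth <- logistic4(log10(p), 0, 0.34, log10(3.1), 2)
  y <- truth + rnorm(length(p), sd = 0.02)
  tb <- data.frame(power = p, corrected = y)
  fit <- fit_dose_response(tb)

  grid <- expand.grid(top = seq(0.2, 0.5, by = 0.01),
                      log_e = seq(log10(1), log10(10), length.out = 81),
                      slope = seq(0.5, 4, by = 0.05))
  ss <- mapply(function(top, le, sl)
    sum((y - logistic4(log10(p), 0, top, le, sl))^2),
    grid$top, grid$log_e, grid$slope)
  best <- grid[which.min(ss), ]
  expect_lte(fit$ss_residual, min(ss) + 1e-10)
  expect_equal(log10(fit$etp50), best$log_e,
               tolerance = diff(range(grid$log_e)) / 80 * 2)

  # fitted curve is monotone in power for a positive Hill slope
  pp <- 10^seq(-0.5, 2, length.out = 100)
  expect_true(all(diff(predict(fit, data.frame(power = pp))) >= 0))
})

test_that("ETP50 is equivariant under rescaling of the power axis", {
  set.seed(53)
  p <- default_tap_powers()
  y <- logistic4(log10(p), 0, 0.34, log10(3.1), 2.2) +
    rnorm(length(p), sd = 0.01)
  f1 <- fit_dose_response(data.frame(power = p, corrected = y))
  f2 <- fit_dose_response(data.frame(power = 7 * p, corrected = y))
  expect_equal(f2$etp50, 7 * f1$etp50, tolerance = 1e-4)
})

test_that("percent change reproduces the reported ETP50 decreases", {
  expect_equal(percent_change(3.1, 2.1), -32.2580645, tolerance = 1e-7)
  expect_equal(percent_change(5.7, 2.6), -54.3859649, tolerance = 1e-7)
  expect_equal(percent_change(4.2, 4.2), 0)
  expect_error(percent_change(0, 1), "nonzero")
})

test_that("the extra-SS F statistic matches its defining formula", {
  set.seed(57)
  p <- default_tap_powers()
  mk <- function(etp, seed) {
    set.seed(seed)
    data.frame(power = p, corrected = logistic4(
      log10(p), 0, 0.34, log10(etp), 2) + rnorm(length(p), sd = 0.02))
  }
  ta <- mk(3.1, 61); tb <- mk(2.1, 62)
  cmp <- compare_fits(ta, tb, shared = "etp50")

  # recompute F from independently refit SS components
  fa <- fit_dose_response(ta); fb <- fit_dose_response(tb)
  ss_sep <- fa$ss_residual + fb$ss_residual
  df_sep <- fa$df + fb$df
  F_oracle <- ((cmp$ss_shared - ss_sep) / cmp$df_num) / (ss_sep / df_sep)
  expect_equal(cmp$F, F_oracle, tolerance = 1e-10)
  expect_equal(cmp$df_den, df_sep)
  expect_equal(cmp$p_value,
               pf(F_oracle, cmp$df_num, df_sep, lower.tail = FALSE))

  # identical groups: tying parameters costs nothing -> F ~ 0, p ~ 1
  same <- compare_fits(ta, ta, shared = "all")
  expect_lt(same$F, 1e-4)
  expect_gt(same$p_value, 0.999)
})

test_that("the OLS engine agrees with an independent nls implementation", {
  set.seed(63)
  p <- default_tap_powers()
  y <- logistic4(log10(p), 0, 0.34, log10(3.1), 2) +
    rnorm(length(p), sd = 0.015)
  fit <- fit_dose_response(data.frame(power = p, corrected = y))
  ref <- minpack.lm::nlsLM(
    y ~ top / (1 + 10^((le - log10(p)) * h)),
    start = list(top = 0.3, le = 0.5, h = 2),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(fit$ss_residual, sum(residuals(ref)^2), tolerance = 1e-6)
  expect_equal(log10(fit$etp50), unname(coef(ref)["le"]),
               tolerance = 1e-4)
})
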