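test_that("rebin sums within windows and conserves total activity", {
  x <- toy_activity(matrix(c(1, 0, 2, 0, 0, 3), nrow = 1), bin_width = 10)
  y <- rebin(x, 60)
  expect_equal(as.vector(y$values), 6)
  expect_equal(y$bin_width, 60)

  # identity when widths match
  expect_identical(rebin(x, 10), x)

  # conservation on random traces
  set.seed(11)
  for (i in 1:20) {
    z <- toy_activity(matrix(runif(5 * 36, 0, 10), nrow = 5),
                      bin_width = 10)
    expect_equal(sum(rebin(z, 60)$values), sum(z$values))
  }

  expect_error(rebin(x, 25), "integer multiple")
})

test_that("sleep bouts are maximal runs of zero-activity minutes", {
  b <- detect_sleep_bouts(c(0, 0, 0, 5, 0))
  expect_equal(b$start_bin, c(1, 5))
  expect_equal(b$duration, c(3, 1))
  expect_equal(nrow(detect_sleep_bouts(c(1, 2, 0.5))), 0)

  # oracle equivalence on random binary traces
  set.seed(21)
  for (i in 1:1000) {
    v <- rbinom(sample(5:60, 1), 1, runif(1))
    expect_identical(detect_sleep_bouts(v), bout_oracle(v))
  }
})

test_that("epoch summaries reproduce the hand-computed toy example", {
  v <- c(3, 0, 0, 4, 0, 0, 0, 2, 5, 0)
  x <- toy_activity(matrix(v, nrow = 1))
  s <- summarize_epoch(x, short_day_schedule(10), "day 1")
  expect_equal(s$sleep, 6)
  expect_equal(s$bout_count, 3)
  expect_equal(s$mean_bout_length, 2)
  expect_equal(s$sleep_latency, 1)
  expect_equal(s$total_activity, 14)
  expect_equal(s$waking_activity, 14 / 4)
  expect_false(s$latency_censored)
})

test_that("degenerate epochs are handled: all-sleep and no-sleep", {
  allz <- summarize_epoch(toy_activity(matrix(0, 1, 10)),
                          short_day_schedule(10), "day 1")
  expect_equal(allz$sleep, 10)
  expect_equal(allz$bout_count, 1)
  expect_equal(allz$sleep_latency, 0)
  expect_equal(allz$waking_activity, 0)
  expect_true(allz$zero_waking)

  awake <- summarize_epoch(toy_activity(matrix(1, 1, 10)),
                          short_day_schedule(10), "day 1")
  expect_equal(awake$sleep, 0)
  expect_equal(awake$sleep_latency, 10)  # censored at epoch length
  expect_true(awake$latency_censored)
})

test_that("sleep + waking minutes always equals the epoch length", {
  x <- simulate_sleep_wake(n_larvae = 12, duration_s = 24 * 3600,
                           seed = 9)
  s <- sleep_summary(x, epoch_schedule())
  ep_min <- ifelse(grepl("^day", s$epoch), 14 * 60, 10 * 60)
  wake_min <- ifelse(s$waking_activity > 0,
                     s$total_activity / s$waking_activity, 0)
  expect_equal(s$sleep + wake_min, ep_min, tolerance = 1e-9)
  # bout_count x mean bout length = sleep
  expect_equal(s$bout_count * s$mean_bout_length, s$sleep)
  expect_true(all(s$sleep_latency >= 0 & s$sleep_latency <= ep_min))
})

test_that("summaries are invariant to chunked reconstruction", {
  x <- simulate_sleep_wake(n_larvae = 4, duration_s = 24 * 3600,
                           seed = 13)
  half <- ncol(x$values) %/% 2
  rebuilt <- activity_matrix(
    cbind(x$values[, 1:half], x$values[, (half + 1):ncol(x$values)]),
    x$larva_ids, x$bin_start, x$bin_width)
  expect_equal(sleep_summary(rebuilt, epoch_schedule()),
               sleep_summary(x, epoch_schedule()))
})

test_that("heat-shock ratio divides by the genotype mean of the pre night", {
  mk_sum <- function(larva, epoch, sleep)
    data.frame(larva = larva, epoch = epoch, sleep = sleep)
  pm <- plate_map(data.frame(well = paste0("A", 1:4),
                             larva = paste0("L", 1:4),
                             genotype = c("wt", "wt", "mut", "mut")))
  s <- rbind(mk_sum(paste0("L", 1:4), "night 5", c(200, 200, 100, 300)),
             mk_sum(paste0("L", 1:4), "night 6", c(200, 200, 100, 300)))
  hs <- heat_shock_sleep_change(s, "night 5", "night 6", pm)
  # post == pre for every larva and the wt means match -> 100%
  expect_equal(hs$pct_of_baseline[hs$larva %in% c("L1", "L2")],
               c(100, 100))
  # mut genotype mean pre = 200; L3 post 100 -> 50%, L4 post 300 -> 150%
  expect_equal(hs$pct_of_baseline[hs$larva == "L3"], 50)

  # forced example: pre-night genotype mean 200 min, post 80 -> 40%
  s2 <- rbind(mk_sum("L1", "night 5", 200), mk_sum("L2", "night 5", 200),
              mk_sum("L1", "night 6", 80), mk_sum("L2", "night 6", 200))
  hs2 <- heat_shock_sleep_change(s2, "night 5", "night 6", pm)
  expect_equal(hs2$pct_of_baseline[hs2$larva == "L1"], 40)

  # zero baseline is an error
  s3 <- rbind(mk_sum("L3", "night 5", 0), mk_sum("L3", "night 6", 10))
  expect_error(heat_shock_sleep_change(s3, "night 5", "night 6", pm),
               "undefined")
})

test_that("a planted post/pre sleep ratio is recovered on simulation", {
  # pre night: sleep fraction 4/8 = 0.5; post night: 3/8 -> ratio 0.75
  sched5 <- epoch_schedule(start = "23:00", first_day = 5L)
  sched6 <- epoch_schedule(start = "23:00", first_day = 6L)
  pre <- simulate_sleep_wake(
    n_larvae = 48, duration_s = 10 * 3600, schedule = sched5,
    night = list(wake_bout_min = 4, sleep_bout_min = 4,
                 activity_mean = 3, activity_sd = 1.5), seed = 31)
  post <- simulate_sleep_wake(
    n_larvae = 48, duration_s = 10 * 3600, schedule = sched6,
    night = list(wake_bout_min = 5, sleep_bout_min = 3,
                 activity_mean = 3, activity_sd = 1.5), seed = 32)
  s <- rbind(sleep_summary(pre, sched5), sleep_summary(post, sched6))
  pm <- plate_map(data.frame(well = pre$larva_ids, larva = pre$larva_ids,
                             genotype = "wt"))
  hs <- heat_shock_sleep_change(s, "night 5", "night 6", pm)
  # expected 75%; SEM of the group mean is ~2-3%
  expect_equal(mean(hs$pct_of_baseline), 75, tolerance = 0.08)
})
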