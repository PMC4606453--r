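test_that("window extraction applies the one-minute onset exclusion", {
  # 360 10-s bins (1 h), light on at 1800 s, off at end
  act <- toy_activity(matrix(0.5, 2, 360), bin_width = 10)
  lg <- stimulus_log(data.frame(time = c(1800, 3600),
                                kind = c("light_on", "light_off"),
                                payload = "blue"))
  w <- extract_windows(act, lg)
  expect_length(w, 1)
  expect_equal(w[[1]]$baseline_idx, 1:174)    # 0..1730 s
  expect_equal(w[[1]]$response_idx, 187:360)  # 1860..3590 s
  expect_length(intersect(w[[1]]$baseline_idx, w[[1]]$response_idx), 0)

  # overlapping trials are rejected
  lg2 <- stimulus_log(data.frame(
    time = c(1800, 3600, 3700, 5000),
    kind = rep(c("light_on", "light_off"), 2), payload = "blue"))
  expect_error(extract_windows(act, lg2), "truncated|overlap")

  # a full synthetic night yields three disjoint window sets
  sim <- simulate_opto_night(seed = 3)
  w3 <- extract_windows(sim$activity, sim$log)
  expect_length(w3, 3)
  all_idx <- unlist(lapply(w3, function(t) c(t$baseline_idx,
                                             t$response_idx)))
  expect_equal(anyDuplicated(all_idx), 0)
})

test_that("normalization gives ratio 1 when response equals baseline", {
  act <- toy_activity(matrix(0.5, 4, 360), bin_width = 10)
  lg <- stimulus_log(data.frame(time = c(1800, 3600),
                                kind = c("light_on", "light_off"),
                                payload = "blue"))
  pm <- plate_map(data.frame(well = act$larva_ids, larva = act$larva_ids,
                             genotype = rep(c("a", "b"), 2)))
  w <- extract_windows(act, lg)
  r <- normalize_light_activity(w, act, pm)
  expect_equal(r$ratio, rep(1, 4))

  # a larva moving twice the genotype baseline mean has ratio 2
  v <- matrix(0.5, 4, 360)
  v[1, 187:360] <- 1
  act2 <- toy_activity(v, bin_width = 10)
  r2 <- normalize_light_activity(w, act2, pm)
  expect_equal(r2$ratio[1], 2)
})

test_that("genotype percent is reference-relative and scale-invariant", {
  ratios <- data.frame(larva = sprintf("L%d", 1:40),
                       genotype = rep(c("wt", "tg"), each = 20),
                       ratio = rep(c(1.0, 0.75), each = 20))
  gp <- genotype_percent(ratios, "wt")
  expect_equal(gp$percent[gp$genotype == "wt"], 100)
  expect_equal(gp$percent[gp$genotype == "tg"], 75)
  expect_error(genotype_percent(ratios, "absent"), "absent")

  # multiplying all activities by a positive constant changes nothing
  scaled <- ratios; scaled$ratio <- scaled$ratio * 37.5
  expect_equal(genotype_percent(scaled, "wt")$percent, gp$percent)
})

test_that("pooled experiments equal the brute-force pooled computation", {
  set.seed(71)
  exps <- lapply(1:3, function(i)
    data.frame(larva = sprintf("e%d_L%d", i, 1:20),
               genotype = rep(c("wt", "tg"), 10),
               ratio = rexp(20) + 0.2))
  pooled <- do.call(rbind, exps)
  gp <- genotype_percent(pooled, "wt")
  want <- 100 * mean(pooled$ratio[pooled$genotype == "tg"]) /
    mean(pooled$ratio[pooled$genotype == "wt"])
  expect_equal(gp$percent[gp$genotype == "tg"], want)
})

test_that("response dynamics find the maximum and its latency", {
  lg <- stimulus_log(data.frame(time = c(1800, 3600),
                                kind = c("light_on", "light_off"),
                                payload = "blue"))
  pm1 <- plate_map(data.frame(well = "L01", larva = "L01",
                              genotype = "wt"))
  # monotone ramp: maximum at the final bin
  ramp <- matrix(seq(0, 8, length.out = 360), nrow = 1)
  act <- toy_activity(ramp, bin_width = 10)
  w <- extract_windows(act, lg)
  d <- response_dynamics(act, w, pm1, smoothing_bins = 1)
  expect_equal(d$A, ramp[1, 360])
  expect_equal(d$T_A_min, (3590 - 1800 + 5) / 60)

  # flat trace: tie broken at the earliest retained bin
  flat <- toy_activity(matrix(2, 1, 360), bin_width = 10)
  d2 <- response_dynamics(flat, w, pm1, smoothing_bins = 5)
  expect_equal(d2$T_A_min, (1860 - 1800 + 5) / 60)
  expect_equal(d2$A, 2)

  expect_error(response_dynamics(act, w, pm1, smoothing_bins = 4),
               "odd")
})

test_that("excluded bins contribute to no statistic", {
  sim <- simulate_opto_night(seed = 5)
  w <- extract_windows(sim$activity, sim$log)
  used <- sort(unique(unlist(lapply(w, function(t)
    c(t$baseline_idx, t$response_idx)))))
  zeroed <- sim$activity
  zeroed$values[, -used] <- 0
  expect_equal(normalize_light_activity(w, zeroed, sim$plate_map),
               normalize_light_activity(w, sim$activity, sim$plate_map))
  expect_equal(response_dynamics(zeroed, w, sim$plate_map),
               response_dynamics(sim$activity, w, sim$plate_map))
})

test_that("a null transgene effect recovers 100% of reference", {
  sim <- simulate_opto_night(
    genotypes = list(chr2 = list(n = 36, response_scale = 1),
                     wt = list(n = 36, response_scale = 1)),
    seed = 77)
  w <- extract_windows(sim$activity, sim$log)
  gp <- genotype_percent(
    normalize_light_activity(w, sim$activity, sim$plate_map), "wt")
  expect_equal(gp$percent[gp$genotype == "chr2"], 100, tolerance = 0.05)
})
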