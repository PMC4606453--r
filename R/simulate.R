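## Run expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate minute-binned sleep/wake activity
#'
#' Generates a cohort of larvae as an alternating-renewal (semi-Markov)
#' process at one-minute resolution: wake and sleep bouts alternate,
#' with bout lengths drawn from geometric distributions (minimum one
#' minute) whose means depend on the epoch type, and each waking minute
#' receives a positive activity draw (gamma, clipped to the 60-s bin).
#' Sleep minutes are exactly zero. This is the simplest process whose
#' summaries exhibit the measures the sleep analysis reports (bout
#' number, bout length, waking activity); it is not a mechanistic model
#' of the fish.
#'
#' Defaults emulate a wild-type larva on a 14:10 light/dark cycle:
#' long wake bouts with sparse short sleep bouts by day, and roughly
#' half-time sleep in consolidated bouts by night.
#'
#' @param n_larvae number of larvae (a 96-well plate by default).
#' @param duration_s recording length in seconds (whole minutes).
#' @param schedule an [epoch_schedule()] giving day/night structure.
#' @param day,night lists with `wake_bout_min`, `sleep_bout_min` (mean
#'   bout lengths, minutes), `activity_mean`, `activity_sd`
#'   (seconds-active per waking minute).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a 60-s [activity_matrix()].
#' @export
simulate_sleep_wake <- function(n_larvae = 96,
                                duration_s = 24 * 3600,
                                schedule = epoch_schedule(),
                                day = list(wake_bout_min = 25,
                                           sleep_bout_min = 1.2,
                                           activity_mean = 6,
                                           activity_sd = 3),
                                night = list(wake_bout_min = 4,
                                             sleep_bout_min = 4,
                                             activity_mean = 3,
                                             activity_sd = 1.5),
                                seed = 1) {
  stopifnot(n_larvae >= 1, duration_s %% 60 == 0)
  for (p in list(day, night))
    if (any(unlist(p[c("wake_bout_min", "sleep_bout_min",
                       "activity_mean")]) <= 0))
      stop("bout-length and activity means must be positive", call. = FALSE)
  n_min <- duration_s %/% 60
  et <- epoch_table(schedule, duration_s)

  with_seed(seed, {
    vals <- matrix(0, nrow = n_larvae, ncol = n_min)
    for (l in seq_len(n_larvae)) {
      # bouts are drawn per epoch segment and clipped at its end, so
      # each epoch carries exactly its own bout parameters
      for (i in seq_len(nrow(et))) {
        pars <- if (et$type[i] == "day") day else night
        seg_start <- et$start_s[i] %/% 60 + 1L
        seg_end <- et$end_s[i] %/% 60
        t <- seg_start
        asleep <- stats::runif(1) <
          pars$sleep_bout_min / (pars$sleep_bout_min + pars$wake_bout_min)
        while (t <= seg_end) {
          m <- if (asleep) pars$sleep_bout_min else pars$wake_bout_min
          len <- 1L + stats::rgeom(1L, prob = min(1, 1 / m))
          idx <- t:min(t + len - 1L, seg_end)
          if (!asleep) {
            sh <- (pars$activity_mean / pars$activity_sd)^2
            vals[l, idx] <- pmin(60, pmax(
              0.1, stats::rgamma(length(idx), shape = sh,
                                 rate = sh / pars$activity_mean)))
          }
          t <- t + len
          asleep <- !asleep
        }
      }
    }
    activity_matrix(vals, sprintf("sim%03d", seq_len(n_larvae)),
                    seq(0, by = 60, length.out = n_min), 60)
  })
}

#' Default tap power series
#'
#' Fourteen tap intensities log-spaced over the power-setting range used
#' in the standard assay design (1 to 36.31 on a driver scale running
#' 0.01 to 40.95).
#'
#' @return numeric vector of 14 power settings.
#' @export
default_tap_powers <- function() {
  round(10^seq(0, log10(36.31), length.out = 14), 2)
}

#' Simulate a full arousal-threshold tap experiment
#'
#' Generates the fine-binned (1-s) activity matrix and stimulus log of a
#' tap assay: taps at a 1-min inter-trial interval with powers applied
#' in random order, `trials_per_power` trials at each power. A larva
#' responds to a tap of power p with probability
#' \eqn{r(p) = bottom + (top - bottom)/(1 + 10^{(\log_{10}etp50 -
#' \log_{10}p) h})}; independently, spontaneous (background) movement
#' occurs with probability `background` in any 5-s window, so observed
#' post-stimulus movement follows response OR background. Movement is
#' placed as a 1-s active bin at a random position inside the relevant
#' 5-s window; outside stimulus windows the trace is quiescent (the
#' assay runs at night).
#'
#' @param etp50 half-maximal tap power (power-setting units).
#' @param hill_slope Hill slope of the response curve.
#' @param top,bottom asymptotic response fractions.
#' @param background per-window spontaneous movement probability.
#' @param powers tap power settings (default [default_tap_powers()]).
#' @param trials_per_power taps delivered at each power.
#' @param n_larvae larvae on the plate.
#' @param seed integer seed.
#' @return list with `activity` (1-s [activity_matrix()]) and `log`
#'   (a [stimulus_log()]).
#' @export
simulate_tap_experiment <- function(etp50 = 3.1, hill_slope = 2,
                                    top = 0.34, bottom = 0,
                                    background = 0.05,
                                    powers = default_tap_powers(),
                                    trials_per_power = 30,
                                    n_larvae = 90, seed = 1) {
  stopifnot(etp50 > 0, top >= bottom, top <= 1, bottom >= 0,
            background >= 0, background <= 1, all(powers > 0))
  with_seed(seed, {
    pw <- sample(rep(powers, each = trials_per_power))
    n_ev <- length(pw)
    tap_t <- 300 + 60 * (seq_len(n_ev) - 1L)          # 1-min ITI
    n_s <- tap_t[n_ev] + 60
    r <- logistic4(log10(pw), bottom, top, log10(etp50), hill_slope)

    vals <- matrix(0, nrow = n_larvae, ncol = n_s)
    for (e in seq_len(n_ev)) {
      pre_move <- stats::runif(n_larvae) < background
      post_move <- (stats::runif(n_larvae) < r[e]) |
        (stats::runif(n_larvae) < background)
      # columns are 1-s bins starting at 0, so bin k covers [k-1, k)
      if (any(pre_move)) {
        off <- sample.int(5L, sum(pre_move), replace = TRUE)
        vals[cbind(which(pre_move), tap_t[e] - off + 1L)] <- 1
      }
      if (any(post_move)) {
        off <- sample.int(5L, sum(post_move), replace = TRUE)
        vals[cbind(which(post_move), tap_t[e] + off)] <- 1
      }
    }
    act <- activity_matrix(vals, sprintf("sim%03d", seq_len(n_larvae)),
                           seq(0, by = 1, length.out = n_s), 1)
    lg <- stimulus_log(data.frame(time = tap_t, kind = "tap",
                                  payload = pw))
    list(activity = act, log = lg)
  })
}

#' Simulate a night of optogenetic light-stimulation trials
#'
#' Generates 10-s-binned activity for a cohort split into genotype
#' groups, with three 30-min light exposures at a 3-h inter-trial
#' interval. Each larva shows gamma-noise activity around a baseline
#' rate; during illumination the expected activity follows a smooth
#' peaked response profile rising as \eqn{(t/T_A)^k e^{k(1 - t/T_A)}}
#' from baseline to its maximum \eqn{A^*} exactly at \eqn{T_A} minutes
#' after onset, then relaxing (mild adaptation). Onset and offset each
#' add a 30-s burst, mimicking the startle common to all genotypes
#' (these bins are excluded by the analysis windows). A genotype's
#' `response_scale` multiplies its whole lit-window expectation, so a
#' scale of 1.46 plants exactly a 46% increase in baseline-normalized
#' response activity and a maximum of `1.46 * peak`.
#'
#' @param genotypes named list: one entry per genotype with fields
#'   `n` (larvae) and `response_scale`.
#' @param baseline_rate mean seconds-active per 10-s bin in the dark.
#' @param peak response-trace maximum A* (seconds-active per bin) for a
#'   genotype with `response_scale` 1; must exceed `baseline_rate`.
#' @param t_peak_min minutes from light onset to the profile maximum.
#' @param shape_k response-profile steepness exponent.
#' @param burst_rate mean activity during the 30-s onset/offset bursts.
#' @param noise_cv coefficient of variation of per-bin gamma noise.
#' @param seed integer seed.
#' @return list with `activity` (10-s [activity_matrix()]), `log`
#'   (a [stimulus_log()]) and `plate_map`.
#' @export
simulate_opto_night <- function(genotypes = list(
                                  chr2 = list(n = 48, response_scale = 1.46),
                                  wt = list(n = 48, response_scale = 1)),
                                baseline_rate = 0.6, peak = 3,
                                t_peak_min = 12, shape_k = 2,
                                burst_rate = 6, noise_cv = 0.4,
                                seed = 1) {
  stopifnot(baseline_rate > 0, peak > baseline_rate, t_peak_min > 0,
            noise_cv > 0)
  onsets <- c(2, 5, 8) * 3600          # 3 trials, 3-h inter-trial interval
  offsets <- onsets + 30 * 60
  duration_s <- offsets[3L] + 30 * 60
  n_bin <- duration_s %/% 10
  bin_t <- seq(0, by = 10, length.out = n_bin)

  n_tot <- sum(vapply(genotypes, `[[`, 1, "n"))
  geno <- rep(names(genotypes), vapply(genotypes, `[[`, 1, "n"))
  scale <- rep(vapply(genotypes, `[[`, 1, "response_scale"),
               vapply(genotypes, `[[`, 1, "n"))

  # expected lit-window trace for response_scale 1 (NA in the dark)
  lit_mu <- rep(NA_real_, n_bin)
  burst <- logical(n_bin)
  for (i in seq_along(onsets)) {
    lit <- bin_t >= onsets[i] & bin_t < offsets[i]
    tmin <- (bin_t[lit] - onsets[i]) / 60
    lit_mu[lit] <- baseline_rate + (peak - baseline_rate) *
      (tmin / t_peak_min)^shape_k * exp(shape_k * (1 - tmin / t_peak_min))
    burst[bin_t >= onsets[i] & bin_t < onsets[i] + 30] <- TRUE
    burst[bin_t >= offsets[i] & bin_t < offsets[i] + 30] <- TRUE
  }

  with_seed(seed, {
    sh <- 1 / noise_cv^2
    vals <- matrix(0, nrow = n_tot, ncol = n_bin)
    for (l in seq_len(n_tot)) {
      mu <- ifelse(is.na(lit_mu), baseline_rate, scale[l] * lit_mu)
      mu[burst] <- burst_rate
      vals[l, ] <- pmin(10, stats::rgamma(n_bin, shape = sh,
                                          rate = sh / mu))
    }
    ids <- sprintf("sim%03d", seq_len(n_tot))
    act <- activity_matrix(vals, ids, bin_t, 10)
    lg <- stimulus_log(data.frame(
      time = c(rbind(onsets, offsets)),
      kind = rep(c("light_on", "light_off"), times = 3),
      payload = "blue"))
    pm <- plate_map(data.frame(well = ids, larva = ids, genotype = geno))
    list(activity = act, log = lg, plate_map = pm)
  })
}

#' Simulate stimulus-locked calcium imaging trials
#'
#' Generates per-neuron GCaMP fluorescence following the standard
#' protocol: a 60-s baseline, then 8 stimulation/imaging cycles of 30 s
#' at 4 Hz. Stimulated neurons receive an exponentially decaying
#' transient at each imaging start; `amplitude_pct` is calibrated as the
#' expected \eqn{\Delta F/F_0} over the standard 10-frame post window
#' (so a planted 30% transient should be recovered as 30%). Control
#' neurons have amplitude 0. Gaussian noise is added frame-wise.
#'
#' @param n_neurons neurons per condition.
#' @param conditions named numeric vector: transient amplitude
#'   (\eqn{\Delta F/F_0} percent) per condition.
#' @param baseline_f baseline fluorescence level (arbitrary units).
#' @param decay_s transient decay time constant, seconds (slow GCaMP6s
#'   kinetics).
#' @param noise_sd_pct frame noise standard deviation, percent of
#'   baseline.
#' @param n_trials stimulation/imaging cycles per neuron.
#' @param frame_rate Hz.
#' @param seed integer seed.
#' @return a [calcium_trials()] object.
#' @export
simulate_calcium <- function(n_neurons = 4,
                             conditions = c(chr2 = 30, egfp = 0),
                             baseline_f = 100, decay_s = 4,
                             noise_sd_pct = 2, n_trials = 8,
                             frame_rate = 4, seed = 1) {
  stopifnot(baseline_f > 0, decay_s > 0, n_trials >= 1)
  n_base <- 60 * frame_rate
  n_seg <- 30 * frame_rate
  # calibrate the peak so the mean over the 10-frame post window equals
  # the requested amplitude
  t_post <- (0:9) / frame_rate
  calib <- mean(exp(-t_post / decay_s))

  with_seed(seed, {
    traces <- list(); markers <- list(); cond_out <- character(0)
    for (cd in names(conditions)) {
      for (j in seq_len(n_neurons)) {
        n_frames <- n_base + n_trials * n_seg
        f <- rep(baseline_f, n_frames)
        mk <- n_base + 1L + (seq_len(n_trials) - 1L) * n_seg
        amp_abs <- baseline_f * (conditions[[cd]] / 100) / calib
        for (m in mk) {
          idx <- m:min(m + n_seg - 1L, n_frames)
          tt <- (idx - m) / frame_rate
          f[idx] <- f[idx] + amp_abs * exp(-tt / decay_s)
        }
        f <- f + stats::rnorm(n_frames,
                              sd = baseline_f * noise_sd_pct / 100)
        nm <- paste0(cd, "_n", j)
        traces[[nm]] <- f
        markers[[nm]] <- mk
        cond_out <- c(cond_out, cd)
      }
    }
    calcium_trials(traces, markers, cond_out, frame_rate)
  })
}
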