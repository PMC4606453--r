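#' Re-bin an activity matrix to a coarser bin width
#'
#' Sums seconds-active within non-overlapping windows; total activity is
#' conserved. The target width must be an integer multiple of the source
#' width and the recording length a whole number of target bins.
#'
#' @param x an [activity_matrix()].
#' @param target_bin_width new bin width in seconds.
#' @return an `activity_matrix` with the new bin width.
#' @export
rebin <- function(x, target_bin_width) {
  stopifnot(inherits(x, "activity_matrix"))
  k <- target_bin_width / x$bin_width
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("target bin width (", target_bin_width,
         ") must be an integer multiple of the source width (",
         x$bin_width, ")", call. = FALSE)
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  n <- length(x$bin_start)
  if (n %% k != 0L)
    stop("recording length (", n, " bins) is not a whole number of ",
         target_bin_width, "-s bins", call. = FALSE)
  grp <- rep(seq_len(n %/% k), each = k)
  vals <- t(apply(x$values, 1L, function(v) tapply(v, grp, sum)))
  if (n %/% k == 1L) vals <- matrix(vals, ncol = 1L,
                                    dimnames = list(x$larva_ids, NULL))
  activity_matrix(vals, x$larva_ids,
                  x$bin_start[seq(1L, n, by = k)], target_bin_width)
}

#' Detect sleep bouts in a minute-binned trace
#'
#' A sleep minute is a 60-s bin with zero locomotor activity (the
#' one-minute-inactivity behavioral sleep criterion for larval
#' zebrafish); a sleep bout is a maximal run of consecutive sleep
#' minutes. The zero threshold is exposed for sensitivity analyses but
#' the criterion is parameter-free by default: the tracker's quantization
#' threshold already lives upstream.
#'
#' @param x numeric vector of minute-binned seconds-active values, or an
#'   `activity_matrix` with 60-s bins (then a list of per-larva bout
#'   tables is returned).
#' @param threshold activity at or below which a minute counts as sleep
#'   (default exactly 0).
#' @return data.frame with columns `start_bin` (1-based index of the
#'   first minute of the bout) and `duration` (minutes); zero rows when
#'   the trace contains no sleep minute.
#' @export
detect_sleep_bouts <- function(x, threshold = 0) {
  if (inherits(x, "activity_matrix")) {
    if (abs(x$bin_width - 60) > 1e-9)
      stop("sleep scoring needs 60-s bins; rebin() the matrix first",
           call. = FALSE)
    out <- apply(x$values, 1L, detect_sleep_bouts, threshold = threshold,
                 simplify = FALSE)
    names(out) <- x$larva_ids
    return(out)
  }
  asleep <- x <= threshold
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_bin = starts[keep], duration = r$lengths[keep])
}

#' Summarize sleep/wake measures for one epoch
#'
#' Computes the six per-larva behavioral measures for a day or night
#' epoch: total activity (s), waking activity (seconds-active per waking
#' minute), sleep (min), sleep bout count, mean bout length (min), and
#' sleep latency (min from epoch start to the first bout; censored at the
#' epoch length and flagged when the larva never sleeps). Bouts spanning
#' an epoch boundary are split at the boundary and their clipped portions
#' counted in each epoch.
#'
#' @param x an `activity_matrix` with 60-s bins.
#' @param schedule an [epoch_schedule()].
#' @param epoch epoch label as produced by [epoch_table()], e.g.
#'   `"night 5"`.
#' @param larvae larva ids to summarize (default all).
#' @param threshold sleep threshold passed to [detect_sleep_bouts()].
#' @return data.frame with one row per larva: `larva`, `epoch`,
#'   `total_activity`, `waking_activity`, `sleep`, `bout_count`,
#'   `mean_bout_length`, `sleep_latency`, `latency_censored`,
#'   `zero_waking`.
#' @export
summarize_epoch <- function(x, schedule, epoch, larvae = NULL,
                            threshold = 0) {
  stopifnot(inherits(x, "activity_matrix"))
  if (abs(x$bin_width - 60) > 1e-9)
    stop("sleep scoring needs 60-s bins; rebin() the matrix first",
         call. = FALSE)
  duration_s <- length(x$bin_start) * x$bin_width
  et <- epoch_table(schedule, duration_s + x$bin_start[1L])
  row <- et[et$label == epoch, ]
  if (nrow(row) != 1L)
    stop("epoch '", epoch, "' not found in the schedule over the recording",
         call. = FALSE)
  # Bins whose start lies within the epoch belong to it.
  sel <- which(x$bin_start >= row$start_s & x$bin_start < row$end_s)
  expected <- round((row$end_s - row$start_s) / 60)
  if (length(sel) < expected)
    stop("epoch '", epoch, "' extends beyond the recorded data",
         call. = FALSE)
  if (is.null(larvae)) larvae <- x$larva_ids
  epoch_min <- length(sel)

  out <- lapply(larvae, function(id) {
    v <- x$values[match(id, x$larva_ids), sel]
    bouts <- detect_sleep_bouts(v, threshold = threshold)
    sleep <- sum(bouts$duration)
    wake_min <- epoch_min - sleep
    total <- sum(v)
    censored <- nrow(bouts) == 0L
    data.frame(
      larva = id, epoch = epoch,
      total_activity = total,
      waking_activity = if (wake_min > 0) total / wake_min else 0,
      sleep = sleep,
      bout_count = nrow(bouts),
      mean_bout_length = if (nrow(bouts)) sleep / nrow(bouts) else 0,
      sleep_latency = if (censored) epoch_min else bouts$start_bin[1L] - 1L,
      latency_censored = censored,
      zero_waking = wake_min == 0L,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sleep summary over all epochs of a recording
#'
#' Applies [summarize_epoch()] to every complete epoch the schedule
#' defines over the recording.
#'
#' @inheritParams summarize_epoch
#' @param complete_only drop epochs not fully covered by the recording.
#' @return data.frame stacking the per-epoch summaries.
#' @export
sleep_summary <- function(x, schedule, larvae = NULL, threshold = 0,
                          complete_only = TRUE) {
  stopifnot(inherits(x, "activity_matrix"))
  duration_s <- length(x$bin_start) * x$bin_width + x$bin_start[1L]
  et <- epoch_table(schedule, duration_s)
  if (complete_only) {
    full_len <- ifelse(et$type == "day", schedule$day_length,
                       schedule$night_length)
    et <- et[abs((et$end_s - et$start_s) - full_len) < 1e-6, ]
  }
  do.call(rbind, lapply(et$label, function(ep)
    summarize_epoch(x, schedule, ep, larvae = larvae,
                    threshold = threshold)))
}

#' Heat-shock sleep-change ratio
#'
#' For heat-shock overexpression experiments: each larva's total sleep in
#' the night after induction is divided by the mean total sleep of all
#' larvae of the same genotype in the night before, and expressed as a
#' percentage. 100% means no change.
#'
#' @param summaries a sleep summary data.frame (from [sleep_summary()] or
#'   [summarize_epoch()]) containing both nights.
#' @param pre_night,post_night epoch labels, e.g. `"night 5"` and
#'   `"night 6"`.
#' @param plate_map a [plate_map()] resolving larva to genotype.
#' @return data.frame with `larva`, `genotype`, `pct_of_baseline`.
#' @export
heat_shock_sleep_change <- function(summaries, pre_night, post_night,
                                    plate_map) {
  pre <- summaries[summaries$epoch == pre_night, ]
  post <- summaries[summaries$epoch == post_night, ]
  if (!nrow(pre) || !nrow(post))
    stop("both nights must be present in the summaries", call. = FALSE)
  missing_pre <- setdiff(post$larva, pre$larva)
  if (length(missing_pre))
    stop("larva(e) missing the pre-induction night: ",
         paste(utils::head(missing_pre, 5L), collapse = ", "), call. = FALSE)
  geno <- map_genotype(post$larva, plate_map)
  pre_geno <- map_genotype(pre$larva, plate_map)
  baseline <- tapply(pre$sleep, pre_geno, mean)
  if (any(baseline[unique(geno)] == 0))
    stop("genotype mean pre-induction sleep is zero; ratio undefined",
         call. = FALSE)
  data.frame(
    larva = post$larva,
    genotype = geno,
    pct_of_baseline = 100 * post$sleep / as.numeric(baseline[geno]),
    stringsAsFactors = FALSE)
}
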