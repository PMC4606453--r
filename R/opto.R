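#' Extract analysis windows for light-stimulation trials
#'
#' Each trial is a 30-min light exposure monitored 30 min before and
#' after light onset on 10-s bins. The baseline window is the 30 min
#' before onset minus its final minute, and the response window the
#' 30 min of illumination minus its first minute: light onset and offset
#' each trigger a short (~30 s) startle burst common to all genotypes, so
#' the minute around onset is excluded and the window ends at offset,
#' dropping the offset burst entirely.
#'
#' @param x an [activity_matrix()] with 10-s bins.
#' @param stim a [stimulus_log()] with paired `light_on`/`light_off`
#'   events.
#' @param exclusion_s seconds excluded on each side of light onset.
#' @return an object of class `opto_windows`: a list of trials, each
#'   holding `onset`, `offset`, `baseline_idx` and `response_idx`
#'   (column indices into `x`).
#' @export
extract_windows <- function(x, stim, exclusion_s = 60) {
  stopifnot(inherits(x, "activity_matrix"))
  if (abs(x$bin_width - 10) > 1e-9)
    stop("light-response analysis expects 10-s bins", call. = FALSE)
  on_t <- stim$time[stim$kind == "light_on"]
  off_t <- stim$time[stim$kind == "light_off"]
  if (length(on_t) != length(off_t) || any(off_t <= on_t))
    stop("light_on/light_off events must come in ordered pairs",
         call. = FALSE)
  pre_s <- 30 * 60
  t0 <- x$bin_start[1L]
  t_end <- x$bin_start[length(x$bin_start)] + x$bin_width
  trials <- lapply(seq_along(on_t), function(i) {
    onset <- on_t[i]; offset <- off_t[i]
    if (onset - pre_s < t0 || offset > t_end)
      stop("trial ", i, " is truncated: needs full coverage from ",
           onset - pre_s, " to ", offset, " s", call. = FALSE)
    if (i > 1L && onset - pre_s < off_t[i - 1L])
      stop("trial ", i, " overlaps the previous trial", call. = FALSE)
    list(onset = onset, offset = offset,
         baseline_idx = bins_in(x, onset - pre_s, onset - exclusion_s),
         response_idx = bins_in(x, onset + exclusion_s, offset))
  })
  structure(trials, class = "opto_windows")
}

## Column indices of bins whose start lies in [from, to).
bins_in <- function(x, from, to) {
  which(x$bin_start >= from - 1e-9 & x$bin_start < to - 1e-9)
}

#' Baseline-normalized light-response activity per larva
#'
#' For each trial, a larva's total activity in the response window is
#' divided by the mean baseline-window activity of all larvae of the
#' same genotype; ratios are then averaged over the night's trials with
#' equal weight.
#'
#' @param windows an `opto_windows` object from [extract_windows()].
#' @param x the same 10-s [activity_matrix()].
#' @param plate_map a [plate_map()] resolving genotypes.
#' @return data.frame with `larva`, `genotype`, `ratio`.
#' @export
normalize_light_activity <- function(windows, x, plate_map) {
  stopifnot(inherits(windows, "opto_windows"))
  geno <- map_genotype(x$larva_ids, plate_map)
  per_trial <- vapply(windows, function(tr) {
    base_tot <- rowSums(x$values[, tr$baseline_idx, drop = FALSE])
    resp_tot <- rowSums(x$values[, tr$response_idx, drop = FALSE])
    base_mean <- tapply(base_tot, geno, mean)
    if (any(base_mean <= 0))
      stop("genotype mean baseline activity is zero; ratio undefined",
           call. = FALSE)
    resp_tot / as.numeric(base_mean[geno])
  }, numeric(length(x$larva_ids)))
  data.frame(larva = x$larva_ids, genotype = geno,
             ratio = rowMeans(as.matrix(per_trial)),
             stringsAsFactors = FALSE)
}

#' Genotype activity as percent of a reference genotype
#'
#' Pools per-larva normalized ratios (optionally across experiments) and
#' expresses each genotype's mean ratio as a percentage of the reference
#' genotype's mean ratio.
#'
#' @param ratios data.frame from [normalize_light_activity()]; rbind
#'   multiple experiments to pool before conversion.
#' @param reference_genotype genotype label serving as 100%.
#' @return data.frame with `genotype`, `n`, `mean_ratio`, `percent`.
#' @export
genotype_percent <- function(ratios, reference_genotype) {
  reference_genotype <- normalize_label(reference_genotype)
  if (!reference_genotype %in% ratios$genotype)
    stop("reference genotype '", reference_genotype,
         "' absent from the data", call. = FALSE)
  m <- tapply(ratios$ratio, ratios$genotype, mean)
  n <- tapply(ratios$ratio, ratios$genotype, length)
  data.frame(genotype = names(m), n = as.integer(n),
             mean_ratio = as.numeric(m),
             percent = 100 * as.numeric(m) / m[[reference_genotype]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Response dynamics: maximum activity A and time-to-maximum T_A
#'
#' Computes, per genotype, the maximum activity A reached during light
#' stimulation and the time T_A from light onset to reach it. The
#' genotype-mean 10-s-bin trace (averaged over larvae and trials,
#' aligned on onset) is smoothed with a centered moving average before
#' taking the maximum; ties are broken by the earliest bin.
#'
#' @param x the 10-s [activity_matrix()].
#' @param windows an `opto_windows` object.
#' @param plate_map a [plate_map()].
#' @param smoothing_bins odd width of the centered moving average
#'   (default 5 bins = 50 s); edge bins use the partial window.
#' @return data.frame with `genotype`, `A` (seconds-active per 10-s bin)
#'   and `T_A_min` (minutes from light onset).
#' @export
response_dynamics <- function(x, windows, plate_map, smoothing_bins = 5) {
  stopifnot(inherits(windows, "opto_windows"))
  if (smoothing_bins %% 2 == 0)
    stop("smoothing_bins must be odd", call. = FALSE)
  geno <- map_genotype(x$larva_ids, plate_map)
  nb <- length(windows[[1L]]$response_idx)
  if (any(vapply(windows, function(tr) length(tr$response_idx), 1L) != nb))
    stop("trials have unequal response-window lengths", call. = FALSE)
  if (nb < smoothing_bins)
    stop("response window shorter than the smoothing kernel", call. = FALSE)
  rel_start <- x$bin_start[windows[[1L]]$response_idx] - windows[[1L]]$onset

  out <- lapply(sort(unique(geno)), function(g) {
    rows <- which(geno == g)
    # mean over larvae and trials, per relative bin
    traces <- vapply(windows, function(tr)
      colMeans(x$values[rows, tr$response_idx, drop = FALSE]), numeric(nb))
    tr_mean <- rowMeans(as.matrix(traces))
    sm <- moving_average(tr_mean, smoothing_bins)
    i_max <- which.max(sm)  # which.max returns the earliest tie
    data.frame(genotype = g, A = sm[i_max],
               T_A_min = (rel_start[i_max] + x$bin_width / 2) / 60,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Centered moving average; edges use the partial window so every bin
## keeps a defined smoothed value.
moving_average <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
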