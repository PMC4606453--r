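#' Construct a set of stimulus-locked calcium imaging trials
#'
#' Holds per-neuron fluorescence time series acquired at a fixed frame
#' rate, with the frame indices at which each stimulation/imaging cycle
#' begins. The standard protocol records a 60-s baseline, then repeats a
#' stimulate-then-image-for-30-s cycle 8 times at 4 Hz; ROI extraction
#' from the movies is upstream of this package.
#'
#' @param traces named list of numeric fluorescence vectors (arbitrary
#'   units, one per neuron).
#' @param markers named list of integer vectors: for each neuron, the
#'   frame index at which each trial's imaging starts (stimulation ends
#'   <0.1 s earlier and is treated as coincident).
#' @param condition named character vector: experimental condition per
#'   neuron (e.g. `"chr2"` vs `"egfp"` control).
#' @param frame_rate acquisition rate in Hz.
#' @return an object of class `calcium_trials`.
#' @export
calcium_trials <- function(traces, markers, condition, frame_rate = 4) {
  stopifnot(is.list(traces), is.list(markers),
            length(traces) == length(markers),
            length(traces) == length(condition))
  if (is.null(names(traces)))
    names(traces) <- paste0("neuron", seq_along(traces))
  names(markers) <- names(traces)
  names(condition) <- names(traces)
  structure(list(traces = traces, markers = markers,
                 condition = condition, frame_rate = frame_rate),
            class = "calcium_trials")
}

#' @export
print.calcium_trials <- function(x, ...) {
  cat("Calcium trial set: ", length(x$traces), " neuron(s), ",
      sum(lengths(x$markers)), " trials at ", x$frame_rate, " Hz (",
      paste(sprintf("%s: %d", names(table(x$condition)),
                    table(x$condition)), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Single-trial stimulus-locked change in fluorescence
#'
#' Computes the percent change in fluorescence for one trial:
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0}, where the baseline \eqn{F_0} is
#' the mean of the `n_baseline` frames immediately preceding the
#' stimulation marker and \eqn{F} the mean of the `n_post` frames from
#' the marker onward (10 frames each at 4 Hz, i.e. 2.5 s).
#'
#' @param values numeric fluorescence trace.
#' @param marker frame index at which post-stimulation imaging starts.
#' @param n_baseline,n_post frames averaged before/after the marker.
#' @return the trial's \eqn{\Delta F/F_0} in percent. Negative values
#'   are retained.
#' @export
dff_trial <- function(values, marker, n_baseline = 10, n_post = 10) {
  if (marker - n_baseline < 1L || marker + n_post - 1L > length(values))
    stop("marker at frame ", marker, " lacks ", n_baseline,
         " baseline or ", n_post, " post frames", call. = FALSE)
  f0 <- mean(values[(marker - n_baseline):(marker - 1L)])
  f <- mean(values[marker:(marker + n_post - 1L)])
  if (f0 <= 0)
    stop("baseline fluorescence F0 = ", f0, " is not positive",
         call. = FALSE)
  100 * (f - f0) / f0
}

#' Per-trial \eqn{\Delta F/F_0} for a whole trial set
#'
#' @param x a [calcium_trials()] object.
#' @param n_baseline,n_post passed to [dff_trial()].
#' @return data.frame with `neuron`, `condition`, `trial`, `dff_pct`.
#' @export
dff_trials <- function(x, n_baseline = 10, n_post = 10) {
  stopifnot(inherits(x, "calcium_trials"))
  rows <- lapply(names(x$traces), function(nm) {
    mk <- x$markers[[nm]]
    data.frame(
      neuron = nm,
      condition = unname(x$condition[nm]),
      trial = seq_along(mk),
      dff_pct = vapply(mk, function(m)
        dff_trial(x$traces[[nm]], m, n_baseline, n_post), numeric(1L)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate \eqn{\Delta F/F_0} across trials
#'
#' Means and standard errors of per-trial \eqn{\Delta F/F_0} values,
#' grouped per neuron or per condition (n counts trials).
#'
#' @param trials data.frame from [dff_trials()] (columns `dff_pct` and
#'   the grouping column).
#' @param grouping grouping column name, `"neuron"` or `"condition"`.
#' @return data.frame with the group label, `n`, `mean_dff_pct`,
#'   `sem_dff_pct`.
#' @export
aggregate_dff <- function(trials, grouping = c("condition", "neuron")) {
  grouping <- match.arg(grouping)
  if (!nrow(trials)) stop("no trials to aggregate", call. = FALSE)
  g <- trials[[grouping]]
  n <- tapply(trials$dff_pct, g, length)
  if (any(n < 2L))
    stop("need >= 2 trials per group for a standard error", call. = FALSE)
  m <- tapply(trials$dff_pct, g, mean)
  s <- tapply(trials$dff_pct, g, stats::sd)
  out <- data.frame(group = names(m), n = as.integer(n),
                    mean_dff_pct = as.numeric(m),
                    sem_dff_pct = as.numeric(s) / sqrt(as.integer(n)),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[1L] <- grouping
  out
}
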