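#' Score tap responses from fine-binned activity
#'
#' A larva responds to a tap if it shows any movement (activity > 0)
#' within `response_window_s` seconds after the stimulus. The window
#' defaults to 5 s, mirroring the 5-s pre-stimulus background window.
#'
#' @param activity_fine an [activity_matrix()] at sub-bin resolution
#'   (typically 1-s bins) covering every response window.
#' @param stim a [stimulus_log()]; only `tap` events are scored.
#' @param response_window_s post-stimulus window length in seconds.
#' @return an object of class `tap_responses`: a list with `responses`
#'   (binary larvae x events matrix), `events` (data.frame of tap time
#'   and power) and `window_s`.
#' @export
score_responses <- function(activity_fine, stim, response_window_s = 5) {
  stopifnot(inherits(activity_fine, "activity_matrix"))
  taps <- stim[stim$kind == "tap", ]
  if (!nrow(taps)) stop("no tap events in the stimulus log", call. = FALSE)
  tt <- taps$time
  if (any(diff(tt) < response_window_s))
    stop("response windows overlap: taps closer than ", response_window_s,
         " s apart", call. = FALSE)
  t0 <- activity_fine$bin_start[1L]
  t_end <- activity_fine$bin_start[length(activity_fine$bin_start)] +
    activity_fine$bin_width
  if (any(tt < t0) || any(tt + response_window_s > t_end))
    stop("tap event(s) outside the recorded range", call. = FALSE)
  resp <- window_any_movement(activity_fine, tt, 0, response_window_s)
  dimnames(resp) <- list(activity_fine$larva_ids, NULL)
  structure(
    list(responses = resp,
         events = data.frame(time = tt,
                             power = as.numeric(taps$payload)),
         window_s = response_window_s),
    class = "tap_responses")
}

## Binary larvae x events matrix: any activity in [t + from, t + to) per
## event time t, resolved on the fine bin grid.
window_any_movement <- function(x, event_times, from, to) {
  w <- x$bin_width
  nbin <- length(x$bin_start)
  t0 <- x$bin_start[1L]
  out <- vapply(event_times, function(t) {
    lo <- ceiling((t + from - t0) / w - 1e-9) + 1L
    hi <- ceiling((t + to - t0) / w - 1e-9)
    lo <- max(lo, 1L); hi <- min(hi, nbin)
    if (hi < lo) return(rep(0L, nrow(x$values)))
    as.integer(rowSums(x$values[, lo:hi, drop = FALSE] > 0) > 0)
  }, integer(nrow(x$values)))
  matrix(out, nrow = nrow(x$values))
}

#' Background movement probability
#'
#' The probability that a larva happens to be moving regardless of the
#' stimulus, estimated as the fraction of all delivered stimuli preceded
#' by movement in the `pre_window_s` seconds before delivery (420 data
#' points per larva in the standard design of 14 tap powers x 30 trials).
#'
#' @inheritParams score_responses
#' @param pre_window_s pre-stimulus window length in seconds.
#' @return named numeric vector, one background probability per larva.
#'   The group-level background used for correction is the mean over
#'   larvae.
#' @export
background_probability <- function(activity_fine, stim, pre_window_s = 5) {
  stopifnot(inherits(activity_fine, "activity_matrix"))
  taps <- stim[stim$kind == "tap", ]
  if (!nrow(taps)) stop("no tap events in the stimulus log", call. = FALSE)
  tt <- taps$time
  t0 <- activity_fine$bin_start[1L]
  if (any(tt - pre_window_s < t0))
    stop("tap event(s) lack a full ", pre_window_s,
         "-s pre-stimulus window", call. = FALSE)
  moved <- window_any_movement(activity_fine, tt, -pre_window_s, 0)
  out <- rowMeans(moved)
  names(out) <- activity_fine$larva_ids
  out
}

#' Background-corrected response table
#'
#' Aggregates scored tap responses per power setting and applies the
#' background correction: corrected response = average response -
#' average background movement. Negative corrected values are retained
#' (clipping would bias the fitted lower asymptote).
#'
#' @param scored a `tap_responses` object from [score_responses()].
#' @param background per-larva background probabilities from
#'   [background_probability()]; their mean is subtracted.
#' @param larvae optionally restrict to a subset of larva ids (e.g. one
#'   genotype group).
#' @return a data.frame of class `tap_response_table` with columns
#'   `power`, `n_trials`, `raw`, `corrected`, sorted by power, plus a
#'   `background` attribute.
#' @export
corrected_response_table <- function(scored, background, larvae = NULL) {
  stopifnot(inherits(scored, "tap_responses"))
  resp <- scored$responses
  if (!is.null(larvae)) {
    resp <- resp[rownames(resp) %in% larvae, , drop = FALSE]
    background <- background[names(background) %in% larvae]
  }
  if (!nrow(resp)) stop("no larvae to aggregate", call. = FALSE)
  b <- mean(background)
  pw <- scored$events$power
  powers <- sort(unique(pw))
  rows <- lapply(powers, function(p) {
    ev <- which(pw == p)
    data.frame(power = p, n_trials = length(ev),
               raw = mean(resp[, ev, drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_trials > 0, ]
  out$corrected <- out$raw - b
  attr(out, "background") <- b
  class(out) <- c("tap_response_table", "data.frame")
  out
}

## Four-parameter logistic in log10(power):
## response(p) = bottom + (top - bottom) / (1 + 10^((log_etp50 - log10 p) * slope))
logistic4 <- function(log10_power, bottom, top, log_etp50, slope) {
  bottom + (top - bottom) / (1 + 10^((log_etp50 - log10_power) * slope))
}

#' Fit a variable-slope log(dose) response curve
#'
#' Ordinary-least-squares fit of the four-parameter logistic
#' \deqn{c(p) = bottom + \frac{top - bottom}{1 + 10^{(\log_{10}ETP_{50} -
#' \log_{10} p)\, h}}}{c(p) = bottom + (top - bottom)/(1 + 10^((log10
#' ETP50 - log10 p) h))}
#' to per-power corrected response fractions, where ETP50 is the
#' effective tap power at which half the maximal response is reached and
#' h the Hill slope. The lower asymptote is fixed at 0 by default since
#' responses are background-corrected; any parameter may be fixed or
#' freed. The sum of squares is minimized from several deterministic
#' starting points spanning the stimulated power range (Nelder-Mead,
#' then BFGS polish); the best converged minimum is kept.
#'
#' @param table a `tap_response_table` (or any data.frame with `power`
#'   and `corrected` columns).
#' @param fix_bottom fix the lower asymptote at this value; `NULL` frees
#'   it.
#' @param fix_top fix the upper asymptote; `NULL` (default) frees it.
#' @param response column of `table` to fit (default `"corrected"`).
#' @param n_starts number of multi-start initializations.
#' @return an object of class `dose_response_fit` with methods `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`. Key fields:
#'   `coefficients` (bottom, top, log_etp50, hill_slope), `etp50`,
#'   `ss_residual`, `df`, `converged`.
#' @examples
#' tb <- data.frame(power = c(1, 2, 3, 5, 9, 16, 30),
#'                  corrected = logistic4(log10(c(1, 2, 3, 5, 9, 16, 30)),
#'                                        0, 0.4, log10(3), 2))
#' fit <- fit_dose_response(tb)
#' coef(fit)["etp50"]
#' @export
fit_dose_response <- function(table, fix_bottom = 0, fix_top = NULL,
                              response = "corrected", n_starts = 5) {
  if (!all(c("power", response) %in% names(table)))
    stop("table needs `power` and `", response, "` columns", call. = FALSE)
  p <- table$power
  y <- table[[response]]
  ok <- is.finite(p) & is.finite(y) & p > 0
  p <- p[ok]; y <- y[ok]
  if (length(unique(p)) < 5L)
    stop("need responses at >= 5 distinct positive powers", call. = FALSE)
  if (diff(range(y)) < 1e-12)
    stop("all responses equal; dose-response fit is degenerate",
         call. = FALSE)
  lp <- log10(p)

  fixed <- c(bottom = NA_real_, top = NA_real_, log_etp50 = NA_real_,
             hill_slope = NA_real_)
  if (!is.null(fix_bottom)) fixed["bottom"] <- fix_bottom
  if (!is.null(fix_top)) fixed["top"] <- fix_top
  free <- names(fixed)[is.na(fixed)]

  obj <- function(theta) {
    par <- fixed
    par[free] <- theta
    sum((y - logistic4(lp, par[1L], par[2L], par[3L], par[4L]))^2)
  }

  starts <- dr_starts(lp, y, fixed, n_starts)
  best <- NULL
  for (s in starts) {
    fit1 <- tryCatch({
      f0 <- stats::optim(s[free], obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      stats::optim(f0$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    if (is.null(fit1)) next
    if (is.null(best) || fit1$value < best$value - 1e-15) best <- fit1
  }
  if (is.null(best))
    stop("dose-response fit failed to converge from any start; powers [",
         min(p), ", ", max(p), "], response range [", min(y), ", ", max(y),
         "]", call. = FALSE)

  par <- fixed
  par[free] <- best$par
  n <- length(y)
  df <- n - length(free)
  if (df < 1L) stop("not enough points for the number of free parameters",
                    call. = FALSE)
  structure(
    list(coefficients = c(par, etp50 = unname(10^par["log_etp50"])),
         etp50 = unname(10^par["log_etp50"]),
         ss_residual = best$value,
         n_points = n, df = df,
         free = free, fixed = fixed[!is.na(fixed)],
         converged = best$convergence == 0,
         data = data.frame(power = p, response = y),
         response_col = response,
         call = match.call()),
    class = "dose_response_fit")
}

## Deterministic multi-start grid: log_etp50 spread over the power range,
## slope over a decade, asymptotes from the data envelope.
dr_starts <- function(lp, y, fixed, n_starts) {
  q <- stats::quantile(lp, probs = seq(0.15, 0.85,
                                       length.out = max(n_starts, 2L)))
  slopes <- rep_len(c(1, 2, 0.5, 4, 8), length(q))
  lapply(seq_along(q), function(i) {
    c(bottom = if (is.na(fixed["bottom"])) min(y) else fixed[["bottom"]],
      top = max(y),
      log_etp50 = unname(q[i]),
      hill_slope = slopes[i])
  })
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  cat("Variable-slope log(dose) response fit (",
      x$n_points, " points, ", length(x$free), " free parameters)\n",
      sep = "")
  print(round(x$coefficients, digits))
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "),
        "\n")
  cat("ETP50 = ", format(x$etp50, digits = digits),
      ";  residual SS = ", format(x$ss_residual, digits = digits),
      " on ", x$df, " df\n", sep = "")
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  out <- object
  out$sigma <- sqrt(object$ss_residual / object$df)
  class(out) <- "summary.dose_response_fit"
  out
}

#' @export
print.summary.dose_response_fit <- function(x, digits = 4, ...) {
  class(x) <- "dose_response_fit"
  print(x, digits = digits)
  cat("residual standard error:", format(x$sigma, digits = digits), "\n")
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  power <- if (is.null(newdata)) object$data$power else newdata$power
  cf <- object$coefficients
  logistic4(log10(power), cf["bottom"], cf["top"], cf["log_etp50"],
            cf["hill_slope"])
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.dose_response_fit <- function(x, ...,
                                   xlab = "tap power (log scale)",
                                   ylab = "corrected response fraction") {
  d <- x$data
  graphics::plot(d$power, d$response, log = "x", xlab = xlab, ylab = ylab,
                 pch = 19, ...)
  pp <- 10^seq(log10(min(d$power)), log10(max(d$power)), length.out = 200)
  graphics::lines(pp, predict(x, data.frame(power = pp)))
  graphics::abline(v = x$etp50, lty = 2)
  invisible(x)
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`; e.g. ETP50 falling from 3.1
#' to 2.1 is a change of -32.3% (a 32% decrease).
#'
#' @param reference reference value (nonzero).
#' @param value new value.
#' @return percent change (negative for a decrease), unrounded.
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be nonzero", call. = FALSE)
  100 * (value - reference) / reference
}

#' Compare two dose-response curves by the extra sum-of-squares F test
#'
#' Tests whether two groups share a dose-response parameter (or the whole
#' curve) by comparing a constrained joint fit against separate fits.
#' `shared = "all"` ties every free parameter (one curve for both
#' groups); `shared = "etp50"` ties only the half-maximal power,
#' `shared = "top"` only the upper asymptote, leaving other parameters
#' group-specific. With SS and df from the nested (shared) and the
#' separate fits,
#' \deqn{F = \frac{(SS_{shared} - SS_{sep})/(df_{shared} - df_{sep})}
#'                {SS_{sep}/df_{sep}}}
#' and p comes from the F distribution.
#'
#' @param table_a,table_b `tap_response_table`s (or data.frames with
#'   `power` and `corrected`) for the two groups.
#' @param shared which parameter(s) the null model shares across groups.
#' @param fix_bottom,fix_top,response,n_starts passed to
#'   [fit_dose_response()].
#' @return an object of class `drc_ftest`: list with `F`, `df_num`,
#'   `df_den`, `p_value`, `shared`, `ss_separate`, `ss_shared`, and the
#'   two separate fits.
#' @export
compare_fits <- function(table_a, table_b,
                         shared = c("all", "etp50", "top"),
                         fix_bottom = 0, fix_top = NULL,
                         response = "corrected", n_starts = 5) {
  shared <- match.arg(shared)
  fit_a <- fit_dose_response(table_a, fix_bottom, fix_top, response,
                             n_starts)
  fit_b <- fit_dose_response(table_b, fix_bottom, fix_top, response,
                             n_starts)
  ss_sep <- fit_a$ss_residual + fit_b$ss_residual
  df_sep <- fit_a$df + fit_b$df

  shared_pars <- switch(shared, all = fit_a$free, etp50 = "log_etp50",
                        top = "top")
  shared_pars <- intersect(shared_pars, fit_a$free)
  if (!length(shared_pars))
    stop("shared parameter(s) are fixed, nothing to tie", call. = FALSE)

  joint <- fit_joint_shared(fit_a, fit_b, shared_pars)
  df_shared <- joint$df
  if (df_shared - df_sep <= 0L)
    stop("nested model has no extra degrees of freedom", call. = FALSE)
  if (ss_sep <= 0)
    stop("separate fits are exact (zero residual SS); F test degenerate",
         call. = FALSE)
  Fstat <- ((joint$ss - ss_sep) / (df_shared - df_sep)) / (ss_sep / df_sep)
  Fstat <- max(Fstat, 0)
  structure(
    list(F = Fstat, df_num = df_shared - df_sep, df_den = df_sep,
         p_value = stats::pf(Fstat, df_shared - df_sep, df_sep,
                             lower.tail = FALSE),
         shared = shared, ss_separate = ss_sep, ss_shared = joint$ss,
         fit_a = fit_a, fit_b = fit_b,
         joint_coefficients = joint$coefficients),
    class = "drc_ftest")
}

#' @export
print.drc_ftest <- function(x, digits = 4, ...) {
  cat("Extra sum-of-squares F test (shared: ", x$shared, ")\n", sep = "")
  cat("  F(", x$df_num, ", ", x$df_den, ") = ", format(x$F, digits = digits),
      ", p = ", format.pval(x$p_value, digits = digits), "\n", sep = "")
  cat("  SS separate = ", format(x$ss_separate, digits = digits),
      ", SS shared = ", format(x$ss_shared, digits = digits), "\n", sep = "")
  invisible(x)
}

## Joint OLS fit of both groups with `shared_pars` tied across groups and
## the remaining free parameters group-specific. Warm-started from the
## separate fits plus the usual deterministic grid.
fit_joint_shared <- function(fit_a, fit_b, shared_pars) {
  free <- fit_a$free
  own <- setdiff(free, shared_pars)
  fixed <- fit_a$fixed

  da <- fit_a$data; db <- fit_b$data
  lpa <- log10(da$power); lpb <- log10(db$power)

  unpack <- function(theta) {
    ns <- length(shared_pars)
    sh <- theta[seq_len(ns)]
    names(sh) <- shared_pars
    pa <- pb <- c(bottom = NA_real_, top = NA_real_, log_etp50 = NA_real_,
                  hill_slope = NA_real_)
    pa[names(fixed)] <- fixed; pb[names(fixed)] <- fixed
    pa[shared_pars] <- sh; pb[shared_pars] <- sh
    if (length(own)) {
      pa[own] <- theta[ns + seq_along(own)]
      pb[own] <- theta[ns + length(own) + seq_along(own)]
    }
    list(a = pa, b = pb)
  }
  obj <- function(theta) {
    p <- unpack(theta)
    sum((da$response - logistic4(lpa, p$a[1L], p$a[2L], p$a[3L],
                                 p$a[4L]))^2) +
      sum((db$response - logistic4(lpb, p$b[1L], p$b[2L], p$b[3L],
                                   p$b[4L]))^2)
  }

  ca <- fit_a$coefficients[free]; cb <- fit_b$coefficients[free]
  mid <- (ca + cb) / 2
  starts <- list(
    c(mid[shared_pars], ca[own], cb[own]),
    c(ca[shared_pars], ca[own], cb[own]),
    c(cb[shared_pars], ca[own], cb[own]))
  best <- NULL
  for (s in starts) {
    fit1 <- tryCatch({
      f0 <- stats::optim(s, obj, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-12))
      stats::optim(f0$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    if (is.null(fit1)) next
    if (is.null(best) || fit1$value < best$value - 1e-15) best <- fit1
  }
  if (is.null(best)) stop("joint constrained fit failed", call. = FALSE)
  n_free <- length(shared_pars) + 2L * length(own)
  list(ss = best$value,
       df = nrow(da) + nrow(db) - n_free,
       coefficients = best$par)
}
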