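#' Define the light/dark schedule of an experiment
#'
#' Larvae are kept on a light/dark cycle (14 h light / 10 h dark by
#' default, lights on at 9:00 and off at 23:00). The schedule anchors the
#' recording's relative time axis (seconds since experiment start) to
#' clock time and names the epochs: "day N" runs from lights-on to
#' lights-off of calendar day N, and "night N" from lights-off on day N
#' to lights-on on day N+1.
#'
#' @param lights_on,lights_off clock times as `"HH:MM"` strings.
#' @param start clock time at which the recording starts.
#' @param first_day calendar day number (days post fertilization) of the
#'   day the recording starts; used only for epoch labels.
#' @return an object of class `epoch_schedule`.
#' @examples
#' sched <- epoch_schedule()  # 14:10 LD, lights on 09:00, off 23:00
#' epoch_table(sched, 48 * 3600)
#' @export
epoch_schedule <- function(lights_on = "09:00", lights_off = "23:00",
                           start = "09:00", first_day = 5L) {
  on_s <- parse_hm(lights_on)
  off_s <- parse_hm(lights_off)
  start_s <- parse_hm(start)
  day_len <- (off_s - on_s) %% 86400
  night_len <- 86400 - day_len
  if (day_len == 0)
    stop("lights_on and lights_off must differ", call. = FALSE)
  structure(
    list(lights_on = on_s, lights_off = off_s, start = start_s,
         day_length = day_len, night_length = night_len,
         first_day = as.integer(first_day)),
    class = "epoch_schedule")
}

parse_hm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1L]]
  if (length(m) != 3L)
    stop("clock time must be 'HH:MM', got: ", x, call. = FALSE)
  3600 * as.numeric(m[2L]) + 60 * as.numeric(m[3L])
}

#' @export
print.epoch_schedule <- function(x, ...) {
  fmt <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)
  cat("Light/dark schedule: lights on ", fmt(x$lights_on), ", off ",
      fmt(x$lights_off), " (", x$day_length / 3600, " h light / ",
      x$night_length / 3600, " h dark); recording starts ", fmt(x$start),
      " on day ", x$first_day, "\n", sep = "")
  invisible(x)
}

#' Enumerate epochs covering a recording
#'
#' @param schedule an [epoch_schedule()].
#' @param duration_s recording length in seconds.
#' @return data.frame with columns `label`, `type` ("day"/"night"),
#'   `start_s`, `end_s` (seconds since experiment start, end exclusive,
#'   clipped to the recording).
#' @export
epoch_table <- function(schedule, duration_s) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  on_s <- schedule$lights_on
  off_s <- schedule$lights_off
  clock0 <- schedule$start

  # Absolute clock seconds (day 0 = midnight of the start day) of every
  # lights transition overlapping [clock0, clock0 + duration_s).
  t_end <- clock0 + duration_s
  days <- seq.int(-1L, ceiling(t_end / 86400) + 1L)
  trans <- data.frame(
    clock = c(days * 86400 + on_s, days * 86400 + off_s),
    type = rep(c("day", "night"), each = length(days)),
    day_no = c(days, days))
  trans <- trans[order(trans$clock), ]

  # The epoch in force at clock0 is the last transition at or before it.
  first <- max(which(trans$clock <= clock0))
  rows <- list()
  i <- first
  while (trans$clock[i] < t_end) {
    s <- max(trans$clock[i], clock0)
    e <- min(trans$clock[i + 1L], t_end)
    day_no <- schedule$first_day + trans$day_no[i]
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste(trans$type[i], day_no),
      type = trans$type[i],
      start_s = s - clock0, end_s = e - clock0,
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  do.call(rbind, rows)
}
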