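#' Construct an activity matrix
#'
#' The universal behavioral input: a per-larva, per-time-bin record of
#' seconds spent moving within each bin, as exported by videotracking
#' systems running in quantization mode. Bins are referenced in seconds
#' since experiment start; clock-time anchoring is supplied separately by
#' an [epoch_schedule()].
#'
#' @param values numeric matrix, one row per larva, one column per bin;
#'   each cell is seconds-active within the bin and must lie in
#'   `[0, bin_width]`.
#' @param larva_ids character vector of unique larva identifiers, one per
#'   row of `values`.
#' @param bin_start numeric vector of bin start times in seconds since
#'   experiment start; strictly increasing with constant spacing equal to
#'   `bin_width`.
#' @param bin_width bin width in seconds (60 for sleep scoring, 10 for
#'   optogenetic assays, 1 for tap-response scoring).
#' @return an object of class `activity_matrix`.
#' @seealso [read_activity_table()], [rebin()]
#' @export
activity_matrix <- function(values, larva_ids, bin_start, bin_width) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  larva_ids <- as.character(larva_ids)
  bin_start <- as.numeric(bin_start)
  bin_width <- as.numeric(bin_width)

  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  if (nrow(values) != length(larva_ids))
    stop("`values` must have one row per larva id", call. = FALSE)
  if (ncol(values) != length(bin_start))
    stop("`values` must have one column per bin start time", call. = FALSE)
  if (anyDuplicated(larva_ids))
    stop("duplicated larva ids: ",
         paste(unique(larva_ids[duplicated(larva_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(bin_start) > 1L) {
    d <- diff(bin_start)
    if (any(d <= 0))
      stop("bin start times must be strictly increasing (first offense at bin ",
           which(d <= 0)[1L] + 1L, ")", call. = FALSE)
    bad <- which(abs(d - bin_width) > 1e-6)
    if (length(bad))
      stop("non-constant bin spacing: bin ", bad[1L] + 1L, " starts ",
           d[bad[1L]], " s after its predecessor; expected ", bin_width,
           call. = FALSE)
  }
  if (anyNA(values))
    stop("activity values contain NA; missing bins are an error, not imputed",
         call. = FALSE)
  out_of_range <- which(values < 0 | values > bin_width, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    cells <- apply(utils::head(out_of_range, 5L), 1L, function(ij)
      paste0("(", larva_ids[ij[1L]], ", bin ", ij[2L], ") = ",
             values[ij[1L], ij[2L]]))
    stop("activity values outside [0, ", bin_width, "]: ",
         paste(cells, collapse = "; "),
         if (nrow(out_of_range) > 5L) " ...", call. = FALSE)
  }

  dimnames(values) <- list(larva_ids, NULL)
  structure(
    list(values = values, larva_ids = larva_ids,
         bin_start = bin_start, bin_width = bin_width),
    class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("Activity matrix: ", length(x$larva_ids), " larvae x ",
      length(x$bin_start), " bins of ", x$bin_width, " s (",
      format(diff(range(x$bin_start)) + x$bin_width, big.mark = ","),
      " s total)\n", sep = "")
  cat("  total activity: ", format(sum(x$values), digits = 6), " s; ",
      format(100 * mean(x$values == 0), digits = 3),
      "% of bins inactive\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.activity_matrix <- function(x, ...) {
  data.frame(
    larva = rep(x$larva_ids, times = length(x$bin_start)),
    time = rep(x$bin_start, each = length(x$larva_ids)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}

#' Column mapping for a delimited activity table
#'
#' Vendor exports differ in column names and delimiters; a dialect names
#' the larva / time / value columns of a long-format table. Times are
#' seconds since experiment start.
#'
#' @param larva,time,value column names in the file.
#' @param sep field delimiter (`","` or `"\t"`).
#' @return a named list used by [read_activity_table()].
#' @export
activity_dialect <- function(larva = "larva", time = "time",
                             value = "value", sep = ",") {
  list(larva = larva, time = time, value = value, sep = sep)
}

#' Read a long-format activity table
#'
#' Reads a delimited per-larva, per-bin activity table (one row per
#' larva-bin pair), validates it and returns an [activity_matrix()].
#' Rows may appear in any order; the result is invariant to row
#' shuffling. The bin width is inferred from the spacing of the time
#' column and verified constant.
#'
#' @param path path to a delimited text file.
#' @param dialect column mapping from [activity_dialect()].
#' @return an `activity_matrix`.
#' @export
read_activity_table <- function(path, dialect = activity_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(dialect[c("larva", "time", "value")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("activity table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[c(need)]
  names(df) <- c("larva", "time", "value")
  activity_from_long(df)
}

## Shared assembly for long-format input (file or in-memory data frame).
activity_from_long <- function(df) {
  df$larva <- as.character(df$larva)
  if (anyDuplicated(df[c("larva", "time")])) {
    dup <- df[duplicated(df[c("larva", "time")]), , drop = FALSE][1L, ]
    stop("duplicated (larva, bin) pair: (", dup$larva, ", t=", dup$time, ")",
         call. = FALSE)
  }
  times <- sort(unique(df$time))
  larvae <- unique(df$larva)
  if (length(times) < 2L)
    stop("need at least two bins to infer bin width", call. = FALSE)
  bin_width <- stats::median(diff(times))
  values <- matrix(NA_real_, nrow = length(larvae), ncol = length(times),
                   dimnames = list(larvae, NULL))
  values[cbind(match(df$larva, larvae), match(df$time, times))] <- df$value
  if (anyNA(values)) {
    ij <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing bin for larva ", larvae[ij[1L]], " at t=", times[ij[2L]],
         "; the tracker emits dense bins and gaps are an error", call. = FALSE)
  }
  activity_matrix(values, larvae, times, bin_width)
}

#' Read a plate map
#'
#' A plate map resolves each well/larva to a genotype and treatment.
#' Genotype and treatment labels are normalized (trimmed, case-folded to
#' lower case) so that spellings differing only in case compare equal.
#'
#' @param path delimited text file with columns `well`, `genotype`,
#'   `treatment`, and optionally `larva` (defaults to the well label) and
#'   `include` (logical, defaults to TRUE).
#' @param sep field delimiter.
#' @return a data.frame of class `plate_map` with columns `well`,
#'   `larva`, `genotype`, `treatment`, `include`.
#' @export
read_plate_map <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  plate_map(df)
}

#' Construct a plate map from a data frame
#'
#' @param df data.frame with at least `well` and `genotype` columns.
#' @return a `plate_map` data.frame.
#' @export
plate_map <- function(df) {
  if (!all(c("well", "genotype") %in% names(df)))
    stop("plate map needs `well` and `genotype` columns", call. = FALSE)
  if (anyDuplicated(df$well))
    stop("duplicate well label(s): ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    well = as.character(df$well),
    larva = as.character(if ("larva" %in% names(df)) df$larva else df$well),
    genotype = normalize_label(df$genotype),
    treatment = if ("treatment" %in% names(df))
      normalize_label(df$treatment) else "none",
    include = if ("include" %in% names(df)) as.logical(df$include) else TRUE,
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$larva))
    stop("duplicate larva id(s) in plate map", call. = FALSE)
  class(out) <- c("plate_map", "data.frame")
  out
}

normalize_label <- function(x) tolower(trimws(as.character(x)))

## Resolve larva ids to one plate-map row each; error on unmapped ids.
map_genotype <- function(larva_ids, plate_map) {
  idx <- match(larva_ids, plate_map$larva)
  if (anyNA(idx))
    stop("larva id(s) not in plate map: ",
         paste(utils::head(larva_ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  plate_map$genotype[idx]
}

#' Read a stimulus event log
#'
#' Events are taps (with a power setting), light transitions, heat-shock
#' boundaries or optogenetic pulses. Tap power settings must lie within
#' the tap driver's representable range, 0.01 to 40.95.
#'
#' @param path delimited file with columns `time` (seconds since
#'   experiment start), `kind`, `payload` (tap power or light color).
#' @param sep field delimiter.
#' @return a data.frame of class `stimulus_log`.
#' @export
read_stimulus_log <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stimulus_log(df)
}

#' Construct a stimulus log from a data frame
#'
#' @param df data.frame with columns `time`, `kind` and optionally
#'   `payload`.
#' @return a `stimulus_log` data.frame sorted by time.
#' @export
stimulus_log <- function(df) {
  kinds <- c("tap", "light_on", "light_off", "heat_shock_start",
             "heat_shock_end", "chr2_pulse")
  if (!all(c("time", "kind") %in% names(df)))
    stop("stimulus log needs `time` and `kind` columns", call. = FALSE)
  bad_kind <- setdiff(unique(df$kind), kinds)
  if (length(bad_kind))
    stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$time)) df <- df[order(df$time), , drop = FALSE]
  if (!"payload" %in% names(df)) df$payload <- NA
  taps <- df$kind == "tap"
  if (any(taps)) {
    p <- suppressWarnings(as.numeric(df$payload[taps]))
    if (anyNA(p))
      stop("tap events must carry a numeric power setting", call. = FALSE)
    if (any(p < 0.01 | p > 40.95))
      stop("tap power setting(s) outside the driver range [0.01, 40.95]: ",
           paste(utils::head(p[p < 0.01 | p > 40.95], 5L), collapse = ", "),
           call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("stimulus_log", "data.frame")
  df
}

#' Write analysis records to delimited text
#'
#' Writes any record data.frame (sleep summaries, fit parameters, response
#' tables) as delimited text with a deterministic column order and full
#' numeric precision, so that reading the file back reproduces the records
#' (doubles round-trip to within 1e-12 relative error).
#'
#' @param rows a data.frame of records.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_summary <- function(rows, path, sep = ",") {
  rows <- as.data.frame(rows)
  num <- vapply(rows, is.double, logical(1L))
  rows[num] <- lapply(rows[num], function(x) {
    out <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
    out[is.na(x)] <- NA
    out
  })
  ok <- tryCatch({
    utils::write.table(rows, path, sep = sep, row.names = FALSE,
                       quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read records written by [write_summary()]
#'
#' @param path path written by [write_summary()].
#' @param sep field delimiter.
#' @return a data.frame.
#' @export
read_summary <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
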