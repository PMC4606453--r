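#' Run an end-to-end analysis pipeline from a config
#'
#' Orchestrates validate -> analyze -> stats for the assays named in a
#' plain-text (YAML) config, writing delimited result tables and a run
#' manifest to an output directory. Outputs are deterministic for fixed
#' inputs and config (timestamps live only in the manifest).
#'
#' Config keys (all paths relative to the config file's directory):
#' \describe{
#'   \item{activity}{long-format activity table (required).}
#'   \item{plate_map}{plate map CSV (required for grouped analyses).}
#'   \item{schedule}{list with `lights_on`, `lights_off`, `start`,
#'     `first_day`.}
#'   \item{events}{stimulus log CSV (arousal/opto).}
#'   \item{assays}{character vector among `"sleep"`, `"arousal"`,
#'     `"opto"`.}
#'   \item{arousal}{list: `window` (s, default 5), `compare_by`
#'     (grouping column, optional), `shared` (F-test null, default
#'     "all").}
#'   \item{opto}{list: `reference` genotype, `smoothing_bins`.}
#'   \item{hs_ratio}{list: `pre`, `post` night labels (optional sleep
#'     add-on).}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named
#'   list (then `base_dir` resolves relative paths).
#' @param out_dir output directory, created if needed.
#' @param base_dir base for relative paths when `config` is a list.
#' @return invisibly, a named list of the result data.frames; files are
#'   written under `out_dir` and listed in `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (is.null(config$activity))
    stop("pipeline stage 'validate': config names no activity table",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  assays <- config$assays %||% "sleep"
  grouped <- any(assays %in% c("opto")) || !is.null(config$hs_ratio) ||
    !is.null(config$arousal$compare_by)
  if (grouped && is.null(config$plate_map))
    stop("pipeline stage 'validate': grouped analysis requested but no ",
         "plate map in config", call. = FALSE)

  act <- stage("validate", read_activity_table(resolve(config$activity)))
  pm <- if (!is.null(config$plate_map))
    stage("validate", read_plate_map(resolve(config$plate_map)))
  ev <- if (!is.null(config$events))
    stage("validate", read_stimulus_log(resolve(config$events)))
  sched <- do.call(epoch_schedule, config$schedule %||% list())

  results <- list()

  if ("sleep" %in% assays) {
    results$sleep_summary <- stage("sleep", {
      m60 <- if (act$bin_width == 60) act else rebin(act, 60)
      sleep_summary(m60, sched)
    })
    write_summary(results$sleep_summary,
                  file.path(out_dir, "sleep_summary.csv"))
    if (!is.null(config$hs_ratio)) {
      results$hs_ratio <- stage("hs-ratio", heat_shock_sleep_change(
        results$sleep_summary, config$hs_ratio$pre, config$hs_ratio$post,
        pm))
      write_summary(results$hs_ratio, file.path(out_dir, "hs_ratio.csv"))
    }
    if (!is.null(pm)) {
      results$sleep_stats <- stage("stats", {
        night <- results$sleep_summary[
          grepl("^night", results$sleep_summary$epoch), ]
        g <- map_genotype(night$larva, pm)
        if (length(unique(g)) >= 2L && all(table(g) >= 2L)) {
          a <- one_way_anova(night$sleep, g)
          data.frame(measure = "night sleep", F = a$F,
                     df_between = a$df_between, df_within = a$df_within,
                     p = a$p_value)
        }
      })
      if (!is.null(results$sleep_stats))
        write_summary(results$sleep_stats,
                      file.path(out_dir, "sleep_stats.csv"))
    }
  }

  if ("arousal" %in% assays) {
    if (is.null(ev))
      stop("pipeline stage 'arousal': no stimulus log in config",
           call. = FALSE)
    w <- config$arousal$window %||% 5
    results$arousal <- stage("arousal", {
      scored <- score_responses(act, ev, response_window_s = w)
      bg <- background_probability(act, ev, pre_window_s = w)
      by <- config$arousal$compare_by
      if (is.null(by)) {
        tb <- corrected_response_table(scored, bg)
        fit <- fit_dose_response(tb)
        list(table = tb, fits = data.frame(
          group = "all", t(coef(fit)), ss_residual = fit$ss_residual))
      } else {
        geno <- map_genotype(rownames(scored$responses), pm)
        groups <- sort(unique(geno))
        tabs <- lapply(groups, function(g) corrected_response_table(
          scored, bg, larvae = rownames(scored$responses)[geno == g]))
        fits <- lapply(tabs, fit_dose_response)
        cmp <- if (length(groups) == 2L)
          compare_fits(tabs[[1L]], tabs[[2L]],
                       shared = config$arousal$shared %||% "all")
        list(table = do.call(rbind, Map(function(tb, g)
          cbind(group = g, tb), tabs, groups)),
          fits = do.call(rbind, Map(function(f, g) data.frame(
            group = g, t(coef(f)), ss_residual = f$ss_residual),
            fits, groups)),
          comparison = cmp)
      }
    })
    write_summary(results$arousal$table,
                  file.path(out_dir, "tap_response_table.csv"))
    write_summary(results$arousal$fits,
                  file.path(out_dir, "dose_response_fits.csv"))
    if (!is.null(results$arousal$comparison)) {
      cmp <- results$arousal$comparison
      write_summary(data.frame(shared = cmp$shared, F = cmp$F,
                               df_num = cmp$df_num, df_den = cmp$df_den,
                               p = cmp$p_value),
                    file.path(out_dir, "dose_response_comparison.csv"))
    }
  }

  if ("opto" %in% assays) {
    if (is.null(ev))
      stop("pipeline stage 'opto': no stimulus log in config",
           call. = FALSE)
    results$opto <- stage("opto", {
      m10 <- if (act$bin_width == 10) act else rebin(act, 10)
      win <- extract_windows(m10, ev)
      ratios <- normalize_light_activity(win, m10, pm)
      ref <- config$opto$reference %||% ratios$genotype[1L]
      list(ratios = ratios,
           percent = genotype_percent(ratios, ref),
           dynamics = response_dynamics(
             m10, win, pm,
             smoothing_bins = config$opto$smoothing_bins %||% 5))
    })
    write_summary(results$opto$ratios,
                  file.path(out_dir, "opto_ratios.csv"))
    write_summary(results$opto$percent,
                  file.path(out_dir, "opto_percent.csv"))
    write_summary(results$opto$dynamics,
                  file.path(out_dir, "opto_dynamics.csv"))
  }

  manifest <- list(
    package = "larvasleep",
    version = as.character(utils::packageVersion("larvasleep")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash(config),
    outputs = list.files(out_dir, pattern = "\\.csv$"),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable hash of the config contents (md5 of its canonical serialization).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
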