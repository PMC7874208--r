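#' Run the full VSR analysis pipeline from a configuration
#'
#' Executes (optional) simulation or trace loading, per-cycle metrics,
#' trial-level temporal statistics and group comparisons, writing
#' `cycles.csv`, one `trial_<larva>.json` per larva, `group_stats.csv` and
#' a plain-text run log into `out_dir`. Any stage error is logged with the
#' larva id and re-raised; partial outputs written up to that point are
#' retained.
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure):
#' \preformatted{
#' seed: 1
#' out_dir: results/run1
#' threshold: 5        # optional, degrees
#' window: 5           # optional, frames
#' startle: 45         # optional, degrees
#' protocol: {frequency: 0.53, amplitude: 75, fps: 30, frames_per_recording: 1280}
#' groups:             # simulation block ...
#'   - {genotype: wildtype, phenotype: wildtype, n: 8}
#'   - {genotype: pcdh15a,  phenotype: null,     n: 8}
#' traces:             # ... or per-larva trace CSV files
#'   - {larva_id: wt_01, genotype: wildtype, file: wt_01.csv}
#' }
#' A `phenotype` entry names a preset (`wildtype`, `null`, `synj1`) or is a
#' list of [phenotype_params()] overrides with a `preset` key.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `metrics` (combined cycle table),
#'   `trials` (per-larva `vsr_trial`s), `stats` (per-metric `vsr_stats`, if
#'   2 genotypes), and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% "vsr_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  logf("vsrquant %s | R %s", as.character(utils::packageVersion("vsrquant")),
       paste(R.version$major, R.version$minor, sep = "."))

  seed <- as.integer(config$seed %||% 1L)
  threshold <- config$threshold %||% 5
  window <- config$window %||% 5L
  startle <- config$startle %||% 45
  proto_args <- config$protocol %||% list()
  protocol <- do.call(stimulus_protocol, proto_args)
  logf("seed=%d threshold=%g window=%d startle=%g", seed, threshold,
       as.integer(window), startle)

  traces <- list()
  if (!is.null(config$groups)) {
    offset <- 0L
    for (g in config$groups) {
      params <- resolve_phenotype(g$phenotype)
      n <- as.integer(g$n)
      co <- simulate_cohort(params, protocol, n, base_seed = seed + offset,
                            genotype = g$genotype)
      offset <- offset + n
      traces <- c(traces, co)
      logf("simulated %d %s larvae (%s phenotype)", n, g$genotype,
           if (is.character(g$phenotype)) g$phenotype else "custom")
    }
  } else if (!is.null(config$traces)) {
    for (tr in config$traces) {
      if (!file.exists(tr$file)) {
        logf("ERROR missing trace file: %s", tr$file)
        stop("trace file not found: ", tr$file, call. = FALSE)
      }
      t0 <- read_trace_csv(tr$file, fps = protocol$fps)
      t0$meta$larva_id <- tr$larva_id
      t0$meta$genotype <- tr$genotype
      t0$meta$protocol <- protocol
      traces[[tr$larva_id]] <- t0
      logf("loaded trace %s (%s)", tr$larva_id, tr$genotype)
    }
  } else {
    stop("config needs a `groups` simulation block or a `traces` list",
         call. = FALSE)
  }

  tables <- list(); trials <- list()
  for (id in names(traces)) {
    tb <- tryCatch(
      cycle_metrics_table(traces[[id]], threshold, window, startle),
      error = function(e) {
        logf("ERROR larva %s at metrics stage: %s", id, conditionMessage(e))
        stop("larva ", id, ": ", conditionMessage(e), call. = FALSE)
      })
    tables[[id]] <- tb
    trials[[id]] <- tryCatch(
      summarize_trial(traces[[id]], protocol, threshold, window, startle),
      error = function(e) {
        logf("ERROR larva %s at temporal stage: %s", id, conditionMessage(e))
        stop("larva ", id, ": ", conditionMessage(e), call. = FALSE)
      })
    write_trial_json(trials[[id]], file.path(out_dir, paste0("trial_", id, ".json")))
  }
  metrics <- do.call(rbind, tables)
  rownames(metrics) <- NULL
  cycles_path <- file.path(out_dir, "cycles.csv")
  utils::write.csv(metrics, cycles_path, row.names = FALSE, quote = FALSE)
  logf("wrote %s (%d rows)", cycles_path, nrow(metrics))

  genos <- vapply(traces, function(tr) tr$meta$genotype, character(1))
  stats_res <- NULL
  if (length(unique(genos)) == 2L) {
    gt <- group_table(tables, genos)
    stats_res <- lapply(unique(gt$metric), function(mm) compare_groups(gt, mm))
    names(stats_res) <- unique(gt$metric)
    stats_df <- do.call(rbind, lapply(stats_res, function(s) {
      data.frame(metric = s$metric, s$per_cycle,
                 F_genotype = s$omnibus$F[1L], p_genotype = s$omnibus$p[1L])
    }))
    rownames(stats_df) <- NULL
    stats_path <- file.path(out_dir, "group_stats.csv")
    utils::write.csv(stats_df, stats_path, row.names = FALSE, quote = FALSE)
    logf("wrote %s", stats_path)
  } else {
    logf("skipping group stats (%d genotype(s))", length(unique(genos)))
  }
  logf("pipeline complete: %d larvae", length(traces))
  invisible(list(metrics = metrics, trials = trials, stats = stats_res,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a config phenotype entry (preset name or list of overrides) onto
# phenotype_params().
resolve_phenotype <- function(ph) {
  if (inherits(ph, "vsr_phenotype")) return(ph)
  if (is.character(ph)) {
    return(switch(ph,
                  wildtype = phenotype_wildtype(),
                  "null" = phenotype_null(),
                  synj1 = phenotype_synj1(),
                  stop("unknown phenotype preset: ", ph, call. = FALSE)))
  }
  if (is.list(ph)) {
    preset <- ph$preset %||% "wildtype"
    ph$preset <- NULL
    base <- switch(preset,
                   wildtype = phenotype_wildtype,
                   "null" = phenotype_null,
                   synj1 = phenotype_synj1,
                   stop("unknown phenotype preset: ", preset, call. = FALSE))
    return(do.call(base, ph))
  }
  stop("cannot interpret phenotype entry", call. = FALSE)
}
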