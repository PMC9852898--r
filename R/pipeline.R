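SCHEMA_VERSION <- "nwlchoice-schema-1"

# tabular outputs carry a schema-version comment line above the header
write_csv_s <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSION), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
}

read_csv_s <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

config_error <- function(msg) {
  stop(structure(class = c("nwl_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a study configuration from a YAML file
#'
#' The file mirrors the [study_config()] fields by name; omitted fields
#' take their defaults. `ddm_truth` is given as a list of records with
#' `context`, `nwl_shown`, `boundary_sep`, `non_decision`, `bias`, `drift`.
#'
#' @param path Path to the YAML configuration.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path))
    config_error(sprintf("configuration file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_participants", "pairs_per_combo", "timeout", "rng_seed",
               "nwl_gradient"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$contexts)) args$contexts <- unlist(y$contexts)
  if (!is.null(y$ddm_truth)) {
    args$ddm_truth <- do.call(rbind, lapply(y$ddm_truth, function(r)
      data.frame(context = r$context, nwl_shown = isTRUE(r$nwl_shown),
                 boundary_sep = r$boundary_sep,
                 non_decision = r$non_decision, bias = r$bias,
                 drift = r$drift, stringsAsFactors = FALSE)))
  }
  if (!is.null(y$rating_model))
    args$rating_model <- do.call(rating_model, y$rating_model)
  if (!is.null(y$contamination))
    args$contamination <- do.call(contamination_rates, y$contamination)
  if (!is.null(y$sampling_rate))
    args$sampling_rate <- unlist(y$sampling_rate)
  if (!is.null(y$between_sd)) args$between_sd <- unlist(y$between_sd)
  tryCatch(do.call(study_config, args),
           error = function(e) config_error(conditionMessage(e)))
}

#' Write a study configuration to YAML
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  y <- list(
    n_participants = config$n_participants, contexts = config$contexts,
    pairs_per_combo = config$pairs_per_combo, timeout = config$timeout,
    rng_seed = config$rng_seed, nwl_gradient = config$nwl_gradient,
    ddm_truth = lapply(seq_len(nrow(config$ddm_truth)), function(i)
      as.list(config$ddm_truth[i, ])),
    rating_model = unclass(config$rating_model),
    contamination = unclass(config$contamination),
    sampling_rate = as.list(config$sampling_rate),
    between_sd = as.list(config$between_sd))
  yaml::write_yaml(y, path)
  invisible(path)
}

write_manifest <- function(out_dir, config, seeds, stage) {
  files <- list.files(out_dir, pattern = "\\.(csv|json|yaml)$",
                      full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    stage = stage,
    schema = SCHEMA_VERSION,
    seeds = seeds,
    config = if (is.null(config)) NULL else list(
      n_participants = config$n_participants,
      pairs_per_combo = config$pairs_per_combo,
      timeout = config$timeout, rng_seed = config$rng_seed),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))),
    written_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic study to disk
#'
#' Runs [simulate_study()] from a YAML configuration and writes
#' `trials.csv`, `paths.csv`, `ratings.csv`, `participants.csv`,
#' `truth.json` and a run manifest (with file digests) to `out_dir`.
#'
#' @param config_path Path to the YAML configuration, or a
#'   [study_config()] object.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional master-seed override.
#' @return The simulated study, invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir, seed = NULL) {
  config <- if (inherits(config_path, "study_config")) config_path
    else read_study_config(config_path)
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  write_csv_s(study$trials, file.path(out_dir, "trials.csv"))
  write_csv_s(study$paths, file.path(out_dir, "paths.csv"))
  write_csv_s(study$ratings, file.path(out_dir, "ratings.csv"))
  write_csv_s(study$participants, file.path(out_dir, "participants.csv"))
  truth <- study$truth
  truth$contamination <- unclass(truth$contamination)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_study_config(config, file.path(out_dir, "config.yaml"))
  write_manifest(out_dir, config, list(master = config$rng_seed),
                 stage = "simulate")
  invisible(study)
}

stage_inputs <- list(
  metrics = c("trials.csv", "paths.csv"),
  qc      = c("metrics.csv", "ratings.csv"),
  fit     = c("retained.csv"),
  recover = c("fits.csv"),
  analyze = c("retained.csv"))

stage_order <- c("metrics", "qc", "fit", "recover", "analyze")

#' Run pipeline stages over a simulated (or imported) study directory
#'
#' Executes the requested stages in dependency order, reading each input
#' from `out_dir` when an earlier stage of the same run produced it, else
#' from `in_dir`. Stage outputs: `metrics.csv`; `retained.csv` and
#' `exclusions.json`; `fits.csv`; `recovery.csv` and
#' `recovery_summary.json`; `analysis_summary.json` plus per-table CSVs.
#' A manifest with file digests is rewritten after the run.
#'
#' @param stages Subset of `c("metrics", "qc", "fit", "recover",
#'   "analyze")`.
#' @param in_dir Directory holding the upstream inputs (e.g. the
#'   [cmd_simulate()] output).
#' @param out_dir Output directory; defaults to `in_dir`.
#' @param seed Master seed for the stochastic stages (bootstrap, recovery);
#'   per-stage seeds are derived from it by stage-name hashing.
#' @param n_sets,n_rt Recovery draw count and simulated trials per draw.
#' @param fit_settings [ddm_fit_settings()] for the fitting stages.
#' @param verbose Print per-stage progress counts.
#' @return Named list of stage results, invisibly.
#' @export
cmd_run <- function(stages, in_dir, out_dir = in_dir, seed = 1L,
                    n_sets = 1000L, n_rt = 128L,
                    fit_settings = ddm_fit_settings(), verbose = FALSE) {
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  stages <- stage_order[stage_order %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  find_input <- function(fname, stage) {
    for (d in unique(c(out_dir, in_dir))) {
      p <- file.path(d, fname)
      if (file.exists(p)) return(p)
    }
    producers <- c(metrics.csv = "metrics", retained.csv = "qc",
                   fits.csv = "fit", trials.csv = "simulate",
                   paths.csv = "simulate", ratings.csv = "simulate")
    stop(sprintf(
      "stage '%s' needs %s; run stage '%s' first", stage, fname,
      producers[[fname]] %||% "an upstream stage"), call. = FALSE)
  }
  results <- list()

  if ("metrics" %in% stages) {
    trials <- read_csv_s(find_input("trials.csv", "metrics"))
    paths <- read_csv_s(find_input("paths.csv", "metrics"))
    metrics <- compute_trial_metrics(trials, paths)
    write_csv_s(metrics, file.path(out_dir, "metrics.csv"))
    say("metrics: %d trials in, %d with paths", nrow(trials), nrow(metrics))
    results$metrics <- metrics
  }
  if ("qc" %in% stages) {
    metrics <- results$metrics %||% read_csv_s(find_input("metrics.csv", "qc"))
    rec_path <- tryCatch(find_input("ratings.csv", "qc"),
                         error = function(e) NULL)
    recognition <- if (is.null(rec_path)) NULL else read_csv_s(rec_path)
    flt <- apply_trial_filters(metrics, recognition)
    write_csv_s(flt$retained, file.path(out_dir, "retained.csv"))
    jsonlite::write_json(
      list(report = flt$report, n_total = flt$n_total,
           n_retained = nrow(flt$retained)),
      file.path(out_dir, "exclusions.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    say("qc: %d/%d retained", nrow(flt$retained), flt$n_total)
    results$qc <- flt
  }
  if ("fit" %in% stages) {
    retained <- results$qc$retained %||%
      read_csv_s(find_input("retained.csv", "fit"))
    fits <- fit_all_conditions(retained, fit_settings)
    write_csv_s(fits, file.path(out_dir, "fits.csv"))
    say("fit: %d conditions, %d converged", nrow(fits),
        sum(isTRUE_vec(fits$converged)))
    results$fits <- fits
  }
  if ("recover" %in% stages) {
    fits <- results$fits %||% read_csv_s(find_input("fits.csv", "recover"))
    summaries <- list()
    rec_rows <- list()
    key <- interaction(fits$context, fits$nwl_shown, drop = TRUE)
    with_seed(derive_seed(seed, "recover"), {
      for (lv in levels(key)) {
        cf <- fits[key == lv & isTRUE_vec(fits$converged), ]
        cond <- list(context = cf$context[1], nwl_shown = cf$nwl_shown[1])
        if (nrow(cf) < 5L) {
          summaries[[lv]] <- c(cond, list(skipped = "fewer than 5 fits"))
          next
        }
        pop <- fit_param_population(cf)
        rec <- run_recovery(pop, n_sets = n_sets, n_rt = n_rt,
                            settings = fit_settings)
        fl <- flag_outlier_params(cf, rec)
        r <- recovery_correlation(rec)
        summaries[[lv]] <- c(cond, list(
          n_source = pop$n_source, n_sets = n_sets, n_rt = n_rt,
          n_failed_refits = rec$n_failed, n_clamped_draws = rec$n_clamped,
          pearson_r = as.list(r),
          quantile_bounds = as.data.frame(fl$bounds),
          n_flagged_source = sum(fl$any_flag)))
        rec_rows[[lv]] <- data.frame(
          context = cond$context, nwl_shown = cond$nwl_shown,
          draw = seq_len(n_sets), rec$draws,
          refit = rec$refits, valid = rec$valid)
      }
    })
    if (length(rec_rows))
      write_csv_s(do.call(rbind, rec_rows),
                  file.path(out_dir, "recovery.csv"))
    jsonlite::write_json(unname(summaries),
                         file.path(out_dir, "recovery_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    say("recover: %d conditions", length(summaries))
    results$recovery <- summaries
  }
  if ("analyze" %in% stages) {
    retained <- results$qc$retained %||%
      read_csv_s(find_input("retained.csv", "analyze"))
    sd1 <- derive_seed(seed, "analyze")
    probs <- healthy_choice_prob(retained,
                                 grouping = c("context", "nwl_shown"),
                                 seed = sd1)
    paired <- pair_trials(retained)
    census <- decision_path_census(paired)
    rev <- reversal_probability(paired, seed = sd1)
    deltas <- compute_deltas(paired)
    d_auc <- delta_summary(deltas, "auc", seed = sd1)
    d_rt <- delta_summary(deltas, "rt", seed = sd1)
    dnwl <- delta_nwl_effect(retained, seed = sd1)
    write_csv_s(probs, file.path(out_dir, "probabilities.csv"))
    write_csv_s(census, file.path(out_dir, "path_census.csv"))
    write_csv_s(d_auc, file.path(out_dir, "deltas_auc.csv"))
    write_csv_s(d_rt, file.path(out_dir, "deltas_rt.csv"))
    write_csv_s(dnwl, file.path(out_dir, "delta_nwl.csv"))
    jsonlite::write_json(
      list(estimator = "pooled proportions/means with participant-cluster percentile bootstrap (2000 resamples)",
           healthy_choice_prob = probs, reversal_probability = rev,
           path_census = census, delta_auc = d_auc, delta_rt = d_rt,
           delta_nwl = dnwl,
           n_incomplete_pairs = attr(paired, "n_incomplete")),
      file.path(out_dir, "analysis_summary.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    say("analyze: %d retained trials, %d paired", nrow(retained),
        nrow(paired))
    results$analysis <- list(probs = probs, reversal = rev, census = census,
                             delta_auc = d_auc, delta_rt = d_rt,
                             delta_nwl = dnwl)
  }
  cfg_path <- file.path(in_dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) read_study_config(cfg_path) else NULL
  write_manifest(out_dir, cfg, list(master = seed), stage = "run")
  invisible(results)
}
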