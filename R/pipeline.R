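#' Pipeline configuration
#'
#' Bundles the inputs and knobs of [run_pipeline()]. Sessions are either
#' paths to HDF5 session files or [sim_config()] objects (generated on the
#' fly). Every stochastic stage derives its own seed from the master seed
#' and a stage name via [derive_seed()], so results are reproducible from
#' `(config, seed)` alone.
#'
#' @param sessions List of file paths and/or `sim_config` objects.
#' @param out_dir Output directory for CSV tables, the JSON summary and the
#'   log; `NULL` to skip writing.
#' @param threshold_run,threshold_stat Running-label thresholds, cm/s.
#' @param n_perm Permutations for the PC-running correlation test.
#' @param n_boot Bootstrap resamples for modulation inference.
#' @param l2_grid,smooth_z Gain-model hyperparameters.
#' @param fit_gain_model Whether to fit the gain model per session.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sessions, out_dir = NULL, threshold_run = 3,
                       threshold_stat = 1, n_perm = 1000, n_boot = 2000,
                       l2_grid = 10^seq(-4, -1), smooth_z = 1e-3,
                       fit_gain_model = TRUE, seed = 1L) {
  if (length(sessions) == 0) stop("usage error: empty session list")
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror [run_config()]; entries under
#' `sessions:` are either file paths (strings) or mappings of
#' [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sessions <- lapply(y$sessions, function(s) {
    if (is.character(s)) s else do.call(sim_config, s)
  })
  y$sessions <- sessions
  do.call(run_config, y)
}

analyze_one_session <- function(session, truth, cfg, seed) {
  rates <- trial_rates(session)
  labels <- split_by_running(session, cfg$threshold_run, cfg$threshold_stat)
  curves <- compute_tuning(rates, session)
  pc <- first_neural_pc(rates)
  corr <- permutation_correlation(pc$pc1, session$running_speed,
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(seed, "perm"))
  mod_all <- unit_modulation(session, rates, labels, curves,
                             scope = "all_stimuli", n_boot = cfg$n_boot,
                             seed = derive_seed(seed, "mod-all"))
  agg_all <- aggregate_modulation(mod_all, n_boot = cfg$n_boot,
                                  seed = derive_seed(seed, "agg-all"))
  tuned <- vapply(curves, function(tc) tc$tuned, logical(1))
  mod_pref <- unit_modulation(session, rates, labels, curves,
                              scope = "preferred_stimulus", n_boot = cfg$n_boot,
                              seed = derive_seed(seed, "mod-pref"))
  gain <- NULL
  if (cfg$fit_gain_model) {
    design <- build_design(session)
    split <- speckled_split(n_trials(session), n_units(session),
                            seed = derive_seed(seed, "split"))
    gain <- fit_gain(session, design, split, l2_grid = cfg$l2_grid,
                     smooth_z = cfg$smooth_z, labels = labels,
                     seed = derive_seed(seed, "gain"))
  }
  eye <- NULL
  if (!is.null(session$saccade_times)) {
    feats <- eye_features(session, labels)
    eye <- list(
      comparison = eye_state_comparison(feats, labels, n_boot = cfg$n_boot,
                                        seed = derive_seed(seed, "eye")),
      saccade_prediction = saccade_rate_prediction(rates, feats, labels))
  }
  z_recovery <- if (!is.null(truth) && !is.null(gain) &&
                    stats::sd(truth$z_true) > 0)
    stats::cor(gain$params$z, truth$z_true) else NA_real_
  list(session_id = session$session_id, species = session$species,
       labels = labels, curves = curves, pc = pc, corr = corr,
       modulation_all = mod_all, aggregate_all = agg_all,
       modulation_preferred = mod_pref, tuned = tuned, gain = gain,
       eye = eye, z_recovery = z_recovery)
}

session_row <- function(res, session, labels) {
  frac_run <- mean(labels$label == "running")
  data.frame(
    session_id = res$session_id, species = res$species,
    n_trials = n_trials(session), n_units = n_units(session),
    frac_running = frac_run, r = res$corr$r, p = res$corr$p,
    significant = res$corr$significant,
    geomean_ratio_all = res$aggregate_all$geometric_mean,
    median_r2_baseline = if (is.null(res$gain)) NA_real_ else res$gain$result$session_r2$baseline,
    median_r2_gain = if (is.null(res$gain)) NA_real_ else res$gain$result$session_r2$gain,
    gain_sd = if (is.null(res$gain)) NA_real_ else res$gain$result$gain_sd,
    gain_diff_running = if (is.null(res$gain)) NA_real_ else res$gain$result$gain_diff_running,
    reverted = if (is.null(res$gain)) NA else res$gain$result$reverted_to_init,
    n_beat_null = if (is.null(res$gain)) NA_integer_ else res$gain$result$n_beat_null,
    gain_included = if (is.null(res$gain)) NA else res$gain$result$n_beat_null >= 10)
}

unit_rows <- function(res) {
  m <- res$modulation_all
  osis <- vapply(res$curves, function(tc) tc$osi, numeric(1))
  data.frame(session_id = res$session_id, species = res$species,
             unit_id = m$unit_id, osi = osis[m$unit_id],
             tuned = res$tuned[m$unit_id],
             rate_running = m$rate_run, rate_stationary = m$rate_stat,
             ratio = m$ratio,
             significant = m$significant_increase | m$significant_decrease)
}

#' Run the full species-comparison workflow
#'
#' For every session: inclusion filters, tuning curves and OSIs, running
#' labels, first-PC correlation with running (permutation significance),
#' unit-level modulation ratios, the shared-gain model fit, and eye-movement
#' analyses where eye data exist. Across species groups it then compares
#' per-session correlations, unit log-ratios, gain standard deviations and
#' running gain differences with Mann-Whitney tests. A session failing any
#' stage is marked failed and the pipeline continues; the call errors only
#' if every session fails. With an output directory set, writes
#' `session_table.csv`, `unit_table.csv`, `summary.json` and `pipeline.log`.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: `session_table`, `unit_table`,
#'   `per_session` (full per-session results), `group_comparisons`,
#'   `failed`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (length(cfg$sessions) == 0) stop("usage error: empty session list")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  per_session <- list()
  session_tab <- list()
  unit_tab <- list()
  failed <- character(0)
  for (k in seq_along(cfg$sessions)) {
    src <- cfg$sessions[[k]]
    seed_k <- derive_seed(cfg$seed, paste0("session-", k))
    res <- tryCatch({
      if (is.character(src)) {
        session <- read_session(src)
        truth <- NULL
      } else {
        sim <- generate_session(src)
        session <- sim$session
        truth <- sim$truth
      }
      labels <- split_by_running(session, cfg$threshold_run, cfg$threshold_stat)
      filt <- filter_sessions(list(session), list(labels))
      if (!filt$included[1]) {
        note("session %s excluded: %s", session$session_id, filt$reason[1])
        NULL
      } else {
        note("session %s: analyzing with stage seed %d", session$session_id, seed_k)
        out <- analyze_one_session(session, truth, cfg, seed_k)
        session_tab[[length(session_tab) + 1]] <- session_row(out, session, labels)
        unit_tab[[length(unit_tab) + 1]] <- unit_rows(out)
        out
      }
    }, error = function(e) {
      note("session %d FAILED: %s", k, conditionMessage(e))
      failed <<- c(failed, sprintf("session-%d: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) per_session[[length(per_session) + 1]] <- res
  }
  if (length(per_session) == 0)
    stop("all sessions failed or were excluded: ",
         paste(failed, collapse = "; "))
  session_table <- do.call(rbind, session_tab)
  unit_table <- do.call(rbind, unit_tab)

  group_comparisons <- NULL
  spp <- unique(session_table$species)
  if (length(spp) == 2) {
    a <- session_table$species == spp[1]
    cmp <- function(v) tryCatch(compare_groups(v[a], v[!a]),
                                error = function(e) NULL)
    gi <- if (all(is.na(session_table$gain_included))) rep(TRUE, nrow(session_table))
          else !is.na(session_table$gain_included) & session_table$gain_included
    lr_by_sp <- split(log(unit_table$ratio[!is.na(unit_table$ratio)]),
                      unit_table$species[!is.na(unit_table$ratio)])
    group_comparisons <- list(
      species = spp,
      correlation = cmp(session_table$r),
      gain_sd = tryCatch(compare_groups(session_table$gain_sd[a & gi],
                                        session_table$gain_sd[!a & gi]),
                         error = function(e) NULL),
      gain_diff = tryCatch(compare_groups(session_table$gain_diff_running[a & gi],
                                          session_table$gain_diff_running[!a & gi]),
                           error = function(e) NULL),
      log_ratio = tryCatch(compare_groups(lr_by_sp[[spp[1]]], lr_by_sp[[spp[2]]]),
                           error = function(e) NULL))
  }
  report <- structure(list(session_table = session_table,
                           unit_table = unit_table,
                           per_session = per_session,
                           group_comparisons = group_comparisons,
                           failed = failed, log = log_lines),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$session_table,
                   file.path(out_dir, "session_table.csv"), row.names = FALSE)
  utils::write.csv(report$unit_table,
                   file.path(out_dir, "unit_table.csv"), row.names = FALSE)
  summary <- list(n_sessions = nrow(report$session_table),
                  n_failed = length(report$failed),
                  group_comparisons = report$group_comparisons)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
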