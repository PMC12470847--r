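# End-to-end orchestration: config validation, seeding, and the
# simulate -> fit -> QC -> stats (+ behaviour) chain with a
# machine-readable summary.

#' Default pipeline configuration
#'
#' Nested sections for the fMRI arm (a [sim_config()]), the search grid,
#' and the behavioural arm. Override any subset via `validate_config()`.
#'
#' @param fmri a [sim_config()].
#' @param grid list of [prf_search_grid()] arguments.
#' @param behaviour list: `n_participants`, `n_sessions`, `observer`.
#' @param run_behaviour include the psychophysics arm.
#' @return list of class `pipeline_config`.
#' @export
default_config <- function(fmri = sim_config(),
                           grid = list(),
                           behaviour = list(n_participants = 10,
                                            n_sessions = 3,
                                            observer = observer_model()),
                           run_behaviour = TRUE) {
  structure(list(fmri = fmri, grid = grid, behaviour = behaviour,
                 run_behaviour = run_behaviour),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown sections or grid arguments, odd run counts, and
#' negative noise; returns the validated config.
#'
#' @param config a list or `pipeline_config`.
#' @return validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  known <- c("fmri", "grid", "behaviour", "run_behaviour")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config sections: ", paste(unknown, collapse = ", "))
  base <- default_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  validate_sim_config(base$fmri)
  grid_args <- c("n_ecc", "n_angle", "n_sigma", "max_ecc", "sigma_range")
  bad <- setdiff(names(base$grid), grid_args)
  if (length(bad) > 0)
    stop("unknown grid arguments: ", paste(bad, collapse = ", "))
  if (!is.null(base$behaviour$observer) &&
      !inherits(base$behaviour$observer, "observer_model"))
    stop("behaviour$observer must be an observer_model")
  base
}

#' Run the full analysis pipeline
#'
#' Simulates the dataset, fits every vertex and condition, applies the
#' vertex filter, computes per-participant Mood's tests, the binned H - L
#' size-difference profile, and (optionally) the behavioural arm, and
#' writes CSV tables plus a `summary.json` when `out_dir` is given.
#'
#' @param config a [default_config()]; validated before use.
#' @param seed root seed; every stage derives its own sub-seed.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param progress print stage progress.
#' @return list: `dataset` config echo, `fits`, `qc`, `summary_by_participant`,
#'   `profile`, `behaviour`, and `summary` (the JSON-serialisable digest:
#'   median sigma per condition and ROI, the direction flag
#'   `sigma_high_gt_low`, recovery RMSE against the oracle truth, and
#'   behavioural aftereffect recovery).
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = NULL, progress = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (progress) message(sprintf(...))

  say("stage simulate: %d participants x %d vertices",
      config$fmri$n_participants, config$fmri$n_vertices)
  dataset <- simulate_fmri_dataset(config$fmri, seed)
  say("stage fit: %d vertex-conditions", 2 * nrow(dataset$vertices))
  grid_df <- do.call(prf_search_grid, config$grid)
  fits <- fit_dataset(dataset, grid_df, progress = progress)
  qc <- filter_vertices(fits)
  kept <- qc[qc$keep, ]
  say("stage qc: kept %d / %d vertex-conditions", nrow(kept), nrow(qc))

  summary_tab <- group_summary(kept, by_roi = TRUE)
  profiles <- lapply(split(kept, kept$participant), function(g) {
    d <- size_difference(g[g$condition == "high_adapted", ],
                         g[g$condition == "low_adapted", ])
    sliding_bins(d$ecc, d$diff)
  })
  profile <- group_profile(profiles)

  behaviour <- NULL
  if (isTRUE(config$run_behaviour)) {
    say("stage behaviour: %d participants x %d sessions",
        config$behaviour$n_participants, config$behaviour$n_sessions)
    btrials <- simulate_behaviour_experiment(
      config$behaviour$n_participants, config$behaviour$n_sessions,
      config$behaviour$observer, seed)
    behaviour <- analyze_behaviour(btrials)
  }

  ok_truth <- kept[is.finite(kept$truth_sigma), ]
  med_by <- aggregate(kept$sigma,
                      by = list(roi = kept$roi, condition = kept$condition),
                      FUN = median)
  names(med_by)[3] <- "median_sigma"
  valid_bins <- profile$mean[!is.na(profile$mean)]
  summary <- list(
    seed = seed,
    n_vertex_conditions = nrow(qc),
    n_kept = nrow(kept),
    median_sigma = med_by,
    sigma_high_gt_low = all(
      med_by$median_sigma[med_by$condition == "high_adapted"] >
        med_by$median_sigma[med_by$condition == "low_adapted"]),
    participants_high_gt_low = sum(tapply(
      summary_tab$median_diff, summary_tab$participant, function(d) all(d > 0))),
    prop_bins_above_zero = if (length(valid_bins)) mean(valid_bins > 0) else NA,
    recovery_rmse = if (nrow(ok_truth))
      sqrt(mean((ok_truth$sigma - ok_truth$truth_sigma)^2)) else NA
  )
  if (!is.null(behaviour)) {
    g <- behaviour$group
    summary$aftereffect_pct <- setNames(
      g$mean_pct[g$family == "raw"], g$condition[g$family == "raw"])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(dataset$vertices, file.path(out_dir, "truth.csv"),
              row.names = FALSE)
    write.csv(qc, file.path(out_dir, "fits_qc.csv"), row.names = FALSE)
    write.csv(summary_tab, file.path(out_dir, "participant_tests.csv"),
              row.names = FALSE)
    write.csv(profile, file.path(out_dir, "difference_profile.csv"),
              row.names = FALSE)
    if (!is.null(behaviour)) {
      write.csv(behaviour$participants, file.path(out_dir, "behaviour.csv"),
                row.names = FALSE)
      write.csv(behaviour$group, file.path(out_dir, "behaviour_group.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(list(dataset_cfg = config$fmri, fits = fits, qc = qc,
                 summary_by_participant = summary_tab, profile = profile,
                 behaviour = behaviour, summary = summary))
}
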