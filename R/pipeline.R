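## Reproducible orchestration of the analysis stages: each run takes a
## config, writes its outputs plus a manifest (parameters, seed, package
## version, input digests), and cleans up partial outputs on failure.
## A thin command-line wrapper around run_pipeline() is installed at
## inst/cli/flocknet.R.

#' Run one pipeline stage reproducibly
#'
#' Subcommands mirror the analysis stages:
#' * `simulate` -- [simulate_flock()]; writes `flock.csv`, `survey.csv`,
#'   `truth.json`. Parameters: any [simulation_config()] argument.
#' * `accuracy` -- [fence_error()] + [error_histogram()]; needs
#'   `trajectory` and `survey` file parameters, optional `bin_width`;
#'   writes `errors.csv`, `histogram.csv`.
#' * `leaders` -- [movement_leaders()]; needs `data`; optional `interval`,
#'   `move_threshold`, `separation_threshold`, `tie_window`, `smooth`;
#'   writes `ranks.csv`, `scores.csv`.
#' * `network` -- [group_times()] + [nearest_neighbour_edges()] +
#'   [neighbour_counts()]; needs `data`; optional `bin`, `threshold`;
#'   writes `edges.csv`, `counts.csv`.
#' * `sampling` -- [compare_regimes()]; needs `data`; optional `regimes`
#'   (spec string such as `"continuous:5,single:300,burst:60/240"`) and
#'   `thresholds` (numeric vector or comma string); writes
#'   `comparison.csv`.
#' * `demo` -- simulate then run every stage on the simulated data.
#'
#' @param subcommand one of `"simulate"`, `"accuracy"`, `"leaders"`,
#'   `"network"`, `"sampling"`, `"demo"`.
#' @param params named list of stage parameters (see above).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used for any
#'   randomness in the stage.
#' @return invisibly, the manifest list; side effect: output files plus
#'   `manifest.json` in `out_dir`. On error all outputs written by the
#'   failed run are removed and the error is re-raised with context.
#' @export
run_pipeline <- function(subcommand, params = list(), out_dir = ".",
                         seed = 1L) {
  subcommand <- match.arg(subcommand, c("simulate", "accuracy", "leaders",
                                        "network", "sampling", "demo"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(f) {
    p <- file.path(out_dir, f)
    written <<- c(written, p)
    p
  }
  inputs <- unlist(params[names(params) %in% c("data", "trajectory", "survey")])
  tryCatch({
    stage_outputs <- .run_stage(subcommand, params, out, seed)
    manifest <- list(
      subcommand = subcommand,
      package_version = as.character(utils::packageVersion("flocknet")),
      r_version = as.character(getRversion()),
      seed = seed,
      parameters = params[!vapply(params, is.null, logical(1))],
      input_digests = if (length(inputs))
        as.list(tools::md5sum(inputs)) else list(),
      outputs = basename(written),
      results = stage_outputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", subcommand,
                 conditionMessage(e)), call. = FALSE)
  })
}

.num <- function(params, name, default) {
  v <- params[[name]]
  if (is.null(v)) default else as.numeric(v)
}

.parse_regimes <- function(spec) {
  if (is.list(spec)) return(spec)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    kind <- kv[1]
    arg <- if (length(kv) > 1L) kv[2] else ""
    switch(kind,
      continuous = regime_continuous(dt = if (nzchar(arg)) as.numeric(arg) else 5),
      single = regime_single(period = if (nzchar(arg)) as.numeric(arg) else 300),
      burst = {
        oo <- as.numeric(strsplit(arg, "/", fixed = TRUE)[[1]])
        if (length(oo) != 2L || any(is.na(oo)))
          stop("burst regime must be burst:<on>/<off>")
        regime_burst(on_duration = oo[1], off_duration = oo[2])
      },
      stop("unknown regime kind: ", kind))
  })
}

.run_stage <- function(subcommand, params, out, seed) {
  switch(subcommand,
    simulate = {
      cfg_args <- params[names(params) %in% names(formals(simulation_config))]
      if (is.null(cfg_args$seed)) cfg_args$seed <- seed
      sim <- simulate_flock(do.call(simulation_config, cfg_args))
      write_trajectories(sim$dataset, out("flock.csv"))
      write_survey(sim$dataset$paddock, out("survey.csv"))
      write_ground_truth(sim$truth, out("truth.json"))
      list(n_fixes = nrow(sim$dataset$fixes),
           n_events = nrow(sim$truth$leader_events),
           n_bouts = nrow(sim$truth$contact_log))
    },
    accuracy = {
      if (is.null(params$trajectory) || is.null(params$survey))
        stop("accuracy needs 'trajectory' and 'survey' file parameters")
      ds <- read_trajectories(params$trajectory)
      sv <- read_survey(params$survey)
      lines <- fit_fence_lines(sv)
      err <- fence_error(ds, lines)
      hist <- error_histogram(err$distance,
                              bin_width = .num(params, "bin_width", 0.01))
      fwrite(err, out("errors.csv"))
      fwrite(as.data.table(hist), out("histogram.csv"))
      list(n_fixes = nrow(err), mean_error = mean(err$distance),
           max_error = max(err$distance))
    },
    leaders = {
      if (is.null(params$data)) stop("leaders needs a 'data' file parameter")
      ds <- read_trajectories(params$data)
      res <- movement_leaders(
        ds, interval_spec(length = .num(params, "interval", 600)),
        move_threshold = .num(params, "move_threshold", 1),
        separation_threshold = .num(params, "separation_threshold", 1),
        tie_window = .num(params, "tie_window", 10),
        smooth = .num(params, "smooth", 30))
      fwrite(res$ranks, out("ranks.csv"))
      fwrite(res$scores, out("scores.csv"))
      list(n_intervals = length(unique(res$ranks$interval)),
           top_animal = res$scores$animal_id[1],
           top_score = res$scores$score[1])
    },
    network = {
      if (is.null(params$data)) stop("network needs a 'data' file parameter")
      threshold <- .num(params, "threshold", 0.30)
      if (threshold < 0) stop("threshold must be >= 0")
      ds <- read_trajectories(params$data)
      g <- group_times(ds, bin = .num(params, "bin", 5))
      edges <- suppressWarnings(nearest_neighbour_edges(g, threshold))
      counts <- neighbour_counts(edges, animals = animal_ids(ds))
      fwrite(edges, out("edges.csv"))
      fwrite(counts, out("counts.csv"))
      list(n_edges = sum(!is.na(edges$neighbour)),
           counts = stats::setNames(as.list(counts$count),
                                    counts$animal_id))
    },
    sampling = {
      if (is.null(params$data)) stop("sampling needs a 'data' file parameter")
      ds <- read_trajectories(params$data)
      regimes <- .parse_regimes(
        if (is.null(params$regimes))
          "continuous:5,single:300,burst:60/240,burst:60/540"
        else params$regimes)
      thresholds <- params$thresholds
      thresholds <- if (is.null(thresholds)) c(0.10, 0.20, 0.30)
        else if (is.character(thresholds))
          as.numeric(strsplit(thresholds, ",")[[1]]) else as.numeric(thresholds)
      cmp <- compare_regimes(ds, regimes, thresholds)
      fwrite(cmp, out("comparison.csv"))
      rec <- unique(cmp[, .(regime, threshold, recovered)])
      list(n_regimes = length(regimes),
           recovered = rec[recovered == TRUE, .N],
           compared = nrow(rec))
    },
    demo = {
      sim_params <- params
      sim_params$duration <- .num(params, "duration", 3600)
      res_sim <- .run_stage("simulate", sim_params, out, seed)
      flock_csv <- file.path(dirname(out("flock.csv")), "flock.csv")
      survey_csv <- file.path(dirname(out("survey.csv")), "survey.csv")
      res_lead <- .run_stage("leaders", list(data = flock_csv), out, seed)
      res_net <- .run_stage("network", list(data = flock_csv), out, seed)
      res_samp <- .run_stage("sampling", list(data = flock_csv), out, seed)
      walk <- simulate_boundary_walk(read_survey(survey_csv),
                                     noise_sigma = 0.1, seed = seed)
      walk_csv <- out("walk.csv")
      write_trajectories(walk, walk_csv)
      res_acc <- .run_stage("accuracy",
                            list(trajectory = walk_csv, survey = survey_csv),
                            out, seed)
      list(simulate = res_sim, leaders = res_lead, network = res_net,
           sampling = res_samp, accuracy = res_acc)
    })
}
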