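#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults follow the
#' reference design where it states them: 50-sample windows at step 1,
#' a 0.01-0.1 Hz band, 10 discarded volumes, a resolution grid 0.1-1.5
#' in steps of 0.1, and alpha = 0.05.
#'
#' @param input_mode `"simulate"` or `"tsv"`.
#' @param input_dir directory of per-subject TSVs plus `atlas.tsv` and
#'   `participants.csv` (tsv mode).
#' @param sim_spec a [simulation_spec()] (simulate mode).
#' @param n_per_group cohort size per group (simulate mode).
#' @param n_discard leading volumes to drop.
#' @param do_detrend,do_bandpass preprocessing switches.
#' @param low_hz,high_hz band edges.
#' @param window_length,window_step sliding-window geometry.
#' @param gs_exclude_self leave each ROI out of its own hemisphere mean.
#' @param lf_ddof LF degrees-of-freedom correction.
#' @param aggregate unit aggregation mode (see [build_metric_table()]).
#' @param k1 stage-1 per-subject cluster count.
#' @param r_min,r_max,r_step resolution grid.
#' @param alpha significance / FDR level.
#' @param families FDR family modes to analyse.
#' @param correlation_sidedness sidedness for clinical correlations.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input_mode = c("simulate", "tsv"),
                       input_dir = NULL,
                       sim_spec = simulation_spec(),
                       n_per_group = 48L,
                       n_discard = 10L,
                       do_detrend = TRUE,
                       do_bandpass = TRUE,
                       low_hz = 0.01, high_hz = 0.1,
                       window_length = 50L, window_step = 1L,
                       gs_exclude_self = FALSE,
                       lf_ddof = 1L,
                       aggregate = "series",
                       k1 = 5L,
                       r_min = 0.1, r_max = 1.5, r_step = 0.1,
                       alpha = 0.05,
                       families = c("subnet12", "node"),
                       correlation_sidedness = "two.sided",
                       seed = 1L) {
  input_mode <- match.arg(input_mode)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from JSON
#'
#' A flat JSON object whose keys mirror the [run_config()] arguments
#' (unknown keys are rejected); `sim_spec` may itself be an object of
#' [simulation_spec()] arguments.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim_spec)) {
    raw$sim_spec <- do.call(simulation_spec, raw$sim_spec)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full dynamic-laterality pipeline
#'
#' simulate (or load) -> preprocess -> laterality series -> state
#' discovery -> MLI/LF metrics -> group statistics, clinical
#' correlations and demographics, with every artifact written as plain
#' text under `out_dir`. Identical configuration and seed give
#' identical artifacts.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with the in-memory results (`cohort` or
#'   subject list, `laterality`, `states`, `metrics`, `group_results`,
#'   `correlations`, `demographics`, `state_correlations`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  inp <- stage("input", {
    if (config$input_mode == "simulate") {
      cohort <- simulate_cohort(config$sim_spec, config$n_per_group,
                                seed = derive_seed(config$seed, 1))
      list(ts = lapply(cohort$subjects, `[[`, "ts"),
           atlas = cohort$atlas, group = cohort$group,
           scores = cohort$scores, demographics = cohort$demographics,
           cohort = cohort)
    } else {
      read_cohort_dir(config$input_dir)
    }
  })
  say("input: ", length(inp$ts), " subjects, ", nrow(inp$atlas), " ROIs")

  pre <- stage("preprocess", lapply(inp$ts, function(ts) {
    out <- discard_initial_volumes(ts, config$n_discard)
    if (config$do_detrend) out <- detrend_and_regress(out)
    if (config$do_bandpass) {
      out <- bandpass(out, config$low_hz, config$high_hz)
    }
    out
  }))
  say("preprocess: T = ", nrow(pre[[1L]]$values), " after discard")

  wspec <- window_spec(config$window_length, config$window_step)
  lat <- stage("laterality", lapply(pre, function(ts) {
    laterality_series(ts, wspec, inp$atlas,
                      gs_exclude_self = config$gs_exclude_self)
  }))
  say("laterality: ", nrow(lat[[1L]]$values), " windows per subject")

  states <- stage("states", fit_laterality_states(
    lat, k1 = config$k1, r_min = config$r_min, r_max = config$r_max,
    r_step = config$r_step, seed = derive_seed(config$seed, 2)))
  say("states: k = ", states$k, ", occupancy ",
      paste(sprintf("%.3f", states$occupancy), collapse = " "))

  metrics <- stage("metrics", build_metric_table(
    lat, inp$atlas, inp$group, assignments = states$assignments,
    k = states$k, lf_ddof = config$lf_ddof,
    aggregate = config$aggregate))

  state_ids <- c("ALL", as.character(seq_len(states$k)))
  group_results <- stage("group statistics", {
    do.call(rbind, lapply(config$families, function(fam) {
      do.call(rbind, lapply(state_ids, function(st) {
        do.call(rbind, lapply(c("mli", "lf"), function(me) {
          group_compare(metrics, metric = me, state = st, family = fam,
                        alpha = config$alpha)
        }))
      }))
    }))
  })
  say("group statistics: ", sum(group_results$significant),
      " significant units of ", nrow(group_results))

  correlations <- stage("clinical correlations", {
    sel <- group_results[group_results$significant,
                         c("unit_id", "unit_level", "metric", "state")]
    clinical_correlations(metrics, inp$scores, sel,
                          alternative = config$correlation_sidedness)
  })

  demographics <- stage("demographics", demographics_table(
    inp$demographics))

  state_correlations <- stage("state correlation matrices", {
    lapply(seq_len(states$k), function(s) {
      state_laterality_correlation(lat, states$assignments, s)
    })
  })

  stage("write artifacts", {
    write_pipeline_artifacts(out_dir, config, inp, lat, states, metrics,
                             group_results, correlations, demographics,
                             state_correlations)
  })
  say("artifacts written to ", out_dir)

  invisible(list(atlas = inp$atlas, cohort = inp$cohort,
                 laterality = lat, states = states, metrics = metrics,
                 group_results = group_results,
                 correlations = correlations,
                 demographics = demographics,
                 state_correlations = state_correlations))
}

read_cohort_dir <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  manifest <- utils::read.csv(file.path(dir, "participants.csv"),
                              stringsAsFactors = FALSE)
  ts <- lapply(manifest$subject_id, function(id) {
    read_roi_timeseries(file.path(dir, paste0(id, "_bold.tsv")),
                        subject_id = id)
  })
  score_cols <- intersect(c("BPRS", "SANS", "YMRS"), names(manifest))
  list(ts = ts, atlas = atlas, group = manifest$group,
       scores = manifest[, c("subject_id", score_cols)],
       demographics = manifest, cohort = NULL)
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_pipeline_artifacts <- function(out_dir, config, inp, lat, states,
                                     metrics, group_results,
                                     correlations, demographics,
                                     state_correlations) {
  lat_dir <- file.path(out_dir, "laterality")
  dir.create(lat_dir, showWarnings = FALSE)
  for (ls in lat) {
    write_matrix_tsv(ls$values,
                     file.path(lat_dir, paste0(ls$subject_id, "_dli.tsv")))
  }
  st_dir <- file.path(out_dir, "states")
  dir.create(st_dir, showWarnings = FALSE)
  write_matrix_tsv(states$centroids, file.path(st_dir, "centroids.tsv"))
  asg <- do.call(rbind, lapply(seq_along(states$assignments), function(i) {
    data.frame(subject_id = states$subject_ids[i],
               window = seq_along(states$assignments[[i]]),
               state = states$assignments[[i]])
  }))
  utils::write.csv(asg, file.path(st_dir, "assignments.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(resolutions = states$sweep$resolutions,
         persistence = states$sweep$persistence,
         k = states$k, occupancy = states$occupancy),
    file.path(st_dir, "sweep.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(group_results, file.path(out_dir, "group_results.csv"),
                   row.names = FALSE)
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  for (s in seq_along(state_correlations)) {
    write_matrix_tsv(state_correlations[[s]],
                     file.path(out_dir, sprintf("state_corr_%d.tsv", s)))
  }
  prov <- unclass(config)
  prov$sim_spec <- if (config$input_mode == "simulate") {
    sp <- config$sim_spec
    sp$atlas <- NULL
    sp$lambda <- NULL
    unclass(sp)
  } else NULL
  prov$package_version <- as.character(utils::packageVersion("dynlat"))
  prov$r_version <- R.version.string
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
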