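#' Pipeline configuration
#'
#' One flat, JSON-serializable list of every tunable parameter, with
#' defaults matching the pipeline's reference operating point: confidence
#' gate 0.4, 4 Hz second-order zero-phase Butterworth, 35% foot-strike
#' threshold, 3-strike retention minimum, PCKh alpha 0.5, 14-day baseline
#' window, and 0.05 significance.
#'
#' @param ... Overrides for any default entry (unknown names error).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    conf_threshold = 0.4,
    cutoff_hz = 4,
    filter_order = 2,
    zero_phase = TRUE,
    hip_span_floor_px = 1,
    span_policy = "per_frame",
    threshold_frac = 0.35,
    min_step_interval_s = 0.25,
    min_peak_frac = 0.3,
    min_strikes = 3,
    g = 9.81,
    window_days = 14,
    alpha = 0.05,
    collinearity_r = 0.8,
    pckh_alpha = 0.5,
    conf_cutoffs = c(0.2, 0.4, 0.6, 0.8)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config entries: ", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, dots), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run feature extraction over a bout manifest
#'
#' Processes every bout listed in a manifest through track selection and
#' [extract_features()], logging each discard and its reason (manual flags
#' recorded at collection time dominate; bouts with too few detected foot
#' strikes or unusable keypoints are discarded during processing). The
#' summary reports the overall discard fraction, the bookkeeping figure a
#' study reports alongside its cohort.
#'
#' @param manifest A manifest tibble or CSV path (see
#'   [read_bout_manifest()]).
#' @param config A [pipeline_config()].
#' @param enrollment Optional tibble (`participant_id`, `enrollment_date`)
#'   to also compute baselines via [baseline_aggregate()].
#' @param track_policy Track-selection policy passed to
#'   [select_participant_track()].
#' @param out_dir Optional directory: writes `features.csv`,
#'   `discards.csv`, optionally `baselines.csv`, and a `run_meta.json`
#'   sidecar with the config and counts.
#' @return A `gait_extract_run` list: `features`, `discards` (tibble of
#'   `bout_id`, `reason`), `baselines` (or `NULL`), `summary` (counts and
#'   `discard_fraction`), `config`.
#' @export
run_extract <- function(manifest, config = pipeline_config(),
                        enrollment = NULL,
                        track_policy = "largest_hip_span", out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_bout_manifest(manifest)
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    abort("Empty manifest: nothing to extract.")
  }
  feats <- list()
  discards <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    flags <- parse_flags(row$flags %||% NA_character_)
    manual <- intersect(flags, c("handrail", "turned_around", "occluded"))
    if (length(manual)) {
      discards[[length(discards) + 1L]] <-
        tibble(bout_id = row$bout_id, reason = manual[1])
      next
    }
    res <- tryCatch({
      pose <- read_pose_json(row$path, fps = row$fps)
      attr(pose, "bout_id") <- row$bout_id
      attr(pose, "participant_id") <- row$participant_id
      attr(pose, "recorded_at") <- row$recorded_at
      bout <- select_participant_track(pose, policy = track_policy,
                                       flags = flags)
      extract_features(bout, config = config)
    }, gaitvision_bout_rejected = function(e) {
      tibble(bout_id = row$bout_id,
             reason = e$reason %||% "rejected")
    })
    if ("reason" %in% names(res)) {
      discards[[length(discards) + 1L]] <- res
    } else {
      feats[[length(feats) + 1L]] <- res
    }
  }
  features <- bind_rows(feats)
  if (nrow(features) == 0L) {
    abort("All bouts were discarded; extraction produced no features.")
  }
  discards <- if (length(discards)) bind_rows(discards) else
    tibble(bout_id = character(), reason = character())
  summary <- list(
    n_total = nrow(manifest),
    n_retained = nrow(features),
    n_discarded = nrow(discards),
    discard_fraction = nrow(discards) / nrow(manifest),
    discard_reasons = table(discards$reason)
  )
  baselines <- if (!is.null(enrollment)) {
    baseline_aggregate(features, enrollment, window_days = config$window_days)
  }
  run <- structure(
    list(features = features, discards = discards, baselines = baselines,
         summary = summary, config = config),
    class = "gait_extract_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(discards, file.path(out_dir, "discards.csv"))
    if (!is.null(baselines)) {
      readr::write_csv(baselines, file.path(out_dir, "baselines.csv"))
    }
    jsonlite::write_json(
      list(config = unclass(config),
           counts = summary[c("n_total", "n_retained", "n_discarded",
                              "discard_fraction")]),
      file.path(out_dir, "run_meta.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  run
}

#' @export
print.gait_extract_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<gait_extract_run> %d bouts: %d retained, %d discarded (%.1f%%)\n",
    s$n_total, s$n_retained, s$n_discarded, 100 * s$discard_fraction
  ))
  if (length(s$discard_reasons)) {
    for (r in names(s$discard_reasons)) {
      cat(sprintf("  discarded (%s): %d\n", r, s$discard_reasons[[r]]))
    }
  }
  invisible(x)
}

one_model_row <- function(m) {
  td <- tidy(m)
  gl <- glance(m)
  slope <- td[td$term != "(Intercept)", , drop = FALSE]
  tibble(
    outcome = gl$outcome,
    predictor = if (nrow(slope)) slope$term else "(Intercept)",
    estimate = if (nrow(slope)) slope$estimate else td$estimate,
    std.error = if (nrow(slope)) slope$std.error else td$std.error,
    p.value = if (nrow(slope)) slope$p.value else td$p.value,
    r2 = gl$r2,
    adjusted_r2 = gl$adjusted_r2,
    n = gl$n
  )
}

#' Run the cohort association analyses
#'
#' Joins participant baselines to the cohort table and fits the four
#' association analyses: univariate linear models of each feature to the
#' POMA-gait and POMA-balance sub-scores, univariate Poisson models of fall
#' counts (exposure offset), and the multivariate Poisson model assembled by
#' [build_multivariate()].
#'
#' @param baselines Baseline table from [baseline_aggregate()] (or any
#'   tibble with `participant_id` + the seven features).
#' @param cohort Tibble with `participant_id`, `poma_gait`, `poma_balance`,
#'   `n_falls`, `exposure_days`.
#' @param config A [pipeline_config()].
#' @param features Candidate features (default all seven).
#' @return A `gait_stats_run` list of tidy tables: `poma_gait`,
#'   `poma_balance`, `falls_univariate` (one row per feature; degenerate
#'   features are reported with `NA` estimates and a note), and
#'   `falls_multivariate` (one row per term), plus `models` with the fitted
#'   objects.
#' @export
run_stats <- function(baselines, cohort, config = pipeline_config(),
                      features = gait_feature_names()) {
  records <- inner_join(baselines, cohort, by = "participant_id")
  if (nrow(records) < 3L) {
    abort("Fewer than 3 participants after joining baselines to the cohort table.")
  }
  fit_table <- function(fun) {
    rows <- purrr::map(features, function(f) {
      tryCatch(one_model_row(fun(f)),
               gaitvision_degenerate = function(e) {
                 tibble(outcome = NA_character_, predictor = f,
                        estimate = NA_real_, std.error = NA_real_,
                        p.value = NA_real_, r2 = NA_real_,
                        adjusted_r2 = NA_real_, n = NA_integer_)
               })
    })
    bind_rows(rows)
  }
  poma_gait <- fit_table(function(f) univariate_linear(records, f, "poma_gait"))
  poma_balance <- fit_table(function(f) univariate_linear(records, f, "poma_balance"))
  univ <- purrr::map(
    setNames(features, features),
    function(f) {
      tryCatch(univariate_poisson(records, f),
               gaitvision_degenerate = function(e) NULL)
    }
  )
  falls_univariate <- fit_table(function(f) {
    if (is.null(univ[[f]])) {
      abort("degenerate", class = "gaitvision_degenerate")
    }
    univ[[f]]
  })
  multi <- build_multivariate(records, univariate = purrr::compact(univ),
                              features = features,
                              alpha = config$alpha,
                              collinearity_r = config$collinearity_r)
  multi_gl <- glance(multi)
  falls_multivariate <- tidy(multi) |>
    mutate(r2 = multi_gl$r2, adjusted_r2 = multi_gl$adjusted_r2,
           n = multi_gl$n)
  structure(
    list(poma_gait = poma_gait, poma_balance = poma_balance,
         falls_univariate = falls_univariate,
         falls_multivariate = falls_multivariate,
         models = list(univariate_poisson = univ, multivariate = multi),
         n_participants = nrow(records)),
    class = "gait_stats_run"
  )
}

#' @export
print.gait_stats_run <- function(x, ...) {
  cat(sprintf("<gait_stats_run> %d participants\n", x$n_participants))
  cat("\nLinear regression to POMA-gait:\n"); print(x$poma_gait)
  cat("\nLinear regression to POMA-balance:\n"); print(x$poma_balance)
  cat("\nUnivariate Poisson regression to falls:\n"); print(x$falls_univariate)
  cat("\nMultivariate Poisson regression to falls:\n")
  print(x$falls_multivariate)
  invisible(x)
}

#' PCKh verification report
#'
#' Convenience wrapper producing the plain PCKh row block plus the
#' confidence-cutoff sweep in one table.
#'
#' @inheritParams pckh
#' @param config A [pipeline_config()] (uses `pckh_alpha` and
#'   `conf_cutoffs`).
#' @return A `pck_report` tibble.
#' @export
run_validate_pck <- function(predictions, annotations,
                             config = pipeline_config()) {
  base <- pckh(predictions, annotations, alpha = config$pckh_alpha)
  base$discarded_fraction <- 0
  sweep <- confidence_sweep(
    predictions, annotations,
    cutoffs = config$conf_cutoffs, alpha = config$pckh_alpha,
    subsets = list(all = NULL, ankles = c("left_ankle", "right_ankle"),
                   hips = c("left_hip", "right_hip"))
  )
  out <- bind_rows(base, sweep)
  class(out) <- unique(c("pck_report", class(out)))
  out
}
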