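#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run: either the three input CSV
#' paths or a simulation block, the session gap threshold, clustering
#' radius and density, inclusion thresholds, study region, time zone and
#' seed. The configuration is serialised into the run directory so any
#' run can be reproduced from its own output.
#'
#' @param gps_path,wifi_path,meta_path Input CSVs (ignored when
#'   `simulate` is given).
#' @param simulate Optional [cohort_config()]; when set, the cohort is
#'   simulated instead of read.
#' @param gap_threshold Wi-Fi session gap threshold in seconds.
#' @param eps_km,min_pts Location-clustering parameters.
#' @param min_wifi_days,study_days Inclusion-filter parameters.
#' @param region Study region box (see [flag_out_of_region()]).
#' @param tz Local time zone.
#' @param seed Integer seed (overrides the simulation block's seed).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(gps_path = NULL, wifi_path = NULL, meta_path = NULL,
                       simulate = NULL,
                       gap_threshold = 1000, eps_km = 0.5, min_pts = 5,
                       min_wifi_days = 14, study_days = 180,
                       region = region_illinois(), tz = "America/Chicago",
                       seed = 1, out_dir = NULL) {
  if (is.null(simulate) &&
        (is.null(gps_path) || is.null(wifi_path) || is.null(meta_path))) {
    abort("provide gps_path/wifi_path/meta_path or a simulate block")
  }
  structure(
    list(
      gps_path = gps_path, wifi_path = wifi_path, meta_path = meta_path,
      simulate = simulate, gap_threshold = gap_threshold,
      eps_km = eps_km, min_pts = min_pts,
      min_wifi_days = min_wifi_days, study_days = study_days,
      region = region, tz = tz, seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Per-participant Wi-Fi feature table from a raw event stream
#'
#' Convenience wrapper: segments each participant's events into sessions,
#' classifies the SSIDs, and computes the Wi-Fi feature set.
#'
#' @param events Wi-Fi event tibble (any number of participants).
#' @param gap_threshold Session gap threshold in seconds.
#' @param public_lexicon Public-name lexicon for [classify_network()].
#' @param tz Local time zone.
#' @return One row per participant; see [compute_wifi_features()].
#' @export
wifi_feature_table <- function(events, gap_threshold = 1000,
                               public_lexicon = default_public_lexicon(),
                               tz = "America/Chicago") {
  sessions <- events |>
    dplyr::arrange(.data$participant_id, .data$t) |>
    (\(x) split(x, x$participant_id))() |>
    purrr::map(segment_sessions, gap_threshold = gap_threshold) |>
    dplyr::bind_rows()
  if (nrow(sessions) == 0) abort("no Wi-Fi events to featurize")
  classes <- classify_network(unique(sessions$ssid), public_lexicon)
  compute_wifi_features(sessions, classes, tz = tz)
}

#' Run the full passive-sensing pipeline
#'
#' Stages, in order: load or simulate the cohort; merge replacement-device
#' streams into one sequence per participant; apply the inclusion filters
#' (180-day truncation, minimum Wi-Fi days); flag out-of-region fixes;
#' extract Wi-Fi and mobility features; fit the symptom-association
#' suite. Per-stage counts are logged, and when `out_dir` is set all
#' outputs plus a manifest (config hash, seed, package version) are
#' written there; a fatal stage error leaves partial outputs and a
#' `FAILED` marker.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return List with `features`, `associations`, `exclusions`,
#'   `participants`, and `truth` (simulated runs only).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (!quiet) message("[mobsense] ", ...)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  result <- tryCatch({
    truth <- NULL
    if (!is.null(config$simulate)) {
      sim_cfg <- config$simulate
      sim_cfg$seed <- config$seed
      log_msg("simulating cohort: n = ", sim_cfg$n_participants,
              ", seed = ", sim_cfg$seed)
      cohort <- simulate_cohort(sim_cfg)
      gps <- cohort$gps
      wifi <- cohort$wifi
      participants <- cohort$participants
      truth <- cohort$truth
    } else {
      log_msg("reading traces")
      traces <- read_traces(config$gps_path, config$wifi_path,
                            config$meta_path, quiet = quiet)
      gps <- traces$gps
      wifi <- traces$wifi
      participants <- traces$participants
    }
    log_msg("input: ", nrow(participants), " participants, ",
            nrow(gps), " fixes, ", nrow(wifi), " wifi events")

    gps <- merge_all_devices(gps)
    wifi <- merge_all_devices(wifi)

    filtered <- apply_inclusion_filters(
      participants, wifi, gps,
      min_wifi_days = config$min_wifi_days,
      study_days = config$study_days, tz = config$tz
    )
    log_msg("inclusion filters: retained ", nrow(filtered$participants),
            " of ", nrow(participants), " participants")

    gps_flagged <- flag_out_of_region(filtered$gps, config$region)
    log_msg("out-of-region fixes: ", sum(!gps_flagged$in_region))

    wifi_feats <- wifi_feature_table(
      filtered$wifi, gap_threshold = config$gap_threshold, tz = config$tz
    )
    mob_feats <- compute_mobility_features(
      gps_flagged, eps_km = config$eps_km, min_pts = config$min_pts,
      tz = config$tz
    )
    features <- dplyr::full_join(mob_feats, wifi_feats, by = "participant_id",
                                 suffix = c("_gps", "_wifi"))
    log_msg("features for ", nrow(features), " participants")

    associations <- run_association_suite(features, filtered$participants)

    list(
      features = features, associations = associations,
      exclusions = filtered$exclusions,
      participants = filtered$participants, truth = truth
    )
  }, error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    }
    abort(paste0("pipeline failed: ", conditionMessage(e)), parent = e)
  })

  if (!is.null(out_dir)) {
    readr::write_csv(result$features, file.path(out_dir, "features.csv"))
    readr::write_csv(result$associations, file.path(out_dir, "associations.csv"))
    readr::write_csv(result$exclusions, file.path(out_dir, "exclusions.csv"))
    cfg_json <- jsonlite::serializeJSON(config)
    writeLines(cfg_json, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(
        config_hash = rlang::hash(config),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("mobsense"))
      ),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE
    )
    log_msg("outputs written to ", out_dir)
  }
  invisible(result)
}

# Merge per-device streams participant by participant.
merge_all_devices <- function(events) {
  if (nrow(events) == 0) return(events)
  split(events, events$participant_id) |>
    purrr::map(merge_device_streams) |>
    dplyr::bind_rows()
}

#' Render the association results as aligned text tables
#'
#' Formats the long-format suite output into one small table per stratum
#' (coefficient, p-value, bivariate R-squared), mirroring how such
#' results are usually reported.
#'
#' @param associations Output of [run_association_suite()].
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_association_tables <- function(associations) {
  lines <- character(0)
  for (st in unique(associations$stratum)) {
    d <- associations[associations$stratum == st, ]
    lines <- c(lines, paste0("stratum: ", st),
               sprintf("  %-6s %-26s %8s %8s %6s %4s",
                       "outcome", "predictor", "b", "p", "R2", "n"))
    lines <- c(lines, sprintf(
      "  %-6s %-26s %8.2f %8.3f %6.2f %4d",
      d$outcome, d$predictor, d$b, d$p_value, d$r2, d$n
    ), "")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
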