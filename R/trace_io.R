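#' Read raw sensor streams and participant metadata
#'
#' Reads the three CSV inputs of the pipeline: GPS fixes
#' (`participant_id,t,lat,lon[,device_index]`), Wi-Fi connection events
#' (`participant_id,t,ssid[,ip][,device_index]`) and participant metadata
#' (`participant_id,employed,student,shelter,phq9_total,pcl5_total`).
#' Rows with unparseable timestamps or out-of-range coordinates are
#' rejected and counted, never silently dropped; a missing required column
#' is a fatal error.
#'
#' @param gps_path,wifi_path,meta_path Paths to the three CSV files.
#' @param quiet If `FALSE` (default), report rejected-row counts via
#'   `message()`.
#' @return A list with elements `gps`, `wifi`, `participants` (tibbles,
#'   streams sorted by participant then time) and `rejected`, a named
#'   integer vector of rejected row counts per stream.
#' @export
read_traces <- function(gps_path, wifi_path, meta_path, quiet = FALSE) {
  gps <- read_gps_csv(gps_path)
  wifi <- read_wifi_csv(wifi_path)
  participants <- read_participants_csv(meta_path)
  rejected <- c(
    gps = attr(gps, "n_rejected"),
    wifi = attr(wifi, "n_rejected")
  )
  if (!quiet && sum(rejected) > 0) {
    message(
      "rejected malformed rows: gps = ", rejected[["gps"]],
      ", wifi = ", rejected[["wifi"]]
    )
  }
  list(gps = gps, wifi = wifi, participants = participants, rejected = rejected)
}

#' Read a GPS fix stream from CSV
#'
#' @param path CSV with header `participant_id,t,lat,lon` and optional
#'   `device_index` (0 = original phone).
#' @return Tibble of fixes sorted by `(participant_id, t)`, with attribute
#'   `n_rejected` counting rows dropped for unparseable or out-of-range
#'   values.
#' @export
read_gps_csv <- function(path) {
  x <- read_delimited(path, required = c("participant_id", "t", "lat", "lon"))
  x <- dplyr::mutate(x,
    t = suppressWarnings(as.numeric(.data$t)),
    lat = suppressWarnings(as.numeric(.data$lat)),
    lon = suppressWarnings(as.numeric(.data$lon)),
    device_index = default_device_index(x)
  )
  ok <- !is.na(x$t) & x$t >= 0 &
    !is.na(x$lat) & abs(x$lat) <= 90 &
    !is.na(x$lon) & abs(x$lon) <= 180
  out <- dplyr::arrange(
    dplyr::select(
      x[ok, , drop = FALSE],
      "participant_id", "t", "lat", "lon", "device_index"
    ),
    .data$participant_id, .data$t
  )
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Read a Wi-Fi event stream from CSV
#'
#' @param path CSV with header `participant_id,t,ssid` and optional `ip`,
#'   `device_index` columns. Empty SSIDs are kept (they classify as
#'   unclassifiable downstream); rows without a parseable timestamp are
#'   rejected and counted.
#' @return Tibble of events sorted by `(participant_id, t)` with attribute
#'   `n_rejected`.
#' @export
read_wifi_csv <- function(path) {
  x <- read_delimited(path, required = c("participant_id", "t", "ssid"))
  x <- dplyr::mutate(x,
    t = suppressWarnings(as.numeric(.data$t)),
    ssid = ifelse(is.na(.data$ssid), "", as.character(.data$ssid)),
    ip = if ("ip" %in% names(x)) as.character(x$ip) else NA_character_,
    device_index = default_device_index(x)
  )
  ok <- !is.na(x$t) & x$t >= 0
  out <- dplyr::arrange(
    dplyr::select(
      x[ok, , drop = FALSE],
      "participant_id", "t", "ssid", "ip", "device_index"
    ),
    .data$participant_id, .data$t
  )
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Read the participant metadata table from CSV
#'
#' Validates symptom totals against instrument ranges: PHQ-9 in 0-27,
#' PCL-5 in 0-80. Out-of-range totals are fatal (they indicate a corrupt
#' survey export, not a sensor glitch).
#'
#' @param path CSV with header
#'   `participant_id,employed,student,shelter,phq9_total,pcl5_total`.
#' @return Tibble with logical `employed`/`student`, character `shelter`
#'   and integer symptom totals.
#' @export
read_participants_csv <- function(path) {
  req <- c(
    "participant_id", "employed", "student", "shelter",
    "phq9_total", "pcl5_total"
  )
  x <- read_delimited(path, required = req)
  x <- dplyr::mutate(x,
    employed = as_flag(.data$employed),
    student = as_flag(.data$student),
    shelter = as.character(.data$shelter),
    phq9_total = as.integer(.data$phq9_total),
    pcl5_total = as.integer(.data$pcl5_total)
  )
  bad_phq <- !is.na(x$phq9_total) & (x$phq9_total < 0 | x$phq9_total > 27)
  bad_pcl <- !is.na(x$pcl5_total) & (x$pcl5_total < 0 | x$pcl5_total > 80)
  if (any(bad_phq) || any(bad_pcl)) {
    abort(paste0(
      "symptom totals out of instrument range for participant(s): ",
      paste(unique(x$participant_id[bad_phq | bad_pcl]), collapse = ", ")
    ))
  }
  dplyr::arrange(dplyr::select(x, dplyr::all_of(req)), .data$participant_id)
}

#' Write streams back to the CSV dialect `read_traces` consumes
#'
#' @param x A tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

read_delimited <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  x
}

default_device_index <- function(x) {
  if ("device_index" %in% names(x)) {
    d <- suppressWarnings(as.integer(x$device_index))
    ifelse(is.na(d), 0L, d)
  } else {
    rep(0L, nrow(x))
  }
}

as_flag <- function(v) {
  if (is.logical(v)) return(v)
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Merge per-device event streams for one participant
#'
#' Participants who lost a phone received a replacement; the replacement's
#' stream is appended to the original and the result is analysed as a
#' single sequence. Events identical on every payload column (everything
#' except `device_index`) are deduplicated; near-duplicates are kept.
#'
#' @param streams Either a single tibble containing a `device_index`
#'   column, or a list of per-device tibbles, all for the same
#'   participant.
#' @return One time-sorted tibble.
#' @export
merge_device_streams <- function(streams) {
  x <- if (is.data.frame(streams)) streams else dplyr::bind_rows(streams)
  if (nrow(x) == 0) return(x)
  if (length(unique(x$participant_id)) > 1) {
    abort("merge_device_streams received streams from different participants")
  }
  payload <- setdiff(names(x), "device_index")
  x <- dplyr::arrange(x, .data$t, .data$device_index)
  x[!duplicated(x[payload]), , drop = FALSE]
}

#' Apply the cohort inclusion rules
#'
#' Two rules, applied in order. First, events recorded beyond each
#' participant's study window (enrollment start + `study_days`; enrollment
#' start is the participant's earliest event on either stream) are
#' removed; stray uploads past the study end are not data. Second, a
#' participant is retained only if at least `min_wifi_days` distinct local
#' calendar days contain a Wi-Fi event ("less than 14 days" excluded, so
#' exactly 14 is retained). Every excluded participant appears in the
#' exclusion report with a reason.
#'
#' @param participants Metadata tibble (one row per participant).
#' @param wifi_events,gps_fixes Event streams.
#' @param min_wifi_days Minimum distinct Wi-Fi days to retain; default 14.
#' @param study_days Length of the study window in days; default 180.
#' @param tz Local time zone for day counting.
#' @return List with `participants`, `wifi`, `gps` (filtered) and
#'   `exclusions`, a tibble of `(participant_id, reason)`.
#' @export
apply_inclusion_filters <- function(participants, wifi_events, gps_fixes,
                                    min_wifi_days = 14, study_days = 180,
                                    tz = "America/Chicago") {
  ids <- participants$participant_id
  starts <- enrollment_starts(ids, wifi_events, gps_fixes)

  wifi <- truncate_to_window(wifi_events, starts, study_days)
  gps <- truncate_to_window(gps_fixes, starts, study_days)

  wifi_days <- wifi |>
    dplyr::mutate(day = local_day(.data$t, tz)) |>
    dplyr::distinct(.data$participant_id, .data$day) |>
    dplyr::count(.data$participant_id, name = "n_days")
  n_days <- setNames(rep(0L, length(ids)), ids)
  n_days[wifi_days$participant_id] <- wifi_days$n_days

  has_any <- ids %in% c(wifi_events$participant_id, gps_fixes$participant_id)
  reason <- dplyr::case_when(
    !has_any ~ "no data",
    n_days[ids] < min_wifi_days ~
      sprintf("insufficient wifi days (%d < %d)", n_days[ids], min_wifi_days),
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)

  list(
    participants = participants[keep, , drop = FALSE],
    wifi = wifi[wifi$participant_id %in% ids[keep], , drop = FALSE],
    gps = gps[gps$participant_id %in% ids[keep], , drop = FALSE],
    exclusions = tibble::tibble(
      participant_id = ids[!keep],
      reason = reason[!keep]
    )
  )
}

enrollment_starts <- function(ids, wifi, gps) {
  first_t <- dplyr::bind_rows(
    wifi[c("participant_id", "t")],
    gps[c("participant_id", "t")]
  ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(start = min(.data$t), .groups = "drop")
  out <- setNames(rep(NA_real_, length(ids)), ids)
  hit <- first_t$participant_id %in% ids
  out[first_t$participant_id[hit]] <- first_t$start[hit]
  out
}

truncate_to_window <- function(events, starts, study_days) {
  if (nrow(events) == 0) return(events)
  s <- starts[events$participant_id]
  keep <- !is.na(s) & events$t < s + study_days * 86400
  # events for participants without metadata are dropped with their owner
  events[keep & !is.na(keep), , drop = FALSE]
}

#' Flag GPS fixes outside the study region
#'
#' Out-of-region travel (for this cohort, out-of-state trips) is excluded
#' from cluster generation but still contributes to travel-distance
#' features. The region is a closed latitude/longitude box: fixes exactly
#' on the boundary count as in-region.
#'
#' @param fixes GPS fix tibble.
#' @param region Named numeric vector or list with `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`. The default is a box around Illinois.
#' @return `fixes` with an added logical `in_region` column.
#' @export
flag_out_of_region <- function(fixes, region = region_illinois()) {
  region <- as.list(region)
  need <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(region))) {
    abort("region must provide lat_min, lat_max, lon_min, lon_max")
  }
  if (region$lat_min > region$lat_max || region$lon_min > region$lon_max) {
    abort("region box is empty (min exceeds max)")
  }
  dplyr::mutate(fixes,
    in_region = .data$lat >= region$lat_min & .data$lat <= region$lat_max &
      .data$lon >= region$lon_min & .data$lon <= region$lon_max
  )
}

#' Default study region: a box around Illinois
#' @return Named list of box edges in decimal degrees.
#' @export
region_illinois <- function() {
  list(lat_min = 36.97, lat_max = 42.51, lon_min = -91.52, lon_max = -87.02)
}
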