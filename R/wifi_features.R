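#' Reconstruct Wi-Fi sessions from connection-event timestamps
#'
#' A session is a maximal run of events whose consecutive gaps are all at
#' or below `gap_threshold` seconds: a larger gap means the participant
#' dropped off the network for a while and reconnected, so a new session
#' starts. Session duration is last event time minus first event time, so
#' a singleton session has duration zero and total connected time equals
#' the sum of all below-threshold gaps. A change of SSID also splits the
#' session, so no duration is attributed across networks.
#'
#' @param events Time-sorted Wi-Fi event tibble for one participant
#'   (columns `participant_id`, `t`, `ssid`).
#' @param gap_threshold Gap in seconds above which a new session starts;
#'   default 1000 s (roughly a quarter of an hour).
#' @return Tibble with one row per session: `participant_id`, `ssid`,
#'   `start_t`, `end_t`, `duration` (seconds), `n_events`.
#' @export
segment_sessions <- function(events, gap_threshold = 1000) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      participant_id = character(), ssid = character(),
      start_t = numeric(), end_t = numeric(),
      duration = numeric(), n_events = integer()
    ))
  }
  if (length(unique(events$participant_id)) > 1) {
    abort("segment_sessions expects events from a single participant")
  }
  if (is.unsorted(events$t)) {
    abort("events must be sorted ascending by t")
  }
  dt <- diff(events$t)
  new_session <- c(TRUE, dt > gap_threshold | events$ssid[-1] != events$ssid[-nrow(events)])
  sid <- cumsum(new_session)
  events |>
    dplyr::mutate(.session = sid) |>
    dplyr::group_by(.data$.session) |>
    dplyr::summarise(
      participant_id = .data$participant_id[1],
      ssid = .data$ssid[1],
      start_t = min(.data$t),
      end_t = max(.data$t),
      duration = max(.data$t) - min(.data$t),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-".session")
}

#' Classify Wi-Fi networks as public or private by name
#'
#' Mirrors a manual SSID review: any name containing "guest" is public
#' (e.g. "Starbucks-Guest"); names matching a configurable lexicon of
#' common public-venue patterns (libraries, transit, hotels, cafe chains)
#' are public; every other named network is private; an empty name is
#' unclassifiable. Exactly one rule fires per SSID and is recorded.
#'
#' @param ssid Character vector of network names.
#' @param public_lexicon Character vector of lower-case patterns matched
#'   case-insensitively as substrings; defaults to the list shipped in
#'   `inst/extdata/public_ssid_lexicon.txt`.
#' @return Tibble `(ssid, label, rule_fired)` with `label` one of
#'   `"public"`, `"private"`, `"unclassifiable"`.
#' @export
classify_network <- function(ssid, public_lexicon = default_public_lexicon()) {
  s <- tolower(trimws(ifelse(is.na(ssid), "", as.character(ssid))))
  label <- rep("private", length(s))
  rule <- rep("default-private", length(s))

  lex_hit <- rep(NA_character_, length(s))
  for (pat in rev(public_lexicon)) {
    hit <- grepl(pat, s, fixed = TRUE)
    lex_hit[hit] <- pat # reversed loop => earliest pattern in file wins
  }
  label[!is.na(lex_hit)] <- "public"
  rule[!is.na(lex_hit)] <- paste0("lexicon:", lex_hit[!is.na(lex_hit)])

  guest <- grepl("guest", s, fixed = TRUE)
  label[guest] <- "public"
  rule[guest] <- "guest-substring"

  empty <- s == ""
  label[empty] <- "unclassifiable"
  rule[empty] <- "empty-ssid"

  tibble::tibble(ssid = as.character(ssid), label = label, rule_fired = rule)
}

#' Load the shipped public-network name lexicon
#'
#' @param path Optional path to a replacement lexicon (one pattern per
#'   line, `#` comments allowed).
#' @return Character vector of lower-case patterns.
#' @export
default_public_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "public_ssid_lexicon.txt", package = "mobsense")
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(lines[lines != "" & !startsWith(lines, "#")])
}

#' Per-participant Wi-Fi usage features
#'
#' Computes total and mean daily connected minutes, per-network usage
#' shares, the public/private split, and the share of the single most
#' used network. Days observed are distinct local calendar days touched
#' by at least one session. Shares are weighted by session duration; in
#' the degenerate case where every session is a singleton (total duration
#' zero) shares fall back to event counts so they still sum to one.
#'
#' @param sessions Session tibble from [segment_sessions()], one or many
#'   participants.
#' @param classes Network classification tibble from [classify_network()];
#'   by default the distinct SSIDs in `sessions` are classified with the
#'   shipped lexicon.
#' @param tz Local time zone for day counting.
#' @return Tibble with one row per participant: `total_wifi_minutes`,
#'   `mean_daily_wifi_minutes`, `days_observed`, `private_share`,
#'   `public_share`, `unclassifiable_share`, `dominant_network_share`,
#'   `n_networks`, `private_dominant`.
#' @export
compute_wifi_features <- function(sessions, classes = NULL,
                                  tz = "America/Chicago") {
  if (nrow(sessions) == 0) abort("compute_wifi_features requires sessions")
  if (is.null(classes)) {
    classes <- classify_network(unique(sessions$ssid))
  }
  sessions <- dplyr::left_join(
    sessions, dplyr::distinct(classes[c("ssid", "label")]),
    by = "ssid"
  )
  sessions$label[is.na(sessions$label)] <- "private"

  days <- dplyr::bind_rows(
    sessions |> dplyr::transmute(.data$participant_id, day = local_day(.data$start_t, tz)),
    sessions |> dplyr::transmute(.data$participant_id, day = local_day(.data$end_t, tz))
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$participant_id, name = "days_observed")

  sessions |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ wifi_features_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::left_join(days, by = "participant_id") |>
    dplyr::mutate(
      mean_daily_wifi_minutes = .data$total_wifi_minutes / .data$days_observed
    ) |>
    dplyr::select(
      "participant_id", "total_wifi_minutes", "mean_daily_wifi_minutes",
      "days_observed", "private_share", "public_share",
      "unclassifiable_share", "dominant_network_share", "n_networks",
      "private_dominant"
    )
}

wifi_features_one <- function(s) {
  w <- if (sum(s$duration) > 0) s$duration else as.numeric(s$n_events)
  total_w <- sum(w)
  by_net <- tapply(w, s$ssid, sum) / total_w
  by_class <- tapply(w, s$label, sum) / total_w
  share <- function(lbl) if (lbl %in% names(by_class)) unname(by_class[[lbl]]) else 0
  tibble::tibble(
    total_wifi_minutes = sum(s$duration) / 60,
    private_share = share("private"),
    public_share = share("public"),
    unclassifiable_share = share("unclassifiable"),
    dominant_network_share = max(by_net),
    n_networks = length(by_net),
    private_dominant = share("private") > 0.5
  )
}
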