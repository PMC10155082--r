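#' Mobility profile for a simulated participant
#'
#' Describes a participant's movement world: a small set of anchor
#' locations (shelter, work, school, transit hubs) with dwell-weight
#' fractions that control the true location entropy, GPS noise, sampling
#' rate and missingness. Anchors a few kilometres apart are separable at
#' the default clustering radius of 0.5 km.
#'
#' @param anchors Two-column matrix or data frame of anchor `lat`, `lon`.
#' @param dwell_weights Per-anchor time fractions; must sum to 1.
#' @param jitter_sd_km Isotropic GPS noise standard deviation in km;
#'   default 0.01 (10 m, typical smartphone accuracy).
#' @param fixes_per_minute GPS sampling rate ("multiple times each
#'   minute"); default 2.
#' @param missingness Probability that any 15-minute interval records no
#'   fixes (phone off, no signal, upload gap).
#' @param mean_dwell_hours Mean length of a dwell episode at an anchor.
#' @param dwell_sdlog Log-scale SD of the log-normal episode length.
#' @param speed_kmh Straight-line travel speed between anchors.
#' @param transit_fix_prob Probability that a 15-minute interval of
#'   in-transit fixes is recorded at all; GPS in vehicles and
#'   underground drops out in long stretches, so corridors are sampled
#'   sparsely.
#' @param out_of_region_episodes Optional list of trips away, each a list
#'   with `start_day`, `duration_days`, `lat`, `lon`.
#' @return A `mobility_profile` list.
#' @export
mobility_profile <- function(anchors, dwell_weights,
                             jitter_sd_km = 0.01,
                             fixes_per_minute = 2,
                             missingness = 0.15,
                             mean_dwell_hours = 2.5,
                             dwell_sdlog = 0.5,
                             speed_kmh = 25,
                             transit_fix_prob = 0.05,
                             out_of_region_episodes = NULL) {
  anchors <- as.data.frame(anchors)
  names(anchors)[1:2] <- c("lat", "lon")
  if (abs(sum(dwell_weights) - 1) > 1e-8) {
    abort("dwell_weights must sum to 1")
  }
  if (length(dwell_weights) != nrow(anchors)) {
    abort("one dwell weight per anchor required")
  }
  structure(
    list(
      anchors = anchors, dwell_weights = dwell_weights,
      jitter_sd_km = jitter_sd_km, fixes_per_minute = fixes_per_minute,
      missingness = missingness, mean_dwell_hours = mean_dwell_hours,
      dwell_sdlog = dwell_sdlog, speed_kmh = speed_kmh,
      transit_fix_prob = transit_fix_prob,
      out_of_region_episodes = out_of_region_episodes
    ),
    class = "mobility_profile"
  )
}

#' Simulate a GPS fix stream for one participant
#'
#' Semi-Markov anchor occupancy: dwell episodes are drawn with
#' probability proportional to the profile's dwell weights and log-normal
#' lengths, so the long-run fraction of dwell time at each anchor
#' converges to the weights and the programmed entropy is
#' `-sum(w * log(w))`. Between episodes at different anchors the
#' participant travels the straight corridor at `speed_kmh`, with only a
#' small fraction of in-transit fixes actually recorded (GPS degrades in
#' vehicles), so corridors appear as sparse noise rather than spurious
#' clusters. Fixes are emitted at the profile's sampling rate with
#' isotropic Gaussian jitter (converted from km to degrees with the
#' local metric), and whole 15-minute intervals are dropped at the
#' missingness rate. Optional out-of-region episodes relocate all fixes
#' in their window to a distant point (an out-of-state trip). Fully
#' deterministic per seed.
#'
#' @param profile A [mobility_profile()].
#' @param days Number of days to simulate.
#' @param seed Integer seed.
#' @param participant_id Id string for the emitted fixes.
#' @param start_t Unix time of enrollment start.
#' @return GPS fix tibble `(participant_id, t, lat, lon, device_index)`
#'   sorted by `t`.
#' @export
simulate_mobility_trace <- function(profile, days, seed,
                                    participant_id = "P1", start_t = 0) {
  stopifnot(inherits(profile, "mobility_profile"))
  with_seed(seed, {
    total <- days * 86400
    mean_len <- profile$mean_dwell_hours * 3600
    meanlog <- log(mean_len) - profile$dwell_sdlog^2 / 2
    anc <- profile$anchors

    # dwell episodes + travel segments until the study window is covered
    seg_start <- numeric(0)
    seg_dur <- numeric(0)
    seg_transit <- logical(0)
    seg_from <- seg_to <- integer(0)
    now <- 0
    cur <- sample.int(nrow(anc), 1, prob = profile$dwell_weights)
    while (now < total) {
      len <- rlnorm(1, meanlog, profile$dwell_sdlog)
      seg_start <- c(seg_start, now)
      seg_dur <- c(seg_dur, len)
      seg_transit <- c(seg_transit, FALSE)
      seg_from <- c(seg_from, cur)
      seg_to <- c(seg_to, cur)
      now <- now + len
      nxt <- sample.int(nrow(anc), 1, prob = profile$dwell_weights)
      if (nxt != cur && now < total) {
        d <- haversine_km(anc$lat[cur], anc$lon[cur], anc$lat[nxt], anc$lon[nxt])
        tt <- d / profile$speed_kmh * 3600
        seg_start <- c(seg_start, now)
        seg_dur <- c(seg_dur, tt)
        seg_transit <- c(seg_transit, TRUE)
        seg_from <- c(seg_from, cur)
        seg_to <- c(seg_to, nxt)
        now <- now + tt
      }
      cur <- nxt
    }

    step <- 60 / profile$fixes_per_minute
    t_rel <- seq(0, total - step, by = step)
    si <- findInterval(t_rel, seg_start)
    frac <- (t_rel - seg_start[si]) / seg_dur[si]
    lat0 <- anc$lat[seg_from[si]] + frac * (anc$lat[seg_to[si]] - anc$lat[seg_from[si]])
    lon0 <- anc$lon[seg_from[si]] + frac * (anc$lon[seg_to[si]] - anc$lon[seg_from[si]])

    # GPS in transit drops out in long stretches (vehicles, underground):
    # whole 15-minute intervals of transit fixes survive only with
    # probability transit_fix_prob, so corridors yield sparse noise bins
    interval <- floor(t_rel / 900)
    transit_interval_kept <- runif(max(interval) + 1) < profile$transit_fix_prob
    keep <- !seg_transit[si] | transit_interval_kept[interval + 1]

    for (ep in profile$out_of_region_episodes) {
      win <- t_rel >= ep$start_day * 86400 &
        t_rel < (ep$start_day + ep$duration_days) * 86400
      lat0[win] <- ep$lat
      lon0[win] <- ep$lon
      keep[win] <- TRUE
    }
    lat <- lat0 + rnorm(length(t_rel), sd = profile$jitter_sd_km / 111.195)
    lon <- lon0 + rnorm(length(t_rel), sd = profile$jitter_sd_km /
                          (111.195 * cos(lat0 * pi / 180)))

    dropped <- runif(max(interval) + 1) < profile$missingness
    keep <- keep & !dropped[interval + 1]

    tibble::tibble(
      participant_id = participant_id,
      t = start_t + t_rel[keep],
      lat = lat[keep],
      lon = lon[keep],
      device_index = 0L
    )
  })
}

#' Simulate a Wi-Fi connection-event log for one participant
#'
#' Sessions arrive at per-network daily rates, with log-normal lengths;
#' within a session, connectivity events are spaced 30-120 s apart on a
#' single SSID. Session windows are laid out without overlap (a phone
#' associates with one network at a time) and separated by more than the
#' default reconstruction gap, so the programmed per-session minutes are
#' a usable ground truth: session reconstruction should recover them up
#' to one inter-event spacing per session.
#'
#' @param roster Tibble with columns `ssid`, `rate_per_day` (sessions per
#'   day) and `mean_session_minutes`.
#' @param days Number of days to simulate.
#' @param seed Integer seed.
#' @param participant_id Id string for the emitted events.
#' @param start_t Unix time of enrollment start.
#' @return Wi-Fi event tibble `(participant_id, t, ssid, ip,
#'   device_index)` sorted by `t`, with attribute `truth`: a tibble of
#'   programmed sessions `(ssid, start_t, programmed_minutes)`.
#' @export
simulate_wifi_log <- function(roster, days, seed,
                              participant_id = "P1", start_t = 0) {
  if (nrow(roster) == 0) abort("roster must contain at least one network")
  with_seed(seed, {
    n_sessions <- rpois(nrow(roster), roster$rate_per_day * days)
    ses <- tibble::tibble(
      ssid = rep(roster$ssid, n_sessions),
      mean_min = rep(roster$mean_session_minutes, n_sessions)
    )
    empty <- tibble::tibble(
      participant_id = character(), t = numeric(), ssid = character(),
      ip = NA_character_, device_index = integer()
    )
    if (nrow(ses) == 0) {
      attr(empty, "truth") <- tibble::tibble(
        ssid = character(), start_t = numeric(), programmed_minutes = numeric()
      )
      return(empty)
    }
    ses$start <- runif(nrow(ses), 0, days * 86400)
    ses$len <- rlnorm(nrow(ses), log(ses$mean_min * 60) - 0.5^2 / 2, 0.5)
    ses <- ses[order(ses$start), , drop = FALSE]
    # push overlapping sessions forward so windows are disjoint and
    # separated by > 1000 s (keeps ground truth recoverable)
    gap <- 2000
    for (i in seq_len(nrow(ses))[-1]) {
      min_start <- ses$start[i - 1] + ses$len[i - 1] + gap
      if (ses$start[i] < min_start) ses$start[i] <- min_start
    }

    events <- purrr::pmap(
      list(ses$ssid, ses$start, ses$len),
      function(ssid, start, len) {
        # expected spacing 75 s; draw enough gaps to cover the session
        gaps <- runif(ceiling(len / 30) + 1, 30, 120)
        tt <- start + c(0, cumsum(gaps))
        tibble::tibble(t = tt[tt <= start + len], ssid = ssid)
      }
    ) |>
      dplyr::bind_rows()

    out <- tibble::tibble(
      participant_id = participant_id,
      t = start_t + events$t,
      ssid = events$ssid,
      ip = NA_character_,
      device_index = 0L
    ) |>
      dplyr::arrange(.data$t)
    attr(out, "truth") <- tibble::tibble(
      ssid = ses$ssid,
      start_t = start_t + ses$start,
      programmed_minutes = ses$len / 60
    )
    out
  })
}

#' True linear effects for the symptom generator
#'
#' Defaults are magnitudes plausible for this population and instrument
#' scales: Wi-Fi minutes raise PCL-5 by 0.09 points per daily minute,
#' location entropy lowers PCL-5 by 30.55 and PHQ-9 by 7.08 points per
#' nat; Wi-Fi has no programmed effect on PHQ-9. Any element can be
#' overridden, e.g. `true_effects(beta_entropy_pcl5 = 0)` for a null
#' world.
#'
#' @param ... Named overrides of any default element.
#' @return Named list of generator coefficients and noise SDs.
#' @export
true_effects <- function(...) {
  defaults <- list(
    beta0_pcl5 = 60, beta_wifi = 0.09, beta_entropy_pcl5 = -30.55,
    beta_employed_pcl5 = -4, beta_student_pcl5 = -3, beta_shelterB_pcl5 = 3,
    noise_sd_pcl5 = 10,
    beta0_phq9 = 20, beta_wifi_phq9 = 0, beta_entropy_phq9 = -7.08,
    beta_employed_phq9 = -1.5, beta_student_phq9 = -1, beta_shelterB_phq9 = 1,
    noise_sd_phq9 = 4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown effect name(s): ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, over)
}

#' Programmed (ground-truth) feature table
#'
#' Draws a per-participant feature table directly, without simulating
#' traces: cluster counts, entropy as `normalized * ln K` with Beta
#' normalized entropy, and log-normal daily Wi-Fi minutes spanning the
#' observed 1-628 min/day range. Used for large calibration and recovery
#' simulations where trace-level generation would be wasteful.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return Tibble `(participant_id, n_clusters, entropy,
#'   normalized_entropy, mean_daily_wifi_minutes)`.
#' @export
simulate_feature_table <- function(n, seed) {
  with_seed(seed, {
    k <- sample(2:12, n, replace = TRUE)
    ne <- stats::rbeta(n, 5, 2)
    tibble::tibble(
      participant_id = sprintf("S%03d", seq_len(n)),
      n_clusters = k,
      entropy = ne * log(k),
      normalized_entropy = ne,
      mean_daily_wifi_minutes = pmin(rlnorm(n, log(120), 1), 700)
    )
  })
}

#' Simulate symptom scores from features under a known linear model
#'
#' Generates PCL-5 and PHQ-9 totals as linear functions of entropy and
#' mean daily Wi-Fi minutes plus covariate effects and Gaussian noise,
#' rounded and clipped to the instrument ranges (0-80, 0-27). Covariates
#' (`employed`, `student`, `shelter`) are taken from `features` when
#' present, otherwise drawn at the configured prevalences. The fraction
#' of scores affected by clipping is reported as attribute
#' `clipping_rate` (clipping biases recovered coefficients toward zero
#' when effects push scores past the scale ends).
#'
#' @param features Feature tibble with `entropy` and
#'   `mean_daily_wifi_minutes`.
#' @param effects Coefficient list from [true_effects()].
#' @param seed Integer seed.
#' @param employed_prev,student_prev Covariate prevalences used when the
#'   columns are absent (defaults match the study cohort: 15.8%
#'   employed, 57.9% in school).
#' @param shelter_prev Probability of shelter "A".
#' @return Participant metadata tibble `(participant_id, employed,
#'   student, shelter, phq9_total, pcl5_total)` with attribute
#'   `clipping_rate`.
#' @export
simulate_symptoms <- function(features, effects = true_effects(), seed,
                              employed_prev = 0.158, student_prev = 0.579,
                              shelter_prev = 0.5) {
  with_seed(seed, {
    n <- nrow(features)
    employed <- features[["employed"]] %||% (runif(n) < employed_prev)
    student <- features[["student"]] %||% (runif(n) < student_prev)
    shelter <- features[["shelter"]] %||% ifelse(runif(n) < shelter_prev, "A", "B")

    lin_pcl5 <- effects$beta0_pcl5 +
      effects$beta_wifi * features$mean_daily_wifi_minutes +
      effects$beta_entropy_pcl5 * features$entropy +
      effects$beta_employed_pcl5 * employed +
      effects$beta_student_pcl5 * student +
      effects$beta_shelterB_pcl5 * (shelter == "B")
    lin_phq9 <- effects$beta0_phq9 +
      effects$beta_wifi_phq9 * features$mean_daily_wifi_minutes +
      effects$beta_entropy_phq9 * features$entropy +
      effects$beta_employed_phq9 * employed +
      effects$beta_student_phq9 * student +
      effects$beta_shelterB_phq9 * (shelter == "B")

    raw_pcl5 <- round(lin_pcl5 + rnorm(n, sd = effects$noise_sd_pcl5))
    raw_phq9 <- round(lin_phq9 + rnorm(n, sd = effects$noise_sd_phq9))
    out <- tibble::tibble(
      participant_id = features$participant_id,
      employed = employed,
      student = student,
      shelter = shelter,
      phq9_total = as.integer(pmin(pmax(raw_phq9, 0), 27)),
      pcl5_total = as.integer(pmin(pmax(raw_pcl5, 0), 80))
    )
    attr(out, "clipping_rate") <- mean(
      raw_pcl5 < 0 | raw_pcl5 > 80 | raw_phq9 < 0 | raw_phq9 > 27
    )
    out
  })
}

#' Cohort generator configuration
#'
#' Defaults mirror the study's stated world: 19 participants followed for
#' up to 180 days, GPS sampled twice a minute, uneven anchor dwell, a
#' mostly-private Wi-Fi roster, covariate prevalences from the cohort
#' table, and a 3-in-19 chance of a device replacement splitting the
#' stream.
#'
#' @param n_participants Cohort size; default 19.
#' @param study_days Study window; default 180.
#' @param seed Integer master seed.
#' @param mean_active_days Mean of the log-normal per-participant active
#'   span (mean observed Wi-Fi span in the study was 87 days).
#' @param fixes_per_minute,missingness,jitter_sd_km Passed to each
#'   participant's [mobility_profile()].
#' @param center City-center `(lat, lon)` around which anchors are
#'   placed; default central Chicago.
#' @param anchor_radius_km Anchors fall within this radius of the center.
#' @param min_anchor_sep_km Minimum pairwise anchor separation; default
#'   3 km keeps clusters separable at eps 0.5 km.
#' @param device_replacement_probability Chance a participant's streams
#'   are split across an original and a replacement device.
#' @param out_of_state_probability Chance a participant takes a brief
#'   out-of-state trip (fixes outside the study region).
#' @param employed_prev,student_prev,shelter_prev Covariate prevalences.
#' @param effects [true_effects()] list for the symptom generator.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 19, study_days = 180, seed = 1,
                          mean_active_days = 90,
                          fixes_per_minute = 2, missingness = 0.15,
                          jitter_sd_km = 0.01,
                          center = c(41.8781, -87.6298),
                          anchor_radius_km = 8, min_anchor_sep_km = 3,
                          device_replacement_probability = 3 / 19,
                          out_of_state_probability = 3 / 19,
                          employed_prev = 0.158, student_prev = 0.579,
                          shelter_prev = 0.5,
                          effects = true_effects()) {
  structure(
    list(
      n_participants = n_participants, study_days = study_days, seed = seed,
      mean_active_days = mean_active_days,
      fixes_per_minute = fixes_per_minute, missingness = missingness,
      jitter_sd_km = jitter_sd_km, center = center,
      anchor_radius_km = anchor_radius_km,
      min_anchor_sep_km = min_anchor_sep_km,
      device_replacement_probability = device_replacement_probability,
      out_of_state_probability = out_of_state_probability,
      employed_prev = employed_prev, student_prev = student_prev,
      shelter_prev = shelter_prev, effects = effects
    ),
    class = "cohort_config"
  )
}

#' Place random anchors with a minimum separation
#'
#' @param k Number of anchors.
#' @param center `(lat, lon)` of the city center.
#' @param radius_km Maximum distance of an anchor from the center.
#' @param min_sep_km Minimum pairwise separation.
#' @return Data frame of `lat`, `lon`. Draws inside the current RNG
#'   state (callers seed).
#' @export
random_anchors <- function(k, center = c(41.8781, -87.6298),
                           radius_km = 15, min_sep_km = 3) {
  pts <- data.frame(lat = numeric(0), lon = numeric(0))
  tries <- 0
  while (nrow(pts) < k) {
    tries <- tries + 1
    if (tries > 1000 * k) abort("could not place separated anchors; lower min_sep_km")
    r <- radius_km * sqrt(runif(1))
    theta <- runif(1, 0, 2 * pi)
    lat <- center[1] + r * sin(theta) / 111.195
    lon <- center[2] + r * cos(theta) / (111.195 * cos(center[1] * pi / 180))
    if (nrow(pts) == 0 ||
          all(haversine_km(lat, lon, pts$lat, pts$lon) >= min_sep_km)) {
      pts <- rbind(pts, data.frame(lat = lat, lon = lon))
    }
  }
  pts
}

#' Simulate a full synthetic cohort
#'
#' For each participant: draws an anchor set and Dirichlet dwell weights
#' (the programmed entropy), an active span, a Wi-Fi roster dominated by
#' one private network plus public venue networks, simulates the GPS and
#' Wi-Fi streams, optionally splits them across a replacement device, and
#' generates symptom scores from the programmed features under the
#' configured linear model. Identical `(config, seed)` gives identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return List with `gps`, `wifi`, `participants`, `truth` (programmed
#'   per-participant ground truth: anchors count, entropy, Wi-Fi
#'   minutes/day, device split) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  base_seed <- (config$seed %% 20000) * 100000
  public_pool <- c(
    "Starbucks-Guest", "City Library Free WiFi", "CTA-Public-WiFi",
    "McDonalds Free WiFi", "Hotel-Guest", "Airport_Free_WiFi"
  )

  gps_all <- vector("list", config$n_participants)
  wifi_all <- vector("list", config$n_participants)
  truth <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%03d", i)
    s <- base_seed + i * 10

    part <- with_seed(s + 1, {
      k <- sample(2:8, 1)
      anchors <- random_anchors(
        k, config$center, config$anchor_radius_km, config$min_anchor_sep_km
      )
      w <- rgamma(k, 1)
      w <- w / sum(w)
      active <- round(min(
        config$study_days,
        rlnorm(1, log(config$mean_active_days), 0.4)
      ))
      active <- max(active, 7)
      wifi_level <- rlnorm(1, 0, 0.9) # scales daily wifi minutes (wide range)
      trip <- NULL
      if (runif(1) < config$out_of_state_probability && active > 12) {
        # brief out-of-state trip, e.g. to Indianapolis
        trip <- list(list(
          start_day = runif(1, 3, active - 6),
          duration_days = runif(1, 1, 4),
          lat = 39.7684, lon = -86.1581
        ))
      }
      list(anchors = anchors, w = w, active = active,
           wifi_level = wifi_level, trip = trip,
           public_ssids = sample(public_pool, 2))
    })

    profile <- mobility_profile(
      part$anchors, part$w,
      jitter_sd_km = config$jitter_sd_km,
      fixes_per_minute = config$fixes_per_minute,
      missingness = config$missingness,
      out_of_region_episodes = part$trip
    )
    gps <- simulate_mobility_trace(profile, part$active, seed = s + 2,
                                   participant_id = pid)

    roster <- tibble::tibble(
      ssid = c(sprintf("HomeNet-%03d", i), part$public_ssids),
      rate_per_day = c(2.0, 0.4, 0.2) * part$wifi_level,
      mean_session_minutes = c(55, 18, 12)
    )
    wifi <- simulate_wifi_log(roster, part$active, seed = s + 3,
                              participant_id = pid)
    wifi_truth <- attr(wifi, "truth")

    split_day <- with_seed(s + 4, {
      if (runif(1) < config$device_replacement_probability) {
        runif(1, 0.2, 0.8) * part$active
      } else {
        NA_real_
      }
    })
    if (!is.na(split_day)) {
      gps$device_index[gps$t >= split_day * 86400] <- 1L
      wifi$device_index[wifi$t >= split_day * 86400] <- 1L
    }

    gps_all[[i]] <- gps
    wifi_all[[i]] <- wifi
    truth[[i]] <- tibble::tibble(
      participant_id = pid,
      n_anchors = nrow(part$anchors),
      entropy = -sum(part$w * log(part$w)),
      normalized_entropy = -sum(part$w * log(part$w)) / log(nrow(part$anchors)),
      mean_daily_wifi_minutes = sum(wifi_truth$programmed_minutes) / part$active,
      active_days = part$active,
      device_split_day = split_day
    )
  }

  truth <- dplyr::bind_rows(truth)
  participants <- simulate_symptoms(
    truth, effects = config$effects, seed = base_seed + 7,
    employed_prev = config$employed_prev,
    student_prev = config$student_prev,
    shelter_prev = config$shelter_prev
  )
  list(
    gps = dplyr::bind_rows(gps_all),
    wifi = dplyr::bind_rows(wifi_all),
    participants = participants,
    truth = dplyr::left_join(
      truth,
      participants[c("participant_id", "employed", "student", "shelter")],
      by = "participant_id"
    ),
    config = config
  )
}

#' Write a simulated cohort to the CSV dialect the readers consume
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `gps.csv`, `wifi.csv`,
#'   `participants.csv` and a `truth.json` ground-truth sidecar.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$gps, file.path(dir, "gps.csv"))
  readr::write_csv(cohort$wifi, file.path(dir, "wifi.csv"))
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  jsonlite::write_json(
    list(truth = cohort$truth, effects = cohort$config$effects),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  code
}
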