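#' Aggregate GPS fixes into 15-minute location bins
#'
#' GPS is sampled several times a minute, so raw fixes over-represent
#' periods of dense sampling. Fixes are grouped into half-open 900-second
#' intervals `[k*900, (k+1)*900)` aligned to the Unix epoch; a fix exactly
#' on a boundary belongs to the later bin. Each bin is represented by the
#' component-wise median of its member coordinates, which is robust to
#' single-fix GPS jitter.
#'
#' @param fixes GPS fix tibble sorted by time. If an `in_region` column is
#'   present (see [flag_out_of_region()]), out-of-region fixes are dropped
#'   before binning, since they are excluded from cluster generation.
#' @param bin_seconds Bin width; default 900 s (15 minutes).
#' @return Tibble `(participant_id, bin_start, lat, lon, n_fixes)` sorted
#'   by participant and bin start.
#' @export
aggregate_bins <- function(fixes, bin_seconds = 900) {
  if ("in_region" %in% names(fixes)) {
    fixes <- fixes[fixes$in_region, , drop = FALSE]
  }
  if (nrow(fixes) == 0) {
    return(tibble::tibble(
      participant_id = character(), bin_start = numeric(),
      lat = numeric(), lon = numeric(), n_fixes = integer()
    ))
  }
  fixes |>
    dplyr::mutate(bin_start = floor(.data$t / bin_seconds) * bin_seconds) |>
    dplyr::group_by(.data$participant_id, .data$bin_start) |>
    dplyr::summarise(
      lat = median(.data$lat),
      lon = median(.data$lon),
      n_fixes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$participant_id, .data$bin_start)
}

#' Density-based clustering of location bins (great-circle metric)
#'
#' Standard density-based clustering (DBSCAN) under the haversine metric:
#' a bin is a core point when at least `min_pts` bins (itself included)
#' lie within `eps_km`; clusters are the maximal density-connected sets;
#' everything else is noise. Unlike textbook DBSCAN the result here is
#' invariant to input order: clusters are the connected components of the
#' core-point graph, a border point is attached to the cluster of its
#' lowest-index core neighbour, and labels are canonicalised by each
#' cluster's smallest member index.
#'
#' @param bins Location-bin tibble from [aggregate_bins()]; may contain
#'   several participants (clustered independently).
#' @param eps_km Neighbourhood radius in km; default 0.5.
#' @param min_pts Minimum neighbourhood size for a core point; default 5.
#' @return `bins` with an integer `cluster` column (`NA` = noise),
#'   clusters numbered 1..K per participant.
#' @export
cluster_bins <- function(bins, eps_km = 0.5, min_pts = 5) {
  if (eps_km <= 0) abort("eps_km must be positive")
  if (min_pts < 1) abort("min_pts must be at least 1")
  if (nrow(bins) == 0) {
    return(dplyr::mutate(bins, cluster = integer()))
  }
  bins |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(b, key) {
      b$cluster <- dbscan_haversine(b$lat, b$lon, eps_km, min_pts)
      b
    }) |>
    dplyr::ungroup()
}

# Grid-indexed DBSCAN on the sphere. Returns integer labels, NA for noise.
# Neighbor queries go through a lat/lon grid whose cells each span at
# least eps_km, so a 3x3 block of cells covers any point's eps-ball;
# candidates are then verified with the exact haversine distance.
# Neighbor sets are recomputed on demand rather than stored: dense anchor
# clouds would otherwise need O(n^2) memory.
dbscan_haversine <- function(lat, lon, eps_km, min_pts) {
  n <- length(lat)
  if (n == 0) return(integer(0))
  check_coords(lat, lon)

  deg_lat <- eps_km / 110.574
  cmin <- max(min(cos(lat * pi / 180)), 0.01) # cos floor: finite cells near poles
  deg_lon <- eps_km / (111.320 * cmin)
  cx <- floor(lat / deg_lat)
  cy <- floor(lon / deg_lon)
  keys <- paste(cx, cy)
  cell_index <- split(seq_len(n), keys)
  block_of <- lapply(cell_index, function(idx) {
    i <- idx[1]
    unlist(
      cell_index[paste(rep(cx[i] + (-1:1), each = 3), cy[i] + (-1:1))],
      use.names = FALSE
    )
  })
  nb <- function(i) {
    cand <- block_of[[keys[i]]]
    cand[haversine_km(lat[i], lon[i], lat[cand], lon[cand]) <= eps_km]
  }

  is_core <- logical(n)
  for (i in seq_len(n)) {
    cand <- block_of[[keys[i]]]
    is_core[i] <- sum(haversine_km(lat[i], lon[i], lat[cand], lon[cand]) <= eps_km) >= min_pts
  }

  # clusters = connected components of the core-point graph, found by BFS
  # seeded in increasing index order (order-independent by construction)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is_core[s] || !is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    head_ptr <- 1L
    while (head_ptr <= length(queue)) {
      i <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      cnb <- nb(i)
      cnb <- cnb[is_core[cnb] & is.na(comp[cnb])]
      if (length(cnb) > 0) {
        comp[cnb] <- cid
        queue <- c(queue, cnb)
      }
    }
  }

  # border points attach to the cluster of their lowest-index core
  # neighbour (deterministic tie-break)
  labels <- comp
  for (i in which(!is_core)) {
    cnb <- nb(i)
    cnb <- cnb[is_core[cnb]]
    if (length(cnb) > 0) labels[i] <- comp[min(cnb)]
  }

  # canonicalise: clusters numbered by smallest member index
  roots <- unique(labels[!is.na(labels)])
  first_member <- vapply(roots, function(r) min(which(labels == r)), integer(1))
  match(labels, roots[order(first_member)])
}

#' Per-cluster centroids and occupancy fractions
#'
#' @param clustered Output of [cluster_bins()].
#' @return Tibble `(participant_id, cluster, centroid_lat, centroid_lon,
#'   n_bins, occupancy_fraction)`; occupancy fractions are over clustered
#'   bins only (noise excluded) and sum to 1 per participant.
#' @export
cluster_centroids <- function(clustered) {
  clustered |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$participant_id, .data$cluster) |>
    dplyr::summarise(
      centroid_lat = mean(.data$lat),
      centroid_lon = mean(.data$lon),
      n_bins = dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(occupancy_fraction = .data$n_bins / sum(.data$n_bins)) |>
    dplyr::ungroup()
}

#' Location entropy over cluster occupancy
#'
#' Entropy of the distribution of time across location clusters,
#' `E = -sum(p_i * ln p_i)`, where `p_i` is the fraction of clustered
#' time spent in cluster `i`. Each bin carries a uniform 900-second
#' weight; noise bins belong to no cluster and are excluded from both
#' numerator and denominator. High entropy means time was spread evenly
#' across locations; a participant with a single cluster has entropy 0.
#'
#' @param cluster_labels Integer cluster labels for one participant's
#'   bins (`NA` = noise), as produced by [cluster_bins()].
#' @return List with `entropy` (nats; `NA` if no bin was clustered) and
#'   `p`, the named occupancy-fraction vector.
#' @export
compute_entropy <- function(cluster_labels) {
  labs <- cluster_labels[!is.na(cluster_labels)]
  if (length(labs) == 0) {
    return(list(entropy = NA_real_, p = numeric(0)))
  }
  p <- as.vector(table(labs)) / length(labs)
  names(p) <- names(table(labs))
  list(entropy = -sum(p * log(p)), p = p)
}

#' Normalized location entropy
#'
#' Entropy divided by its maximum `ln K` for `K` clusters, giving a value
#' in `[0, 1]` comparable across participants with different cluster
#' counts. Undefined (returned as `NA`) for participants with fewer than
#' two clusters.
#'
#' @param entropy Entropy in nats.
#' @param k Number of clusters.
#' @return Normalized entropy in `[0, 1]`, or `NA` when `k <= 1`.
#' @export
normalized_entropy <- function(entropy, k) {
  ifelse(k >= 2, entropy / log(k), NA_real_)
}

#' Daily travel distance from consecutive GPS fixes
#'
#' Sums great-circle leg distances between consecutive fixes, per local
#' calendar day; a leg crossing midnight is assigned to the day it
#' started. All fixes contribute (including out-of-region travel): the
#' distance actually covered includes trips away. A day with fewer than
#' two fixes has distance 0.
#'
#' @param fixes GPS fix tibble sorted by `(participant_id, t)`.
#' @param tz Local time zone.
#' @return Tibble `(participant_id, day, km, miles)`, one row per
#'   participant-day with at least one fix.
#' @export
daily_distance_km <- function(fixes, tz = "America/Chicago") {
  if (nrow(fixes) == 0) {
    return(tibble::tibble(
      participant_id = character(), day = as.Date(character()),
      km = numeric(), miles = numeric()
    ))
  }
  fixes |>
    dplyr::arrange(.data$participant_id, .data$t) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(f, key) {
      n <- nrow(f)
      leg_km <- if (n >= 2) {
        haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
      } else {
        numeric(0)
      }
      legs <- tibble::tibble(day = local_day(f$t[-n], tz), km = leg_km)
      all_days <- tibble::tibble(day = unique(local_day(f$t, tz)))
      legs |>
        dplyr::group_by(.data$day) |>
        dplyr::summarise(km = sum(.data$km), .groups = "drop") |>
        dplyr::right_join(all_days, by = "day") |>
        dplyr::mutate(km = ifelse(is.na(.data$km), 0, .data$km)) |>
        dplyr::arrange(.data$day)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(miles = km_to_miles(.data$km))
}

#' Per-participant mobility feature set
#'
#' Runs the location half of the pipeline: 15-minute binning of in-region
#' fixes, density-based clustering, entropy and normalized entropy over
#' cluster occupancy, and mean daily travel distance over all fixes.
#'
#' @param fixes GPS fix tibble (ideally already passed through
#'   [flag_out_of_region()]; without an `in_region` column all fixes are
#'   treated as in-region).
#' @param eps_km,min_pts Clustering parameters; defaults 0.5 km and 5.
#' @param tz Local time zone.
#' @return Tibble with one row per participant: `n_clusters`, `entropy`,
#'   `normalized_entropy`, `mean_daily_distance_km`, `days_observed`,
#'   `n_bins`, `n_noise_bins`.
#' @export
compute_mobility_features <- function(fixes, eps_km = 0.5, min_pts = 5,
                                      tz = "America/Chicago") {
  bins <- aggregate_bins(fixes)
  clustered <- cluster_bins(bins, eps_km = eps_km, min_pts = min_pts)

  ent <- clustered |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_clusters = dplyr::n_distinct(.data$cluster, na.rm = TRUE),
      entropy = compute_entropy(.data$cluster)$entropy,
      n_bins = dplyr::n(),
      n_noise_bins = sum(is.na(.data$cluster)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      entropy = ifelse(.data$n_clusters >= 1 & is.na(.data$entropy), 0, .data$entropy),
      normalized_entropy = normalized_entropy(.data$entropy, .data$n_clusters)
    )

  dist <- daily_distance_km(fixes, tz = tz) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_daily_distance_km = mean(.data$km),
      days_observed = dplyr::n(),
      .groups = "drop"
    )

  dplyr::full_join(ent, dist, by = "participant_id") |>
    dplyr::select(
      "participant_id", "n_clusters", "entropy", "normalized_entropy",
      "mean_daily_distance_km", "days_observed", "n_bins", "n_noise_bins"
    )
}
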