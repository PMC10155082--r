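mk_fixes <- function(t, lat, lon, id = "P1") {
  tibble::tibble(participant_id = id, t = t, lat = lat, lon = lon,
                 device_index = 0L)
}

test_that("15-minute binning is half-open with a median representative", {
  # four fixes in one interval at identical coordinates
  b1 <- aggregate_bins(mk_fixes(c(0, 100, 400, 899), rep(41.88, 4), rep(-87.63, 4)))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$lat, 41.88)
  expect_equal(b1$n_fixes, 4L)

  # a fix exactly at the 900-s boundary belongs to the later bin
  b2 <- aggregate_bins(mk_fixes(c(899, 900), c(41.88, 41.88), c(-87.63, -87.63)))
  expect_equal(b2$bin_start, c(0, 900))

  # median is robust to one outlier coordinate
  lat <- c(41.88, 41.88, 41.88, 45.00)
  b3 <- aggregate_bins(mk_fixes(c(0, 10, 20, 30), lat, rep(-87.63, 4)))
  expect_equal(b3$lat, median(lat))
  expect_equal(b3$lat, 41.88)

  expect_equal(nrow(aggregate_bins(mk_fixes(numeric(0), numeric(0), numeric(0)))), 0)

  # out-of-region fixes are dropped from binning when flagged
  fx <- mk_fixes(c(0, 10), c(41.88, 39.77), c(-87.63, -86.16))
  fx$in_region <- c(TRUE, FALSE)
  expect_equal(nrow(aggregate_bins(fx)), 1)
})

test_that("haversine distance matches closed-form arcs", {
  r <- 6371.0088
  expect_equal(haversine_km(41.88, -87.63, 41.88, -87.63), 0)
  expect_equal(haversine_km(0, 0, 0, 1), r * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 180), r * pi, tolerance = 1e-6)
  # symmetry
  expect_equal(haversine_km(41.9, -87.6, 42.0, -87.7),
               haversine_km(42.0, -87.7, 41.9, -87.6))
  expect_equal(km_to_miles(1), 0.621371)
})

test_that("density clustering handles canonical small configurations", {
  # 5 coincident bins + 1 bin 10 km away: one cluster of 5, one noise
  b <- tibble::tibble(
    participant_id = "P1", bin_start = 900 * (0:5),
    lat = c(rep(41.88, 5), 41.97), lon = rep(-87.63, 6), n_fixes = 1L
  )
  got <- cluster_bins(b)
  expect_equal(got$cluster, c(rep(1L, 5), NA_integer_))

  # 4 coincident bins with min_pts 5: all noise
  got4 <- cluster_bins(b[1:4, ], min_pts = 5)
  expect_true(all(is.na(got4$cluster)))

  # two 10-bin groups 10 km apart: exactly 2 clusters
  b2 <- tibble::tibble(
    participant_id = "P1", bin_start = 900 * (0:19),
    lat = c(rep(41.88, 10), rep(41.97, 10)), lon = rep(-87.63, 20),
    n_fixes = 1L
  )
  got2 <- cluster_bins(b2)
  expect_equal(length(unique(got2$cluster)), 2)
  expect_true(same_partition(got2$cluster, dbscan_oracle(b2$lat, b2$lon, 0.5, 5)))

  expect_error(cluster_bins(b, eps_km = 0), "eps")
  expect_error(cluster_bins(b, min_pts = 0), "min_pts")
})

test_that("clustering is permutation-invariant and eps-monotone in noise", {
  set.seed(77)
  for (rep in 1:15) {
    n <- sample(10:40, 1)
    lat <- 41.8 + runif(n, 0, 0.05)
    lon <- -87.7 + runif(n, 0, 0.05)
    b <- tibble::tibble(participant_id = "P1", bin_start = 900 * seq_len(n),
                        lat = lat, lon = lon, n_fixes = 1L)
    base <- cluster_bins(b, eps_km = 0.8, min_pts = 4)$cluster

    perm <- sample(n)
    permuted <- cluster_bins(b[perm, ], eps_km = 0.8, min_pts = 4)$cluster
    expect_true(same_partition(base, permuted[order(perm)]))

    # increasing eps never increases the number of noise points
    noise_small <- sum(is.na(cluster_bins(b, eps_km = 0.4, min_pts = 4)$cluster))
    noise_large <- sum(is.na(cluster_bins(b, eps_km = 1.2, min_pts = 4)$cluster))
    expect_lte(noise_large, noise_small)
  }
})

test_that("entropy follows the occupancy formula and normalization bounds", {
  # two clusters, equal time
  e2 <- compute_entropy(rep(c(1L, 2L), each = 10))
  expect_equal(e2$entropy, log(2))
  expect_equal(sum(e2$p), 1, tolerance = 1e-9)

  # single cluster
  expect_equal(compute_entropy(rep(1L, 7))$entropy, 0)

  # p = (0.75, 0.25)
  e34 <- compute_entropy(rep(c(1L, 2L), times = c(15, 5)))
  expect_equal(e34$entropy, -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(e34$entropy, 0.5623, tolerance = 1e-4)

  # noise excluded from numerator and denominator
  with_noise <- compute_entropy(c(rep(c(1L, 2L), each = 10), rep(NA_integer_, 5)))
  expect_equal(with_noise$entropy, log(2))

  # all-noise participant: feature missing
  expect_true(is.na(compute_entropy(rep(NA_integer_, 4))$entropy))

  expect_equal(normalized_entropy(log(2), 2), 1)
  expect_true(is.na(normalized_entropy(0, 1)))
  expect_equal(normalized_entropy(0.5623, 2), 0.8113, tolerance = 1e-4)

  # 0 <= E <= ln K and normalized in [0, 1] on random occupancy vectors
  set.seed(88)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    labs <- sample.int(k, 200, replace = TRUE)
    e <- compute_entropy(labs)
    expect_gte(e$entropy, 0)
    expect_lte(e$entropy, log(k) + 1e-12)
    ne <- normalized_entropy(e$entropy, length(unique(labs)))
    expect_gte(ne, 0)
    expect_lte(ne, 1)
  }
})

test_that("daily distance sums consecutive legs within local days", {
  # stationary participant: zero km every day
  t <- seq(0, 3 * 86400 - 1, by = 3600)
  stat <- daily_distance_km(mk_fixes(t, rep(41.88, length(t)), rep(-87.63, length(t))),
                            tz = "UTC")
  expect_equal(nrow(stat), 3)
  expect_equal(stat$km, rep(0, 3))

  # two fixes ~1 km apart in one day
  dlat <- 1 / 111.19492664455873 # one km of latitude
  two <- daily_distance_km(mk_fixes(c(0, 600), c(41.88, 41.88 + dlat),
                                    c(-87.63, -87.63)), tz = "UTC")
  expect_equal(two$km, 1, tolerance = 1e-3)
  expect_equal(two$miles, km_to_miles(two$km))

  # A -> B -> A with |AB| = 2 km gives 4 km
  dlat2 <- 2 / 111.19492664455873
  aba <- daily_distance_km(
    mk_fixes(c(0, 600, 1200), c(41.88, 41.88 + dlat2, 41.88), rep(-87.63, 3)),
    tz = "UTC"
  )
  expect_equal(aba$km, 4, tolerance = 1e-3)

  # a leg crossing midnight is charged to the day it started
  cross <- daily_distance_km(
    mk_fixes(c(86400 - 600, 86400 + 600), c(41.88, 41.88 + dlat2), rep(-87.63, 2)),
    tz = "UTC"
  )
  expect_equal(cross$km[cross$day == as.Date("1970-01-01")], 2, tolerance = 1e-3)
  expect_equal(cross$km[cross$day == as.Date("1970-01-02")], 0)
})
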