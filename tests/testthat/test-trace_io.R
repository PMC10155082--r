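test_that("GPS reader keeps well-formed rows, rejects bad ones, sorts by time", {
  gps <- tibble::tibble(
    participant_id = c("P1", "P1", "P1"),
    t = c(300, 0, 600),
    lat = c(41.88, 41.88, 41.89),
    lon = c(-87.63, -87.63, -87.64)
  )
  path <- tmp_csv(gps, "gps.csv")
  got <- read_gps_csv(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$t, sort(gps$t)) # explicit sort oracle
  expect_equal(attr(got, "n_rejected"), 0)

  bad <- gps
  bad$lat[2] <- 95
  got2 <- read_gps_csv(tmp_csv(bad, "gps_bad.csv"))
  expect_equal(nrow(got2), 2)
  expect_equal(attr(got2, "n_rejected"), 1)

  unparseable <- gps
  unparseable$t <- as.character(unparseable$t)
  unparseable$t[1] <- "not-a-time"
  got3 <- read_gps_csv(tmp_csv(unparseable, "gps_nat.csv"))
  expect_equal(attr(got3, "n_rejected"), 1)
})

test_that("missing required columns are fatal; round-trips are lossless", {
  gps <- tibble::tibble(
    participant_id = "P1", t = 0, lat = 41.88, lon = -87.63
  )
  no_lon <- gps[c("participant_id", "t", "lat")]
  expect_error(read_gps_csv(tmp_csv(no_lon, "nolon.csv")), "lon")

  first <- read_gps_csv(tmp_csv(gps, "rt.csv"))
  dir <- withr::local_tempdir()
  write_stream_csv(first, file.path(dir, "rt2.csv"))
  second <- read_gps_csv(file.path(dir, "rt2.csv"))
  expect_equal(as.data.frame(first), as.data.frame(second))

  meta <- tibble::tibble(
    participant_id = "P1", employed = TRUE, student = FALSE,
    shelter = "A", phq9_total = 28L, pcl5_total = 10L
  )
  expect_error(read_participants_csv(tmp_csv(meta, "meta.csv")), "range")
})

test_that("device streams merge into one sorted sequence with exact dedup", {
  d0 <- tibble::tibble(
    participant_id = "P1", t = c(0, 86400 * 30), ssid = "HomeNet",
    ip = NA_character_, device_index = 0L
  )
  d1 <- tibble::tibble(
    participant_id = "P1", t = c(86400 * 32, 86400 * 33), ssid = "HomeNet",
    ip = NA_character_, device_index = 1L
  )
  merged <- merge_device_streams(list(d0, d1))
  expect_equal(nrow(merged), 4)
  expect_false(is.unsorted(merged$t))
  # the device gap is preserved, not interpolated
  expect_true((86400 * 32 - 86400 * 30) %in% diff(merged$t))

  # single device: identity
  expect_equal(as.data.frame(merge_device_streams(d0)), as.data.frame(d0))

  # exact duplicate payload appears once; near-duplicates are kept
  dup <- d1
  dup$device_index <- 0L
  merged2 <- merge_device_streams(list(d0, d1, dup))
  expect_equal(nrow(merged2), 4)
  expect_equal(nrow(merged2), nrow(d0) + nrow(d1) + nrow(dup) - 2)

  d_other <- d1
  d_other$participant_id <- "P2"
  expect_error(merge_device_streams(list(d0, d_other)), "different participants")
})

test_that("inclusion filters enforce 14 wifi days (strict less-than) and 180-day window", {
  day <- 86400
  mk_wifi <- function(id, days) {
    tibble::tibble(
      participant_id = id, t = (days - 1) * day + 6 * 3600,
      ssid = "HomeNet", ip = NA_character_, device_index = 0L
    )
  }
  wifi <- dplyr::bind_rows(
    mk_wifi("P13", 1:13),   # 13 distinct days -> excluded
    mk_wifi("P14", 1:14),   # exactly 14 -> retained
    mk_wifi("P200", 1:200)  # events past day 180 are truncated first
  )
  gps <- tibble::tibble(
    participant_id = character(), t = numeric(), lat = numeric(),
    lon = numeric(), device_index = integer()
  )
  participants <- tibble::tibble(
    participant_id = c("P13", "P14", "P200", "Pnone"),
    employed = FALSE, student = FALSE, shelter = "A",
    phq9_total = 5L, pcl5_total = 10L
  )
  res <- apply_inclusion_filters(participants, wifi, gps, tz = "UTC")

  expect_setequal(res$participants$participant_id, c("P14", "P200"))
  expect_true("P13" %in% res$exclusions$participant_id)
  expect_match(res$exclusions$reason[res$exclusions$participant_id == "Pnone"],
               "no data")
  # window is [start, start + 180 days): hand-count = 180 days survive
  p200 <- res$wifi[res$wifi$participant_id == "P200", ]
  expect_equal(nrow(p200), 180)
  expect_true(all(p200$t < min(p200$t) + 180 * day))

  # exclusion report + retained = input participants
  expect_equal(nrow(res$exclusions) + nrow(res$participants), nrow(participants))

  # idempotence: filtering a filtered cohort changes nothing
  res2 <- apply_inclusion_filters(res$participants, res$wifi, res$gps, tz = "UTC")
  expect_equal(as.data.frame(res2$participants), as.data.frame(res$participants))
  expect_equal(as.data.frame(res2$wifi), as.data.frame(res$wifi))
  expect_equal(nrow(res2$exclusions), 0)
})

test_that("out-of-region flagging uses a closed box and matches a point-in-box oracle", {
  box <- list(lat_min = 41, lat_max = 42, lon_min = -88, lon_max = -87)
  fixes <- tibble::tibble(
    participant_id = "P1",
    t = seq_len(100),
    lat = seq(40.5, 42.5, length.out = 100),
    lon = rep(-87.5, 100),
    device_index = 0L
  )
  flagged <- flag_out_of_region(fixes, box)
  oracle <- fixes$lat >= 41 & fixes$lat <= 42 # lon always inside
  expect_equal(flagged$in_region, oracle)

  boundary <- tibble::tibble(
    participant_id = "P1", t = 1, lat = 42, lon = -88, device_index = 0L
  )
  expect_true(flag_out_of_region(boundary, box)$in_region)

  expect_error(
    flag_out_of_region(fixes, list(lat_min = 42, lat_max = 41,
                                   lon_min = -88, lon_max = -87)),
    "empty"
  )
})
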