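ts0 <- function(...) as.POSIXct(paste("2021-11-03", c(...)), tz = "UTC")

rec <- function(times, camera = "CT01", species = "roe")
  data.frame(camera_id = camera, timestamp = times, species = species)

test_that("the 5-minute gap rule splits and merges image bursts correctly", {
  ev <- group_events(rec(ts0("10:00:00", "10:02:00", "10:08:00")))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_time[1], ts0("10:00:00"))
  expect_equal(ev$end_time[1], ts0("10:02:00"))
  expect_equal(ev$n_images, c(2L, 1L))

  # a gap of exactly the threshold starts a new event
  ev2 <- group_events(rec(ts0("10:00:00", "10:05:00")))
  expect_equal(nrow(ev2), 2L)
  ev3 <- group_events(rec(ts0("10:00:00", "10:04:59")))
  expect_equal(nrow(ev3), 1L)

  # empty stream
  expect_equal(nrow(group_events(rec(ts0())[0, ])), 0L)
})

test_that("event counts match a brute-force gap scan on random streams", {
  set.seed(42)
  for (rep in 1:5) {
    mins <- sort(sample(0:1439, 100))
    times <- as.POSIXct("2021-12-01", tz = "UTC") + mins * 60
    ev <- group_events(rec(times), gap_minutes = 5)
    expect_equal(nrow(ev), oracle_event_count(mins, 5))
    expect_equal(sum(ev$n_images), 100L)
  }
})

test_that("grouping is idempotent and monotone in the gap threshold", {
  set.seed(7)
  mins <- sort(sample(0:2000, 150, replace = TRUE))
  times <- as.POSIXct("2021-12-01", tz = "UTC") + mins * 60
  ev <- group_events(rec(times))
  again <- group_events(rec(ev$start_time))
  expect_equal(nrow(again), nrow(ev))

  counts <- vapply(c(1, 2, 5, 10, 30), function(g)
    nrow(group_events(rec(times), gap_minutes = g)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("streams are split by camera and species and input is validated", {
  r <- rbind(rec(ts0("10:00:00", "10:01:00"), camera = "CT01"),
             rec(ts0("10:02:00"), camera = "CT02", species = "red"),
             rec(ts0("10:00:30"), camera = "CT02"))
  ev <- group_events(r)
  expect_equal(nrow(ev), 3L)

  bad <- rec(ts0("10:08:00", "10:00:00"))
  expect_error(group_events(bad), "sorted")
  expect_error(group_events(r, gap_minutes = -1), "positive")
})

test_that("capture rate is events per hundred trap days", {
  expect_equal(round(capture_rate(2594, 6244), 2), 41.54)
  expect_equal(round(capture_rate(124, 6244), 2), 1.99)
  expect_equal(capture_rate(0, 6244), 0)
  expect_error(capture_rate(10, 0), "positive")
})

test_that("detection arrays align occasions on the calendar and respect deployments", {
  dep <- data.frame(camera_id = "CT01",
                    start_date = "2021-11-05", end_date = "2021-11-14")
  # two events on the same day collapse to one detection
  ev <- group_events(rec(ts0("10:00:00", "11:00:00")))
  ev$start_time <- ev$start_time + 3 * 86400  # move to Nov 6
  ev$end_time <- ev$end_time + 3 * 86400
  arr <- build_detection_array(ev, dep, "roe",
                               study_start = "2021-11-01",
                               study_end = "2021-11-15")
  expect_equal(dim(arr), c(1L, 15L, 1L))
  row <- arr[1, , 1]
  expect_true(all(is.na(row[1:4])))   # before deployment
  expect_true(is.na(row[15]))         # after deployment
  expect_equal(sum(row == 1, na.rm = TRUE), 1L)
  expect_equal(sum(row == 0, na.rm = TRUE), 9L)
  expect_equal(sum(!is.na(row)), 10L) # trap days, both ends closed

  # events outside the deployment are rejected with the row listed
  late <- rec(as.POSIXct("2021-11-20 10:00:00", tz = "UTC"))
  expect_error(build_detection_array(group_events(late), dep, "roe"),
               "outside")
})

test_that("non-missing site-days equal total trap days across a survey", {
  sim <- simulate_survey(sim_config(J = 25), seed = 5)
  arr <- build_detection_array(group_events(sim$records), sim$deployments,
                               sim$config$species,
                               sim$config$study_start, sim$config$study_end)
  td <- trap_days(sim$deployments)$trap_days
  for (s in sim$config$species)
    expect_equal(sum(!is.na(arr[, , s])), sum(td))
})

test_that("naive occupancy counts occupied sites among surveyed sites", {
  arr <- array(0L, c(8, 4, 2), dimnames = list(NULL, NULL, c("roe", "red")))
  arr[1:3, 1, "roe"] <- 1L
  arr[8, , ] <- NA_integer_  # site never surveyed
  no <- naive_occupancy(arr)
  expect_equal(unname(no["roe"]), 3 / 7)
  expect_equal(unname(no["red"]), 0)
  expect_error(naive_occupancy(arr, "wolf"), "not in array")

  arr[, , "red"] <- 1L
  arr[8, , ] <- NA_integer_
  expect_equal(unname(naive_occupancy(arr, "red")), 1)
})

test_that("event summaries combine events, effort and naive occupancy", {
  sim <- simulate_survey(sim_config(J = 15), seed = 9)
  ev <- group_events(sim$records)
  arr <- build_detection_array(ev, sim$deployments, sim$config$species,
                               sim$config$study_start, sim$config$study_end)
  tab <- event_summary(ev, arr)
  expect_equal(tab$species, sim$config$species)
  effort <- sum(trap_days(sim$deployments)$trap_days)
  expect_equal(tab$capture_rate, tab$n_events / effort * 100)
  # a one in the array requires at least one event that day
  for (s in sim$config$species) {
    hits <- which(arr[, , s] == 1, arr.ind = TRUE)
    evs <- ev[ev$species == s, ]
    dates <- as.Date(format(evs$start_time))
    for (r in seq_len(nrow(hits))) {
      day <- as.Date(dimnames(arr)[[2]][hits[r, 2]])
      cam <- dimnames(arr)[[1]][hits[r, 1]]
      expect_true(any(evs$camera_id == cam & dates == day))
    }
  }
})
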