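#' Group classified camera-trap images into independent detection events
#'
#' Camera traps fire bursts of photographs while an animal stays in the field
#' of view, so raw image counts overstate activity. Consecutive images of the
#' same species at the same camera are collapsed into one event; a new event
#' starts whenever the time since the *previous image* reaches the gap
#' threshold (5 minutes by default, the interval commonly used to declare
#' independence of camera-trap records).
#'
#' Photographs containing two species must already have been duplicated, one
#' row per species, so that every record carries exactly one species label.
#'
#' @param records data frame with columns `camera_id`, `timestamp`
#'   (`POSIXct`, or a string parseable by [as.POSIXct()]), `species`, and
#'   optionally `n_individuals`. Must be sorted by (camera_id, species,
#'   timestamp).
#' @param gap_minutes positive number; two consecutive images of the same
#'   species at the same camera separated by at least this many minutes
#'   belong to different events.
#' @return data frame of events with columns `camera_id`, `species`,
#'   `start_time`, `end_time`, `n_images`.
#' @examples
#' rec <- data.frame(
#'   camera_id = "CT01", species = "roe",
#'   timestamp = as.POSIXct("2021-11-03 10:00:00", tz = "UTC") +
#'     c(0, 120, 480)
#' )
#' group_events(rec)  # 2 events: 10:00-10:02 and 10:08
#' @export
group_events <- function(records, gap_minutes = 5) {
  if (!is.numeric(gap_minutes) || length(gap_minutes) != 1L || gap_minutes <= 0)
    stop("`gap_minutes` must be a single positive number")
  records <- as.data.frame(records)
  need <- c("camera_id", "timestamp", "species")
  if (!all(need %in% names(records)))
    stop("`records` must have columns ", paste(need, collapse = ", "))
  empty <- data.frame(
    camera_id = character(), species = character(),
    start_time = as.POSIXct(character(), tz = "UTC"),
    end_time = as.POSIXct(character(), tz = "UTC"),
    n_images = integer()
  )
  if (nrow(records) == 0L) return(empty)
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in `records`")

  key <- paste(records$camera_id, records$species, sep = "\r")
  ord <- order(key, ts, method = "radix")
  if (any(diff(ord) < 0))
    stop("`records` must be sorted by (camera_id, species, timestamp)")

  same_stream <- key[-1L] == key[-length(key)]
  dt_min <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "mins"))
  # a record continues the previous event iff same stream and gap < threshold
  new_event <- c(TRUE, !(same_stream & dt_min < gap_minutes))
  last_of_event <- c(new_event[-1L], TRUE)
  ev_id <- cumsum(new_event)

  data.frame(
    camera_id = records$camera_id[new_event],
    species = records$species[new_event],
    start_time = ts[new_event],
    end_time = ts[last_of_event],
    n_images = tabulate(ev_id),
    row.names = NULL
  )
}

#' Capture rate per 100 trap days
#'
#' The standard relative-activity index: number of independent events divided
#' by the sampling effort, expressed per hundred trap days.
#'
#' @param n_events non-negative event count (vectorised).
#' @param trap_days positive total number of camera operating days.
#' @return events per 100 trap days.
#' @examples
#' capture_rate(2594, 6244)  # 41.54
#' @export
capture_rate <- function(n_events, trap_days) {
  if (any(trap_days <= 0)) stop("`trap_days` must be positive")
  if (any(n_events < 0)) stop("`n_events` must be non-negative")
  n_events / trap_days * 100
}

#' Trap days per deployment
#'
#' Deployment intervals are closed on both ends: the first and last calendar
#' day both count as trap days.
#'
#' @param deployments data frame with columns `camera_id`, `start_date`,
#'   `end_date` (`Date` or parseable strings).
#' @return the input with a `trap_days` column appended.
#' @export
trap_days <- function(deployments) {
  d <- as.data.frame(deployments)
  sd <- as.Date(d$start_date); ed <- as.Date(d$end_date)
  if (any(ed < sd)) stop("deployment end_date before start_date")
  d$trap_days <- as.integer(ed - sd) + 1L
  d
}

#' Build daily detection histories from events
#'
#' Converts events and a deployment table into a sites x occasions x species
#' array of daily detection/non-detection. Occasions are calendar days on a
#' global study window shared by all sites, so day-level covariates (hunting
#' calendar, human presence) align across cameras. A cell is 1 if at least
#' one event of that species overlapped that site-day, 0 on deployed days
#' with no event, and `NA` outside the site's deployment window. Events that
#' span midnight mark every day they touch.
#'
#' @param events data frame as returned by [group_events()].
#' @param deployments data frame with columns `camera_id`, `start_date`,
#'   `end_date`; one deployment per camera/site.
#' @param species character vector of species to retain (array layer order).
#' @param study_start,study_end optional `Date`s delimiting the occasion
#'   axis; default to the deployment range.
#' @return a `detection_array`: 3-d array (site x occasion x species) with
#'   `dimnames` site ids, occasion dates (ISO), species, carrying the
#'   deployment table as an attribute.
#' @export
build_detection_array <- function(events, deployments, species,
                                  study_start = NULL, study_end = NULL) {
  dep <- trap_days(deployments)
  dep$start_date <- as.Date(dep$start_date)
  dep$end_date <- as.Date(dep$end_date)
  if (anyDuplicated(dep$camera_id))
    stop("one deployment per camera is assumed")
  study_start <- as.Date(study_start %||% min(dep$start_date))
  study_end <- as.Date(study_end %||% max(dep$end_date))
  days <- seq(study_start, study_end, by = "day")
  J <- nrow(dep); K <- length(days); S <- length(species)

  arr <- array(NA_integer_, dim = c(J, K, S),
               dimnames = list(site = dep$camera_id,
                               occasion = format(days),
                               species = species))
  for (j in seq_len(J)) {
    on <- days >= dep$start_date[j] & days <= dep$end_date[j]
    arr[j, on, ] <- 0L
  }

  ev <- as.data.frame(events)
  ev <- ev[ev$species %in% species, , drop = FALSE]
  if (nrow(ev)) {
    jj <- match(ev$camera_id, dep$camera_id)
    if (anyNA(jj))
      stop("events at cameras absent from `deployments`: ",
           paste(unique(ev$camera_id[is.na(jj)]), collapse = ", "))
    d0 <- as.Date(format(ev$start_time))  # day of each image, local midnight
    d1 <- as.Date(format(ev$end_time))
    bad <- d0 < dep$start_date[jj] | d1 > dep$end_date[jj]
    if (any(bad))
      stop("events outside their deployment window (rows ",
           paste(utils::head(which(bad), 10L), collapse = ", "), ")")
    ss <- match(ev$species, species)
    for (r in seq_len(nrow(ev))) {
      kk <- match(seq(d0[r], d1[r], by = "day"), days)
      kk <- kk[!is.na(kk)]  # events outside a narrowed study window
      arr[jj[r], kk, ss[r]] <- 1L
    }
  }
  structure(arr, deployments = dep, class = c("detection_array", "array"))
}

#' Naive occupancy
#'
#' Proportion of surveyed sites where a species was detected at least once,
#' uncorrected for imperfect detection.
#'
#' @param array a `detection_array` from [build_detection_array()], or any
#'   site x occasion x species array in \{0, 1, NA\}.
#' @param species species label (layer name); if missing, all layers.
#' @return named proportion(s).
#' @examples
#' \dontrun{naive_occupancy(arr, "roe")}
#' @export
naive_occupancy <- function(array, species = NULL) {
  sp <- species %||% dimnames(array)[[3L]]
  missing_sp <- setdiff(sp, dimnames(array)[[3L]])
  if (length(missing_sp))
    stop("species not in array: ", paste(missing_sp, collapse = ", "))
  surveyed <- apply(!is.na(array), 1L, any)
  if (!any(surveyed)) stop("no site has a non-missing occasion")
  vapply(sp, function(s) {
    det <- apply(array[, , s, drop = FALSE] == 1L, 1L, any, na.rm = TRUE)
    sum(det & surveyed) / sum(surveyed)
  }, numeric(1))
}

#' Per-species event, capture-rate and naive-occupancy summary
#'
#' One row per species: number of independent events, capture rate per 100
#' trap days, and naive occupancy — the descriptive table conventionally
#' reported for a camera-trap survey.
#'
#' @param events data frame from [group_events()].
#' @param array `detection_array` for the same survey (supplies effort and
#'   naive occupancy; its species layers define the rows).
#' @return data frame with columns `species`, `n_events`, `capture_rate`,
#'   `naive_occupancy`.
#' @export
event_summary <- function(events, array) {
  dep <- attr(array, "deployments")
  effort <- sum(dep$trap_days)
  sp <- dimnames(array)[[3L]]
  n_ev <- vapply(sp, function(s) sum(events$species == s), numeric(1))
  data.frame(
    species = sp,
    n_events = as.integer(n_ev),
    capture_rate = capture_rate(n_ev, effort),
    naive_occupancy = naive_occupancy(array),
    row.names = NULL
  )
}
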