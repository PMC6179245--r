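#' Read time-stamped camera-trap records
#'
#' Reads a delimited text file of photographic capture events and returns a
#' validated, sorted record table. Each row is one capture of one species at
#' one station; timestamps must have at least minute resolution.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping the required fields
#'   `station_id`, `species`, `timestamp` to column names in the file.
#' @param sep Field separator (default `","`).
#' @param species_list Optional character vector of allowed species labels;
#'   rows with other labels raise an error.
#' @param permissive If `TRUE`, rows with unparseable timestamps are dropped
#'   with a warning instead of aborting the read.
#' @param tz Time zone used to interpret timestamps (default UTC).
#'
#' @return A `data.frame` of class `detection_records` with columns
#'   `station_id` (character), `species` (character) and `timestamp`
#'   (`POSIXct`), sorted by (station, species, timestamp) and de-duplicated.
#'   The number of malformed rows encountered is attached as attribute
#'   `n_malformed`.
#' @export
read_records <- function(path,
                         schema = c(station_id = "station_id",
                                    species = "species",
                                    timestamp = "timestamp"),
                         sep = ",",
                         species_list = NULL,
                         permissive = FALSE,
                         tz = "UTC") {
  if (!file.exists(path)) {
    stop("records file not found: ", path)
  }
  need <- c("station_id", "species", "timestamp")
  if (!all(need %in% names(schema))) {
    stop("schema must map all of: ", paste(need, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(raw))
  if (length(missing_cols) > 0) {
    stop("records file is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(station_id = as.character(raw[[schema[["station_id"]]]]),
                    species = as.character(raw[[schema[["species"]]]]),
                    stringsAsFactors = FALSE)
  ts <- parse_timestamp(raw[[schema[["timestamp"]]]], tz = tz)
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    msg <- paste0("unparseable timestamp in row(s): ",
                  paste(utils::head(bad, 10L), collapse = ", "),
                  if (length(bad) > 10L) ", ...")
    if (!permissive) stop(msg)
    warning(msg, "; dropping ", length(bad), " row(s)")
    out <- out[-bad, , drop = FALSE]
    ts <- ts[-bad]
  }
  out$timestamp <- ts
  if (!is.null(species_list)) {
    unknown <- setdiff(unique(out$species), species_list)
    if (length(unknown) > 0) {
      stop("species not in declared species list: ",
           paste(unknown, collapse = ", "))
    }
  }
  out <- unique(out)
  out <- out[order(out$station_id, out$species, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- length(bad)
  class(out) <- c("detection_records", "data.frame")
  out
}

parse_timestamp <- function(x, tz = "UTC") {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = tz))
  }
  out
}

#' Collapse photographic bursts into independent detection events
#'
#' Within each (station, species) group, walks records in time order and
#' retains a record only if its gap to the previously *retained* record is
#' strictly greater than `window_minutes`. The first record of every group is
#' always retained. This chaining rule is idempotent: filtering a filtered
#' set is a no-op.
#'
#' @param records A `detection_records` data frame (or any data frame with
#'   `station_id`, `species`, `timestamp` columns).
#' @param window_minutes Independence window in minutes (default 5). A gap of
#'   exactly `window_minutes` is *not* independent (strict inequality).
#'
#' @return The retained records, same class and column layout as the input.
#' @export
filter_independent <- function(records, window_minutes = 5) {
  if (!is.numeric(window_minutes) || length(window_minutes) != 1 ||
      is.na(window_minutes) || window_minutes < 0) {
    stop("window_minutes must be a single non-negative number")
  }
  if (nrow(records) == 0) return(records)
  ord <- order(records$station_id, records$species, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  grp <- paste(rec$station_id, rec$species, sep = "\r")
  keep <- logical(nrow(rec))
  win_sec <- window_minutes * 60
  t_num <- as.numeric(rec$timestamp)
  last_kept <- -Inf
  last_grp <- NA_character_
  for (i in seq_len(nrow(rec))) {
    if (!identical(grp[i], last_grp)) {
      keep[i] <- TRUE
      last_grp <- grp[i]
      last_kept <- t_num[i]
    } else if (t_num[i] - last_kept > win_sec) {
      keep[i] <- TRUE
      last_kept <- t_num[i]
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a station table
#'
#' @param stations A data frame with columns `station_id`, `x`, `y`, `area`,
#'   `zone`, `trail_type`. Coordinates are planar metres.
#' @param windows Optional data frame of active deployment windows with
#'   columns `station_id`, `start`, `end` (`Date`; `end` exclusive, so a
#'   window contributes `end - start` active days). If omitted, columns
#'   `active_start` / `active_end` of `stations` are used.
#' @param trail_levels Allowed trail-type labels, reference category first.
#' @param zone_levels Allowed management-zone labels.
#'
#' @return `stations` with class `station_table` and the windows table
#'   attached as attribute `"windows"`.
#' @export
as_station_table <- function(stations, windows = NULL,
                             trail_levels = c("AT", "NT", "RD"),
                             zone_levels = c("national_park", "wma",
                                             "village_land")) {
  need <- c("station_id", "x", "y", "area", "zone", "trail_type")
  miss <- setdiff(need, names(stations))
  if (length(miss) > 0) stop("station table missing column(s): ",
                             paste(miss, collapse = ", "))
  stations$station_id <- as.character(stations$station_id)
  if (anyDuplicated(stations$station_id)) stop("duplicated station_id")
  bad_tr <- setdiff(unique(stations$trail_type), trail_levels)
  if (length(bad_tr) > 0) stop("unknown trail_type: ",
                               paste(bad_tr, collapse = ", "))
  bad_zn <- setdiff(unique(stations$zone), zone_levels)
  if (length(bad_zn) > 0) stop("unknown zone: ", paste(bad_zn, collapse = ", "))
  zz <- unique(stations[, c("area", "zone")])
  if (anyDuplicated(zz$area)) {
    stop("each sampling area must map to exactly one zone")
  }
  if (is.null(windows)) {
    if (all(c("active_start", "active_end") %in% names(stations))) {
      windows <- data.frame(station_id = stations$station_id,
                            start = as.Date(stations$active_start),
                            end = as.Date(stations$active_end),
                            stringsAsFactors = FALSE)
    } else {
      windows <- data.frame(station_id = character(0),
                            start = as.Date(character(0)),
                            end = as.Date(character(0)))
    }
  }
  windows$station_id <- as.character(windows$station_id)
  windows$start <- as.Date(windows$start)
  windows$end <- as.Date(windows$end)
  windows <- windows[!is.na(windows$start) & !is.na(windows$end), , drop = FALSE]
  if (any(!windows$start < windows$end)) {
    stop("active windows must satisfy start < end (end is exclusive)")
  }
  orphan <- setdiff(unique(windows$station_id), stations$station_id)
  if (length(orphan) > 0) stop("windows refer to unknown station(s): ",
                               paste(orphan, collapse = ", "))
  for (sid in unique(windows$station_id)) {
    w <- windows[windows$station_id == sid, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(utils::head(w$end, -1) > utils::tail(w$start, -1))) {
      stop("overlapping active windows for station ", sid)
    }
  }
  attr(stations, "windows") <- windows
  attr(stations, "trail_levels") <- trail_levels
  class(stations) <- unique(c("station_table", class(stations)))
  stations
}

#' Read a station table from delimited text
#'
#' @inheritParams read_records
#' @param ... Passed to [as_station_table()].
#' @return A `station_table` data frame.
#' @export
read_stations <- function(path, sep = ",", ...) {
  if (!file.exists(path)) stop("station file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_station_table(df, ...)
}

#' Active deployment windows of a station table
#' @param stations A `station_table`.
#' @return Data frame with columns `station_id`, `start`, `end`.
#' @export
station_windows <- function(stations) {
  w <- attr(stations, "windows")
  if (is.null(w)) stop("station table has no active windows attached")
  w
}

#' Per-occasion sampling effort
#'
#' Computes the number of active camera-days of each station within each
#' occasion of a global weekly survey grid. Occasion `j` spans the half-open
#' date interval `[survey_start + (j-1)*occasion_days, survey_start +
#' j*occasion_days)`.
#'
#' @param stations A `station_table`.
#' @param survey_start First day of occasion 1 (`Date`).
#' @param n_occasions Number of occasions `J` (default 32 weekly bins).
#' @param occasion_days Days per occasion (default 7).
#' @param windows Active windows; defaults to [station_windows()].
#'
#' @return Integer matrix (stations x occasions) of active days, row names
#'   the station ids. Entries lie in `0..occasion_days`. Stations with no
#'   active window get a zero row with a warning; window days outside the
#'   occasion grid are not counted (with a warning).
#' @export
compute_effort <- function(stations, survey_start, n_occasions = 32,
                           occasion_days = 7,
                           windows = station_windows(stations)) {
  survey_start <- as.Date(survey_start)
  sites <- stations$station_id
  eff <- matrix(0L, nrow = length(sites), ncol = n_occasions,
                dimnames = list(sites, NULL))
  occ_start <- as.numeric(survey_start) + (seq_len(n_occasions) - 1) * occasion_days
  occ_end <- occ_start + occasion_days            # exclusive
  no_window <- setdiff(sites, unique(windows$station_id))
  if (length(no_window) > 0) {
    warning("station(s) with no active window get zero effort: ",
            paste(no_window, collapse = ", "))
  }
  truncated <- FALSE
  for (r in seq_len(nrow(windows))) {
    sid <- windows$station_id[r]
    ws <- as.numeric(windows$start[r])
    we <- as.numeric(windows$end[r])
    if (ws < occ_start[1] || we > occ_end[n_occasions]) truncated <- TRUE
    ov <- pmax(0, pmin(we, occ_end) - pmax(ws, occ_start))
    eff[sid, ] <- eff[sid, ] + as.integer(ov)
  }
  if (truncated) {
    warning("some active windows extend beyond the occasion grid; ",
            "effort outside the grid is not counted")
  }
  eff
}

#' Build an occasion-binned detection history
#'
#' Bins independence-filtered records of one focal species into a sites x
#' occasions matrix of detection (1), non-detection (0) and missing (`NA`,
#' where the station had zero effort in the occasion).
#'
#' @param records Independence-filtered records of the focal species.
#' @param stations A `station_table`.
#' @param survey_start,n_occasions,occasion_days Occasion grid, as in
#'   [compute_effort()].
#' @param species Optional label: restrict `records` to this species.
#' @param effort Optional precomputed effort matrix; defaults to
#'   [compute_effort()] on `stations`.
#'
#' @return An object of class `detection_history`: a list with elements `y`
#'   (0/1/`NA` matrix), `effort` (days matrix), `sites`, `survey_start`,
#'   `occasion_days`, `n_occasions`, `n_events` (independent events per
#'   station).
#' @export
build_detection_history <- function(records, stations, survey_start,
                                    n_occasions = 32, occasion_days = 7,
                                    species = NULL, effort = NULL) {
  survey_start <- as.Date(survey_start)
  if (!is.null(species)) {
    records <- records[records$species %in% species, , drop = FALSE]
  }
  sites <- stations$station_id
  orphans <- setdiff(unique(records$station_id), sites)
  if (length(orphans) > 0) {
    stop("records at station(s) absent from the station table: ",
         paste(orphans, collapse = ", "))
  }
  if (is.null(effort)) {
    effort <- compute_effort(stations, survey_start, n_occasions, occasion_days)
  }
  y <- matrix(0L, nrow = length(sites), ncol = n_occasions,
              dimnames = dimnames(effort))
  y[effort == 0] <- NA_integer_
  n_events <- stats::setNames(integer(length(sites)), sites)
  if (nrow(records) > 0) {
    day <- as.numeric(as.Date(records$timestamp, tz = attr(records$timestamp, "tzone") %||% "UTC"))
    occ <- floor((day - as.numeric(survey_start)) / occasion_days) + 1
    out_of_grid <- occ < 1 | occ > n_occasions
    if (any(out_of_grid)) {
      stop("record(s) dated outside the occasion grid at station(s): ",
           paste(unique(records$station_id[out_of_grid]), collapse = ", "))
    }
    for (r in seq_along(occ)) {
      sid <- records$station_id[r]
      j <- occ[r]
      if (effort[sid, j] == 0) {
        stop("record at station ", sid, " falls in occasion ", j,
             " which has zero effort; records and effort are inconsistent")
      }
      y[sid, j] <- 1L
      n_events[sid] <- n_events[sid] + 1L
    }
  }
  structure(list(y = y, effort = effort, sites = sites,
                 survey_start = survey_start, occasion_days = occasion_days,
                 n_occasions = n_occasions, n_events = n_events),
            class = "detection_history")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.detection_history <- function(x, ...) {
  nd <- sum(apply(x$y, 1, function(r) any(r == 1, na.rm = TRUE)))
  cat("Detection history:", length(x$sites), "sites x", x$n_occasions,
      "occasions (", x$occasion_days, "-day bins )\n", sep = " ")
  cat("  survey start:", format(x$survey_start), "\n")
  cat("  total effort:", sum(x$effort), "trap-days;",
      sum(x$y == 1, na.rm = TRUE), "detection cells at", nd, "sites\n")
  invisible(x)
}

#' Summarise a survey by management zone
#'
#' @param history A `detection_history`.
#' @param records The independence-filtered focal-species records used to
#'   build it (event counts are taken from these).
#' @param stations The `station_table`.
#'
#' @return Data frame with one row per zone: `zone`, `n_stations`,
#'   `n_detected` (stations with at least one detection), `n_events`
#'   (independent events) and `effort_days`.
#' @export
tabulate_by_zone <- function(history, records, stations) {
  zone <- stations$zone[match(history$sites, stations$station_id)]
  detected <- apply(history$y, 1, function(r) any(r == 1, na.rm = TRUE))
  ev <- table(factor(records$station_id, levels = history$sites))
  zl <- unique(zone)
  out <- data.frame(
    zone = zl,
    n_stations = vapply(zl, function(z) sum(zone == z), integer(1)),
    n_detected = vapply(zl, function(z) sum(detected[zone == z]), integer(1)),
    n_events = vapply(zl, function(z) sum(ev[zone == z]), numeric(1)),
    effort_days = vapply(zl, function(z) sum(history$effort[zone == z, ]),
                         numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a detection history as CSV
#'
#' The serialization stores the 0/1/`NA` matrix with `"NA"` for missing
#' cells; effort is written alongside as `<path>` with suffix
#' `"_effort.csv"` if `effort = TRUE`.
#'
#' @param history A `detection_history`.
#' @param path Output CSV path.
#' @param effort Also write the effort matrix next to it?
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path, effort = TRUE) {
  utils::write.csv(history$y, path, na = "NA", row.names = TRUE)
  if (effort) {
    utils::write.csv(history$effort,
                     sub("\\.csv$", "_effort.csv", path), row.names = TRUE)
  }
  invisible(path)
}
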