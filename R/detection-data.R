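#' Convert clock time to an angle on the diel circle
#'
#' Maps time of day to radians on `[0, 2*pi)`, so that midnight is 0,
#' 06:00 is `pi/2`, noon is `pi` and 18:00 is `3*pi/2`. Circular-statistics
#' routines ([vonmises_kde()], [delta1()]) operate on these angles.
#'
#' @param x Time of day. One of: a character vector `"HH:MM"` or `"HH:MM:SS"`,
#'   a `POSIXct`/`POSIXlt` vector (only the time of day is used, in its own
#'   timezone), or a numeric vector of decimal hours in `[0, 24)`.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @examples
#' time_to_radians(c("00:00", "06:00", "18:00"))
#' time_to_radians(12)  # pi
#' @export
time_to_radians <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  } else if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    parts <- strsplit(x, ":", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 2L || length(p) > 3L, logical(1))
    if (any(bad)) {
      stop("unparseable clock time(s): ", paste(x[bad], collapse = ", "))
    }
    secs <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] * 3600 + p[2] * 60 + if (length(p) == 3L) p[3] else 0
    }, numeric(1))
  } else if (is.numeric(x)) {
    secs <- x * 3600
  } else {
    stop("unsupported time representation: ", class(x)[1])
  }
  if (anyNA(secs) || any(secs < 0 | secs >= 86400)) {
    stop("clock times must lie within a 24 h day")
  }
  2 * pi * secs / 86400
}

#' Pool daily camera-trap records into detection occasions
#'
#' Builds one species' detection matrix (sites x occasions) from time-stamped
#' capture records and per-station deployment windows. Consecutive trap-days
#' are pooled into occasions of `occasion_days` days; an entry is 1 if the
#' species was photographed at least once in the window, 0 if the station was
#' active but recorded no capture, and `NA` if the station had no active day
#' in the window (the '-' of a detection history). Trailing partial windows
#' with at least one active day are kept as valid occasions.
#'
#' @param records Data frame with columns `station_id`, `species`, `datetime`
#'   (`POSIXct`, `Date`, or ISO 8601 character).
#' @param deployments Data frame with columns `station_id`, `start_date`,
#'   `end_date` (`Date` or parseable character), inclusive.
#' @param species Species code to extract.
#' @param occasion_days Days pooled per occasion (default 6).
#' @param vocabulary Valid species codes; defaults to the codes present in
#'   `records`. An unknown `species` is an error.
#' @param anchor `"deployment"` (default) anchors occasion windows at each
#'   station's own first active day; `"calendar"` anchors every station to the
#'   earliest deployment start in `deployments`, so occasion columns line up
#'   in calendar time across stations.
#' @return Integer matrix with one row per station (rownames = station ids),
#'   entries in `{1, 0, NA}`.
#' @examples
#' dep <- data.frame(station_id = "s1", start_date = "2018-01-01",
#'                   end_date = "2018-01-12")
#' rec <- data.frame(station_id = "s1", species = "snow_leopard",
#'                   datetime = "2018-01-03 10:00:00")
#' pool_occasions(rec, dep, "snow_leopard")  # [1, 0]
#' @export
pool_occasions <- function(records, deployments, species, occasion_days = 6,
                           vocabulary = NULL,
                           anchor = c("deployment", "calendar")) {
  anchor <- match.arg(anchor)
  if (occasion_days < 1) stop("occasion_days must be >= 1")
  need <- c("station_id", "start_date", "end_date")
  if (!all(need %in% names(deployments))) {
    stop("deployments must have columns: ", paste(need, collapse = ", "))
  }
  need_r <- c("station_id", "species", "datetime")
  if (!all(need_r %in% names(records))) {
    stop("records must have columns: ", paste(need_r, collapse = ", "))
  }
  if (is.null(vocabulary)) vocabulary <- unique(as.character(records$species))
  if (!species %in% vocabulary) {
    stop("unknown species code: ", species)
  }
  dep_start <- as.Date(deployments$start_date)
  dep_end <- as.Date(deployments$end_date)
  if (any(dep_start > dep_end)) stop("deployment start_date after end_date")
  stations <- as.character(deployments$station_id)
  if (anyDuplicated(stations)) stop("duplicated station_id in deployments")

  rec_station <- as.character(records$station_id)
  missing_station <- !rec_station %in% stations
  if (any(missing_station)) {
    stop("records reference stations absent from deployments: ",
         paste(unique(rec_station[missing_station]), collapse = ", "))
  }
  rec_date <- as.Date(records$datetime)
  idx <- match(rec_station, stations)
  outside <- rec_date < dep_start[idx] | rec_date > dep_end[idx]
  if (any(outside)) {
    bad <- which(outside)[1]
    stop(sprintf("record outside deployment window: station %s, %s",
                 rec_station[bad], format(rec_date[bad])))
  }

  origin <- if (anchor == "calendar") min(dep_start) else dep_start
  # day-of-study, 1-based, per record relative to its station's anchor
  first_day <- as.integer(dep_start - origin) + 1L
  last_day <- as.integer(dep_end - origin) + 1L
  n_occ <- max(ceiling(last_day / occasion_days))
  m <- matrix(NA_integer_, nrow = length(stations), ncol = n_occ,
              dimnames = list(stations, NULL))
  for (i in seq_along(stations)) {
    occs <- ceiling(seq(first_day[i], last_day[i]) / occasion_days)
    m[i, unique(occs)] <- 0L
  }
  sp_rec <- as.character(records$species) == species
  if (any(sp_rec)) {
    day <- as.integer(rec_date[sp_rec] -
                        (if (anchor == "calendar") origin else dep_start[idx[sp_rec]])) + 1L
    occ <- ceiling(day / occasion_days)
    m[cbind(idx[sp_rec], occ)] <- 1L
  }
  m
}

#' Collapse within-occasion capture counts to binary detections
#'
#' Multiple photo captures within one occasion count as a single detection:
#' any positive count maps to 1; zeros and missing occasions are preserved.
#'
#' @param m Matrix (or vector) of non-negative capture counts with `NA` for
#'   unsampled occasions.
#' @return Object of the same shape with entries in `{1, 0, NA}`.
#' @export
collapse_within_occasion <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("capture counts must be non-negative")
  out <- m
  out[!is.na(m) & m >= 1] <- 1L
  out
}

#' Align two detection matrices into a paired detection history
#'
#' A two-species occupancy fit needs both species' histories on the same
#' station-by-occasion frame with a shared missing pattern. Entries missing in
#' either matrix become missing in both (a station-occasion only counts as
#' surveyed for the pair if both species could have been recorded).
#'
#' @param matrix_a,matrix_b Detection matrices as returned by
#'   [pool_occasions()], rownames = station ids. Species A is the dominant
#'   species of the conditional model.
#' @param occasion_days Occasion length carried as metadata (default 6).
#' @return A `detection_pair`: list with elements `A`, `B` (aligned matrices)
#'   and `occasion_days`.
#' @export
align_pair <- function(matrix_a, matrix_b, occasion_days = 6) {
  matrix_a <- as.matrix(matrix_a)
  matrix_b <- as.matrix(matrix_b)
  sa <- rownames(matrix_a)
  sb <- rownames(matrix_b)
  if (!is.null(sa) || !is.null(sb)) {
    only_a <- setdiff(sa, sb)
    only_b <- setdiff(sb, sa)
    if (length(only_a) || length(only_b)) {
      stop("station sets differ; only in A: {",
           paste(only_a, collapse = ", "), "}; only in B: {",
           paste(only_b, collapse = ", "), "}")
    }
    matrix_b <- matrix_b[sa, , drop = FALSE]
  }
  if (!all(dim(matrix_a) == dim(matrix_b))) {
    stop("detection matrices must share the occasion structure")
  }
  miss <- is.na(matrix_a) | is.na(matrix_b)
  matrix_a[miss] <- NA_integer_
  matrix_b[miss] <- NA_integer_
  structure(list(A = matrix_a, B = matrix_b, occasion_days = occasion_days),
            class = "detection_pair")
}

#' @export
print.detection_pair <- function(x, ...) {
  cat(sprintf("detection_pair: %d stations x %d occasions (%d d/occasion), %.1f%% missing\n",
              nrow(x$A), ncol(x$A), x$occasion_days, 100 * mean(is.na(x$A))))
  cat(sprintf("  naive occupancy A: %.2f  B: %.2f\n",
              mean(rowSums(x$A, na.rm = TRUE) > 0),
              mean(rowSums(x$B, na.rm = TRUE) > 0)))
  invisible(x)
}

#' Read / write a detection matrix CSV
#'
#' One row per station; first column `station_id`, remaining columns occasions
#' with entries 1/0/NA (NA encodes the '-' of a printed detection history).
#'
#' @param path File path.
#' @return `read_detection_matrix()`: integer matrix with station rownames.
#' @export
read_detection_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"station_id" %in% names(df)) {
    stop("detection matrix CSV must have a station_id column")
  }
  m <- as.matrix(df[setdiff(names(df), "station_id")])
  bad <- !(m %in% c(0, 1) | is.na(m))
  if (any(bad)) stop("detection matrix entries must be 1, 0 or NA")
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$station_id)
  m
}

#' @rdname read_detection_matrix
#' @param m Detection matrix with station rownames.
#' @export
write_detection_matrix <- function(m, path) {
  df <- data.frame(station_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
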