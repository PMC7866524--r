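## Core data model: fixes, trajectories, flock datasets, paddock surveys,
## and the planar projection used for all metric analysis.

#' Project geographic coordinates to local planar metres
#'
#' Equirectangular projection about a reference point: east/north offsets
#' in metres on a sphere of radius 6,371,000 m. Over a paddock-sized window
#' (hundreds of metres) the projection error is far below the sub-metre
#' proximity thresholds used downstream.
#'
#' @param lat,lon numeric vectors of latitude/longitude in decimal degrees.
#' @param ref_lat,ref_lon scalar reference point (degrees); must be within
#'   1 degree of every projected point.
#' @return a `data.table` with columns `x` (metres east of the reference)
#'   and `y` (metres north).
#' @seealso [project_from_local()] for the exact inverse.
#' @export
#' @examples
#' project_to_local(-30.5, 151.3, -30.5, 151.3)  # (0, 0)
project_to_local <- function(lat, lon, ref_lat, ref_lon) {
  stopifnot(length(ref_lat) == 1L, length(ref_lon) == 1L)
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite coordinates")
  if (any(abs(lat) > 90) || any(abs(ref_lat) > 90))
    stop("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180) || any(abs(ref_lon) > 180))
    stop("longitude out of range [-180, 180]")
  if (any(abs(lat - ref_lat) > 1) || any(abs(lon - ref_lon) > 1))
    stop("points further than 1 degree from the reference")
  k <- EARTH_RADIUS * pi / 180
  data.table(
    x = (lon - ref_lon) * cos(ref_lat * pi / 180) * k,
    y = (lat - ref_lat) * k
  )
}

#' Inverse of the local equirectangular projection
#'
#' @param x,y local metres east/north of the reference.
#' @inheritParams project_to_local
#' @return a `data.table` with columns `lat`, `lon` in degrees.
#' @export
project_from_local <- function(x, y, ref_lat, ref_lon) {
  stopifnot(length(ref_lat) == 1L, length(ref_lon) == 1L)
  k <- EARTH_RADIUS * pi / 180
  data.table(
    lat = ref_lat + y / k,
    lon = ref_lon + x / (k * cos(ref_lat * pi / 180))
  )
}

#' Construct a flock dataset
#'
#' The central container for all analyses: one row per GNSS fix across all
#' animals, in local planar metres, with a quality flag per fix.
#'
#' @param fixes a `data.frame` with columns `animal_id`, `t` (seconds since
#'   the dataset epoch), `x`, `y` (metres) and optionally `quality`
#'   (one of [QUALITY_LEVELS]; defaults to `"RTK_FIXED"`).
#' @param paddock optional [paddock_survey()] describing the fence ring.
#' @param epoch optional `POSIXct` giving the absolute time of `t = 0`.
#' @return an object of class `flock_dataset`: a list with elements
#'   `fixes` (a keyed `data.table`), `paddock` and `epoch`.
#' @export
flock_dataset <- function(fixes, paddock = NULL, epoch = NULL) {
  fixes <- as.data.table(fixes)
  req <- c("animal_id", "t", "x", "y")
  miss <- setdiff(req, names(fixes))
  if (length(miss))
    stop("fixes missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!"quality" %in% names(fixes)) fixes[, quality := "RTK_FIXED"]
  bad <- setdiff(unique(fixes$quality), QUALITY_LEVELS)
  if (length(bad))
    stop("unknown quality flag(s): ", paste(bad, collapse = ", "))
  fixes[, animal_id := as.character(animal_id)]
  fixes[, t := as.numeric(t)]
  if (nrow(fixes) && any(fixes$t < 0)) stop("fix times must be >= 0")
  setkey(fixes, animal_id, t)
  if (anyDuplicated(fixes, by = c("animal_id", "t")))
    stop("duplicate (animal_id, t) fixes; times must be strictly increasing")
  if (!is.null(paddock) && !inherits(paddock, "paddock_survey"))
    stop("paddock must be a paddock_survey")
  structure(list(fixes = fixes, paddock = paddock, epoch = epoch),
            class = "flock_dataset")
}

#' @export
print.flock_dataset <- function(x, ...) {
  ids <- unique(x$fixes$animal_id)
  cat(sprintf("<flock_dataset> %d animals, %d fixes", length(ids),
              nrow(x$fixes)))
  if (nrow(x$fixes))
    cat(sprintf(", t in [%g, %g] s", min(x$fixes$t), max(x$fixes$t)))
  cat(if (is.null(x$paddock)) ", no survey\n" else ", with paddock survey\n")
  invisible(x)
}

#' Animal identifiers in a dataset
#' @param ds a [flock_dataset()].
#' @return character vector of unique ids, sorted.
#' @export
animal_ids <- function(ds) sort(unique(ds$fixes$animal_id))

#' Analysis view of a dataset: INVALID fixes excluded
#'
#' Every analysis operation in the package works on this view, so fixes
#' flagged `INVALID` at ingest are excluded once, consistently, and never
#' silently dropped from the stored data.
#'
#' @param ds a [flock_dataset()].
#' @return a `data.table` of fixes with `quality != "INVALID"`.
#' @export
valid_fixes <- function(ds) {
  stopifnot(inherits(ds, "flock_dataset"))
  ds$fixes[quality != "INVALID"]
}

#' Construct a paddock survey
#'
#' An ordered ring of surveyed corner positions in local metres. Consecutive
#' corners (closing back to the first) define the fence segments.
#'
#' @param corners a `data.frame` with columns `label`, `x`, `y`; at least
#'   3 rows; the ring must be simple (non-self-intersecting).
#' @return an object of class `paddock_survey`.
#' @export
paddock_survey <- function(corners) {
  corners <- as.data.table(corners)
  if (!all(c("label", "x", "y") %in% names(corners)))
    stop("corners need columns label, x, y")
  if (nrow(corners) < 3L) stop("a survey needs at least 3 corners")
  corners[, label := as.character(label)]
  n <- nrow(corners)
  nxt <- c(2:n, 1L)
  if (any(corners$x == corners$x[nxt] & corners$y == corners$y[nxt]))
    stop("duplicate consecutive corners")
  if (.ring_self_intersects(corners$x, corners$y))
    stop("survey ring is self-intersecting")
  structure(list(corners = corners[]), class = "paddock_survey")
}

#' @export
print.paddock_survey <- function(x, ...) {
  cat(sprintf("<paddock_survey> %d corners: %s\n", nrow(x$corners),
              paste(x$corners$label, collapse = " -> ")))
  invisible(x)
}

## proper segment intersection between non-adjacent ring edges
.ring_self_intersects <- function(x, y) {
  n <- length(x)
  nxt <- c(2:n, 1L)
  seg <- cbind(x, y, x[nxt], y[nxt])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read trajectories from a delimited file
#'
#' Accepts the package's CSV dialect: header row, one fix per line, columns
#' `animal_id`, a time column (`t` in seconds, or `timestamp` parseable as
#' ISO-8601 UTC), positions either already local (`x`, `y` in metres) or
#' geographic (`lat`, `lon` in degrees, projected about `ref` or the data
#' centroid), and an optional `quality` column. Rows whose timestamp cannot
#' be parsed are dropped with a warning reporting the count. `INVALID`
#' fixes are retained (see [valid_fixes()]).
#'
#' @param path file to read.
#' @param ref optional `c(lat, lon)` reference for the projection; defaults
#'   to the centroid of the data.
#' @param survey optional [paddock_survey()] to attach.
#' @return a [flock_dataset()], fixes sorted by animal and time.
#' @export
read_trajectories <- function(path, ref = NULL, survey = NULL) {
  dt <- fread(path, colClasses = list(character = "animal_id"))
  if (!"animal_id" %in% names(dt)) stop("missing mandatory column animal_id")
  epoch <- NULL
  if ("t" %in% names(dt)) {
    dt[, t := suppressWarnings(as.numeric(t))]
  } else if ("timestamp" %in% names(dt)) {
    ts <- dt$timestamp
    if (is.numeric(ts)) {
      dt[, t := as.numeric(ts) - min(ts, na.rm = TRUE)]
    } else {
      ts <- as.character(ts)
      parsed <- as.POSIXct(strptime(ts, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
      alt <- as.POSIXct(strptime(ts, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
      parsed[is.na(parsed)] <- alt[is.na(parsed)]
      epoch <- min(parsed, na.rm = TRUE)
      dt[, t := as.numeric(difftime(parsed, epoch, units = "secs"))]
    }
    dt[, timestamp := NULL]
  } else stop("missing mandatory time column (t or timestamp)")
  n_bad <- sum(is.na(dt$t))
  if (n_bad) {
    warning(sprintf("%d row(s) with unparseable timestamp dropped", n_bad))
    dt <- dt[!is.na(t)]
  }
  if (all(c("x", "y") %in% names(dt))) {
    # already local
  } else if (all(c("lat", "lon") %in% names(dt))) {
    if (is.null(ref)) ref <- c(mean(dt$lat), mean(dt$lon))
    xy <- project_to_local(dt$lat, dt$lon, ref[1], ref[2])
    dt[, `:=`(x = xy$x, y = xy$y, lat = NULL, lon = NULL)]
  } else stop("missing mandatory position columns (x,y or lat,lon)")
  keep <- intersect(c("animal_id", "t", "x", "y", "quality"), names(dt))
  flock_dataset(dt[, keep, with = FALSE], paddock = survey, epoch = epoch)
}

#' Write trajectories to the package CSV dialect
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_trajectories(write_trajectories(ds))` reproduces the dataset
#' exactly.
#'
#' @param ds a [flock_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ds, path) {
  stopifnot(inherits(ds, "flock_dataset"))
  out <- copy(ds$fixes)
  for (cl in c("t", "x", "y"))
    set(out, j = cl, value = sprintf("%.17g", out[[cl]]))
  fwrite(out[, .(animal_id, t, x, y, quality)], path)
  invisible(path)
}

#' Read a paddock survey from CSV
#'
#' Columns `label` plus either `x`, `y` (metres) or `lat`, `lon` (degrees,
#' projected about `ref` or the corner centroid).
#'
#' @inheritParams read_trajectories
#' @return a [paddock_survey()].
#' @export
read_survey <- function(path, ref = NULL) {
  dt <- fread(path)
  if (!"label" %in% names(dt)) stop("missing mandatory column label")
  if (!all(c("x", "y") %in% names(dt))) {
    if (!all(c("lat", "lon") %in% names(dt)))
      stop("missing position columns (x,y or lat,lon)")
    if (is.null(ref)) ref <- c(mean(dt$lat), mean(dt$lon))
    xy <- project_to_local(dt$lat, dt$lon, ref[1], ref[2])
    dt[, `:=`(x = xy$x, y = xy$y)]
  }
  paddock_survey(dt[, .(label, x, y)])
}

#' Write a paddock survey to CSV
#' @param survey a [paddock_survey()].
#' @param path output file.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "paddock_survey"))
  out <- copy(survey$corners)
  for (cl in c("x", "y"))
    set(out, j = cl, value = sprintf("%.17g", out[[cl]]))
  fwrite(out, path)
  invisible(path)
}
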