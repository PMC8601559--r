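#' Read a checklist survey table
#'
#' A simple CSV schema emulating stationary complete bird checklists:
#' columns `checklist_id, site_id, city, x, y, date, protocol, complete,
#' detected`.  `date` is an ISO date; `complete` and `detected` are 0/1 (or
#' logical); `protocol` is free text (`"stationary"`, `"traveling"`, ...).
#' Non-reporting of the focal species on a complete checklist is treated as
#' a non-detection.
#'
#' @param path CSV file path.
#' @return data frame with parsed `date` and logical `complete`, `detected`.
#' @export
read_checklists <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_checklists(tbl)
}

validate_checklists <- function(tbl) {
  need <- c("checklist_id", "site_id", "city", "x", "y", "date",
            "protocol", "complete", "detected")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("checklist table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tbl$checklist_id)) stop("duplicate checklist_id values")
  tbl$date <- as.Date(tbl$date)
  if (anyNA(tbl$date)) stop("unparseable dates in checklist table")
  tbl$complete <- as.logical(as.integer(as.logical(tbl$complete)))
  tbl$detected <- as.integer(as.logical(tbl$detected))
  tbl
}

#' Filter checklists to the analysis protocol and season
#'
#' Retains only stationary-protocol, complete checklists whose date falls in
#' `[start_date, end_date]` (inclusive); the defaults give the April-through-
#' September breeding season.  Idempotent; an empty result only warns.
#'
#' @param tbl checklist table (see [read_checklists()]).
#' @param start_date,end_date season bounds (ISO strings or Dates).
#' @param protocol protocol value to keep (case-insensitive).
#' @return the filtered table.
#' @export
filter_checklists <- function(tbl, start_date = "2018-04-01",
                              end_date = "2018-09-30",
                              protocol = "stationary") {
  tbl <- validate_checklists(tbl)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date)
    stop("invalid season bounds")
  keep <- tolower(trimws(tbl$protocol)) == tolower(protocol) &
    tbl$complete & tbl$date >= start_date & tbl$date <= end_date
  out <- tbl[keep, , drop = FALSE]
  if (!nrow(out)) warning("no checklists remain after filtering")
  rownames(out) <- NULL
  out
}

#' Scale survey dates to 10-day units
#'
#' Days elapsed since the season start divided by 10, so one unit is ten
#' calendar days; April 1 maps to 0 and September 30 to 18.2.  Scaling eases
#' coefficient interpretation and helps optimisation.
#'
#' @param date Date (or ISO string) vector.
#' @param season_start season start date.
#' @return numeric scaled dates.
#' @export
scale_date <- function(date, season_start = "2018-04-01") {
  date <- as.Date(date); season_start <- as.Date(season_start)
  if (any(date < season_start)) stop("date before season start")
  as.numeric(date - season_start) / 10
}

#' Occupancy-ready data
#'
#' Container pairing a site table (one row per survey location with its
#' city, coordinates and site-level covariates such as the gradient values
#' `HS` and `BG`) with a ragged visit table (one row per checklist: 0/1
#' detection and scaled date).  Every site has at least one visit; visits
#' are ordered by date within site.
#'
#' @param sites data frame with at least `site_id, city, x, y`.
#' @param visits data frame with at least `site_id, date, date_s, y`.
#' @return object of class `occu_data`.
#' @export
occu_data <- function(sites, visits) {
  stopifnot(all(c("site_id", "city", "x", "y") %in% names(sites)),
            all(c("site_id", "date_s", "y") %in% names(visits)))
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in site table")
  if (!all(visits$site_id %in% sites$site_id))
    stop("visit rows reference unknown sites")
  J <- table(factor(visits$site_id, levels = sites$site_id))
  if (any(J < 1L)) stop("every site needs at least one visit")
  if (!all(visits$y %in% c(0L, 1L))) stop("detections must be 0/1")
  if (!all(is.finite(visits$date_s))) stop("non-finite scaled dates")
  sites$city <- factor(as.character(sites$city))
  ord <- order(match(visits$site_id, sites$site_id), visits$date_s)
  visits <- visits[ord, , drop = FALSE]
  rownames(sites) <- rownames(visits) <- NULL
  structure(list(sites = sites, visits = visits), class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  J <- table(factor(x$visits$site_id, levels = x$sites$site_id))
  cat(sprintf("<occu_data: %d sites in %d city(ies), %d visits (J: %d-%d, mean %.2f)>\n",
              nrow(x$sites), nlevels(x$sites$city), nrow(x$visits),
              min(J), max(J), mean(J)))
  cat(sprintf("  naive occupancy: %.3f\n", naive_occupancy(x)))
  invisible(x)
}

#' Share of sites with at least one detection
#'
#' @param data an [occu_data].
#' @param by_city if `TRUE`, return a per-city vector as well.
#' @return naive occupancy proportion (or list with `overall` and `by_city`).
#' @export
naive_occupancy <- function(data, by_city = FALSE) {
  stopifnot(inherits(data, "occu_data"))
  det <- tapply(data$visits$y,
                factor(data$visits$site_id, levels = data$sites$site_id),
                max)
  if (!by_city) return(mean(det))
  list(overall = mean(det),
       by_city = tapply(det, data$sites$city, mean))
}

#' Build detection histories from filtered checklists
#'
#' One site per unique `site_id`; each checklist becomes one visit with the
#' `detected` flag as the 0/1 outcome and the date scaled via [scale_date()].
#' Site coordinates and city are taken from the first checklist of the site
#' (they are fixed properties of a survey location).
#'
#' @param tbl a filtered checklist table.
#' @param season_start season start used for date scaling.
#' @return an [occu_data].
#' @export
build_histories <- function(tbl, season_start = "2018-04-01") {
  tbl <- validate_checklists(tbl)
  if (!nrow(tbl)) stop("empty checklist table")
  first <- tbl[!duplicated(tbl$site_id), c("site_id", "city", "x", "y")]
  visits <- data.frame(site_id = tbl$site_id, date = tbl$date,
                       date_s = scale_date(tbl$date, season_start),
                       y = tbl$detected)
  occu_data(first, visits)
}

#' Randomly thin sites per city
#'
#' Cities with more than `max_per_city` sites are subsampled uniformly
#' without replacement to exactly `max_per_city` (improving balance across
#' cities); smaller cities are untouched.  Deterministic given `seed`.
#'
#' @param data an [occu_data].
#' @param max_per_city maximum retained sites per city (default 250).
#' @param seed integer seed.
#' @return thinned [occu_data].
#' @export
thin_sites <- function(data, max_per_city = 250L, seed = 1L) {
  stopifnot(inherits(data, "occu_data"), max_per_city >= 1L)
  keep <- with_seed(seed, {
    unlist(lapply(split(data$sites$site_id, data$sites$city), function(ids) {
      if (length(ids) <= max_per_city) ids
      else sample(ids, max_per_city)
    }), use.names = FALSE)
  })
  sites <- data$sites[data$sites$site_id %in% keep, , drop = FALSE]
  visits <- data$visits[data$visits$site_id %in% keep, , drop = FALSE]
  sites$city <- factor(as.character(sites$city))
  occu_data(sites, visits)
}

#' Attach raster covariates to sites
#'
#' Joins one covariate column per named surface to the site table via
#' nearest-pixel extraction ([extract_at_points()]).  Sites falling outside
#' a surface extent or on nodata are dropped with a warning.
#'
#' @param data an [occu_data].
#' @param surfaces named list of continuous [land_raster]s; typical names
#'   are `HS` (hard-to-soft) and `BG` (brown-to-green).
#' @return [occu_data] with the new site columns.
#' @export
attach_covariates <- function(data, surfaces) {
  stopifnot(inherits(data, "occu_data"), length(surfaces) > 0,
            !is.null(names(surfaces)), all(nzchar(names(surfaces))))
  pts <- data.frame(id = data$sites$site_id, x = data$sites$x, y = data$sites$y)
  ok <- rep(TRUE, nrow(pts))
  for (nm in names(surfaces)) {
    ex <- suppressWarnings(extract_at_points(surfaces[[nm]], pts))
    data$sites[[nm]] <- ex$value[match(data$sites$site_id, ex$id)]
    ok <- ok & !is.na(data$sites[[nm]])
  }
  if (any(!ok)) {
    warning(sum(!ok), " site(s) outside surface extent/nodata dropped")
    keep <- data$sites$site_id[ok]
    sites <- data$sites[ok, , drop = FALSE]
    sites$city <- factor(as.character(sites$city))
    data <- occu_data(sites,
                      data$visits[data$visits$site_id %in% keep, , drop = FALSE])
  }
  data
}

#' Write / read occupancy data as plain files
#'
#' Two CSVs (`sites.csv`, `visits.csv`) plus a small JSON manifest.
#'
#' @param data an [occu_data].
#' @param dir directory (created if missing).
#' @return `write_occu_data()` invisibly returns `dir`; `read_occu_data()`
#'   the restored [occu_data].
#' @export
write_occu_data <- function(data, dir) {
  stopifnot(inherits(data, "occu_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(data$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_sites = nrow(data$sites),
                            n_visits = nrow(data$visits),
                            cities = levels(data$sites$city),
                            covariates = setdiff(names(data$sites),
                                                 c("site_id", "city", "x", "y"))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_occu_data
#' @export
read_occu_data <- function(dir) {
  sites <- utils::read.csv(file.path(dir, "sites.csv"))
  visits <- utils::read.csv(file.path(dir, "visits.csv"))
  if ("date" %in% names(visits)) visits$date <- as.Date(visits$date)
  occu_data(sites, visits)
}
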