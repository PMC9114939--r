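# Photo-identification catalogue: fixed-schema readers/writers, quality
# filtering, association pairs, and delineation of groups and social units.

#' Read and write photo-identification tables
#'
#' `photos.csv` has exact headers
#' `individual_id,date,time,lat,lon,quality` (an optional `island` column is
#' preserved). `date` is ISO-8601, `time` is seconds since midnight (may be
#' empty), `quality` is the fluke photo quality score Q on the 1--5 scale.
#' Writers emit dates in ISO-8601 and coordinates to 6 decimals, so a
#' write/read round trip reproduces the written table exactly.
#'
#' @param path file path.
#' @return `read_photos()` returns a data.frame with columns `individual_id`
#'   (character), `date` (`Date`), `time` (numeric seconds or `NA`), `lat`,
#'   `lon` (numeric degrees), `quality` (integer) and, if present, `island`.
#' @export
read_photos <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("individual_id", "date", "time", "lat", "lon", "quality"),
                 "photos table")
  df$individual_id <- as.character(df$individual_id)
  df$date <- as.Date(df$date)
  df$time <- suppressWarnings(as.numeric(df$time))
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  df$quality <- as.integer(df$quality)
  validate_photos(df)
  df
}

#' @rdname read_photos
#' @param photos a photo-identification data.frame (see `read_photos()`).
#' @export
write_photos <- function(photos, path) {
  validate_photos(photos)
  out <- photos
  out$date <- format(as.Date(photos$date), "%Y-%m-%d")
  out$lat <- sprintf("%.6f", photos$lat)
  out$lon <- sprintf("%.6f", photos$lon)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_photos <- function(photos) {
  bad_q <- which(is.na(photos$quality) | photos$quality < 1L | photos$quality > 5L)
  if (length(bad_q) > 0L) {
    stop(sprintf("photo quality outside 1-5 in row(s): %s",
                 paste(utils::head(bad_q, 10L), collapse = ", ")), call. = FALSE)
  }
  bad_c <- which(abs(photos$lat) > 90 | abs(photos$lon) > 180)
  if (length(bad_c) > 0L) {
    stop(sprintf("coordinates out of range in row(s): %s",
                 paste(utils::head(bad_c, 10L), collapse = ", ")), call. = FALSE)
  }
  invisible(photos)
}

#' Read and write vessel GPS tracks
#'
#' `gps.csv` has exact headers `timestamp,lat,lon,track_id`; timestamps are
#' UTC (`YYYY-MM-DD HH:MM:SS`) and must be strictly increasing within each
#' track. Fixes are nominally at 5-min resolution.
#'
#' @param path file path.
#' @return a data.frame with `timestamp` (`POSIXct`, UTC), `lat`, `lon`
#'   (degrees), `track_id` (character).
#' @export
read_gps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("timestamp", "lat", "lon", "track_id"), "gps table")
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  df$track_id <- as.character(df$track_id)
  validate_gps(df)
  df
}

#' @rdname read_gps
#' @param gps a GPS track data.frame (see `read_gps()`).
#' @export
write_gps <- function(gps, path) {
  validate_gps(gps)
  out <- gps
  out$timestamp <- format(gps$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out$lat <- sprintf("%.6f", gps$lat)
  out$lon <- sprintf("%.6f", gps$lon)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_gps <- function(gps) {
  for (id in unique(gps$track_id)) {
    tt <- gps$timestamp[gps$track_id == id]
    if (any(diff(as.numeric(tt)) <= 0)) {
      stop(sprintf("track '%s' has non-increasing timestamps", id), call. = FALSE)
    }
  }
  invisible(gps)
}

#' Filter photo-identification records by quality score
#'
#' Keeps records whose fluke photo quality Q is at least `q_min` (the standard
#' analysis threshold is Q >= 3). Order is preserved and the filter is
#' idempotent; raising `q_min` always yields a subset.
#'
#' @param photos photo-identification data.frame.
#' @param q_min minimum quality, an integer in 1..5.
#' @return the subset of `photos` with `quality >= q_min`.
#' @export
filter_photo_quality <- function(photos, q_min = 3L) {
  stopifnot(length(q_min) == 1L, q_min >= 1L, q_min <= 5L)
  validate_photos(photos)
  photos[photos$quality >= q_min, , drop = FALSE]
}

#' Photo-identification association pairs
#'
#' Two individuals are associated on a day when they were photographed within
#' `window_hours` of each other (the gap is the minimum over all pairs of
#' their photo times that day). When either individual has no usable time on
#' that day, same-date co-occurrence suffices and the pair is flagged
#' `timeless`; a warning reports how many pairs used the fallback.
#'
#' @param photos photo-identification data.frame.
#' @param window_hours association window in hours (default 2).
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`), `date`,
#'   `gap_hours` (NA when timeless) and `timeless` (logical).
#' @export
associations <- function(photos, window_hours = 2) {
  stopifnot(window_hours > 0)
  assert_columns(photos, c("individual_id", "date"), "photos table")
  has_time <- "time" %in% names(photos)
  res <- list()
  n_timeless <- 0L
  for (d in as.character(unique(photos$date))) {
    day <- photos[as.character(photos$date) == d, , drop = FALSE]
    ids <- sort(unique(day$individual_id))
    if (length(ids) < 2L) next
    times <- lapply(ids, function(i) {
      if (!has_time) return(numeric(0))
      t <- day$time[day$individual_id == i]
      t[!is.na(t)]
    })
    for (a in seq_len(length(ids) - 1L)) {
      for (b in seq.int(a + 1L, length(ids))) {
        ta <- times[[a]]; tb <- times[[b]]
        if (length(ta) == 0L || length(tb) == 0L) {
          n_timeless <- n_timeless + 1L
          res[[length(res) + 1L]] <- data.frame(
            id_a = ids[a], id_b = ids[b], date = as.Date(d),
            gap_hours = NA_real_, timeless = TRUE)
        } else {
          gap <- min(abs(outer(ta, tb, "-"))) / 3600
          if (gap <= window_hours) {
            res[[length(res) + 1L]] <- data.frame(
              id_a = ids[a], id_b = ids[b], date = as.Date(d),
              gap_hours = gap, timeless = FALSE)
          }
        }
      }
    }
  }
  if (n_timeless > 0L) {
    warning(sprintf("%d association pair(s) fell back to same-date co-occurrence (missing times)",
                    n_timeless), call. = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      date = as.Date(character(0)),
                      gap_hours = numeric(0), timeless = logical(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Delineate groups from association records
#'
#' Groups are connected components of the association graph: per-day
#' components, merged across days whenever they share a member (equivalently,
#' components of the pooled graph). Individuals never associated form
#' singleton groups. Group ids are assigned deterministically by each group's
#' lexicographically smallest member.
#'
#' @param assocs association data.frame from [associations()].
#' @param photos photo-identification data.frame (supplies the full roster of
#'   identified individuals and their observation dates).
#' @return data.frame with columns `group_id`, `individual_id`; attribute
#'   `observation_dates` holds a data.frame of `(group_id, date)`.
#' @export
delineate_groups <- function(assocs, photos) {
  ids <- sort(unique(photos$individual_id))
  memb <- component_membership(assocs, ids)
  first_member <- vapply(split(names(memb), memb), min, character(1))
  ord <- order(first_member)
  relabel <- stats::setNames(sprintf("G%03d", seq_along(ord)), names(first_member)[ord])
  out <- data.frame(group_id = unname(relabel[as.character(memb)]),
                    individual_id = names(memb), row.names = NULL)
  out <- out[order(out$group_id, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  obs <- merge(out, photos[, c("individual_id", "date")], by = "individual_id")
  obs <- unique(obs[, c("group_id", "date")])
  obs <- obs[order(obs$group_id, obs$date), , drop = FALSE]
  rownames(obs) <- NULL
  attr(out, "observation_dates") <- obs
  out
}

# connected components over association edges; vertices = ids
component_membership <- function(assocs, ids) {
  edges <- unique(assocs[, c("id_a", "id_b"), drop = FALSE])
  edges <- edges[edges$id_a %in% ids & edges$id_b %in% ids, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  comp[ids]
}

#' Delineate social units from multi-year associations
#'
#' A social unit is a set of individuals linked by pairwise associations
#' documented in at least two different calendar years: the association graph
#' is restricted to such qualifying pairs and its connected components (of
#' two or more members) are the units. Groups not meeting the criterion
#' remain groups only.
#'
#' @param assocs association data.frame from [associations()].
#' @return data.frame with columns `unit_id`, `individual_id`; attribute
#'   `qualifying_pairs` lists each pair and its number of distinct years.
#' @export
delineate_units <- function(assocs) {
  empty <- data.frame(unit_id = character(0), individual_id = character(0))
  if (nrow(assocs) == 0L) {
    attr(empty, "qualifying_pairs") <- data.frame(
      id_a = character(0), id_b = character(0), n_years = integer(0))
    return(empty)
  }
  key <- paste(assocs$id_a, assocs$id_b, sep = "\r")
  yrs <- tapply(year_of(assocs$date), key, function(y) length(unique(y)))
  qual <- names(yrs)[yrs >= 2L]
  qp <- do.call(rbind, strsplit(qual, "\r", fixed = TRUE))
  qpairs <- if (length(qual) > 0L) {
    data.frame(id_a = qp[, 1], id_b = qp[, 2], n_years = as.integer(yrs[qual]))
  } else {
    data.frame(id_a = character(0), id_b = character(0), n_years = integer(0))
  }
  if (nrow(qpairs) == 0L) {
    attr(empty, "qualifying_pairs") <- qpairs
    return(empty)
  }
  ids <- sort(unique(c(qpairs$id_a, qpairs$id_b)))
  memb <- component_membership(qpairs, ids)
  first_member <- vapply(split(names(memb), memb), min, character(1))
  ord <- order(first_member)
  relabel <- stats::setNames(sprintf("U%02d", seq_along(ord)), names(first_member)[ord])
  out <- data.frame(unit_id = unname(relabel[as.character(memb)]),
                    individual_id = names(memb), row.names = NULL)
  out <- out[order(out$unit_id, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qualifying_pairs") <- qpairs
  out
}

#' Island gazetteer and nearest-island labelling
#'
#' `lesser_antilles_gazetteer()` returns approximate island centroids along
#' the study arc (St. Kitts & Nevis to Grenada). `assign_island()` labels each
#' record with the nearest island centroid by great-circle distance; the
#' label feeds the same-island resighting statistic.
#'
#' @return data.frame with columns `island`, `lat`, `lon`.
#' @export
lesser_antilles_gazetteer <- function() {
  data.frame(
    island = c("StKitts", "Antigua", "Guadeloupe", "Dominica", "Martinique",
               "StLucia", "StVincent", "Grenada"),
    lat = c(17.30, 17.07, 16.25, 15.41, 14.64, 13.90, 13.25, 12.10),
    lon = c(-62.70, -61.80, -61.55, -61.37, -61.02, -60.97, -61.20, -61.67))
}

#' @rdname lesser_antilles_gazetteer
#' @param records data.frame with `lat` and `lon` columns.
#' @param gazetteer island centroid table.
#' @return `assign_island()`: `records` with an `island` column added.
#' @export
assign_island <- function(records, gazetteer = lesser_antilles_gazetteer()) {
  assert_columns(records, c("lat", "lon"), "records")
  dmat <- vapply(seq_len(nrow(gazetteer)), function(i) {
    great_circle_km(records$lat, records$lon, gazetteer$lat[i], gazetteer$lon[i])
  }, numeric(nrow(records)))
  dmat <- matrix(dmat, nrow = nrow(records))
  records$island <- gazetteer$island[max.col(-dmat, ties.method = "first")]
  records
}
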