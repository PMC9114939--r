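# Movement and distribution: great-circle distances, windowed vessel-track
# displacements, survey-effort fields, kernel density habitat grids, the
# same-island resighting statistic and the scale comparison table.

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

#' Windowed displacement along a vessel track
#'
#' Tiles each track into consecutive non-overlapping windows of
#' `window_hours` (1, 3 or 6 h in the standard analysis) and measures the
#' great-circle displacement between the first and last fix of each window.
#' The track is first truncated to `bounds` (e.g. the first and last whale
#' cluster sighting of the day, to drop purposeful transit legs). Windows
#' with fewer than `min_coverage` of the expected 5-min fixes are dropped, as
#' are windows implying speeds above `speed_guard_kmh` (GPS error guard);
#' both are counted in the `dropped` attribute.
#'
#' @param gps GPS data.frame (`timestamp`, `lat`, `lon`, `track_id`).
#' @param window_hours window length in hours.
#' @param bounds optional `POSIXct` length-2 vector truncating every track.
#' @param min_coverage minimum fraction of expected fixes per window.
#' @param speed_guard_kmh maximum plausible sustained speed.
#' @return data.frame `track_id`, `window_hours`, `start_time`,
#'   `displacement_km`; attribute `dropped` = c(low_coverage, speed_guard).
#' @export
window_displacement <- function(gps, window_hours, bounds = NULL,
                                min_coverage = 0.8, speed_guard_kmh = 12) {
  stopifnot(window_hours > 0)
  validate_gps(gps)
  if (!is.null(bounds)) {
    gps <- gps[gps$timestamp >= bounds[1] & gps$timestamp <= bounds[2], , drop = FALSE]
  }
  out <- list()
  dropped <- c(low_coverage = 0L, speed_guard = 0L)
  expected <- window_hours * 12  # 5-min fixes
  for (id in unique(gps$track_id)) {
    tr <- gps[gps$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (nrow(tr) < 2L) next
    hrs <- as.numeric(difftime(tr$timestamp, tr$timestamp[1], units = "hours"))
    win <- floor(hrs / window_hours)
    n_complete <- floor(max(hrs) / window_hours)  # only fully spanned windows
    for (w in seq_len(n_complete) - 1L) {
      idx <- which(win == w)
      if (length(idx) < min_coverage * expected) {
        dropped["low_coverage"] <- dropped["low_coverage"] + 1L
        next
      }
      i1 <- idx[1]; i2 <- idx[length(idx)]
      d <- great_circle_km(tr$lat[i1], tr$lon[i1], tr$lat[i2], tr$lon[i2])
      if (d > speed_guard_kmh * window_hours) {
        dropped["speed_guard"] <- dropped["speed_guard"] + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        track_id = id, window_hours = window_hours,
        start_time = tr$timestamp[i1], displacement_km = d)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(track_id = character(0), window_hours = numeric(0),
               start_time = as.POSIXct(character(0), tz = "UTC"),
               displacement_km = numeric(0))
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Survey-effort field on a lat/lon grid
#'
#' For every survey day with photo-identification effort, each grid cell the
#' vessel visited that day is incremented by one. The resulting weights feed
#' the effort-corrected movement likelihood.
#'
#' @param gps GPS data.frame.
#' @param id_dates `Date` vector of days with identification effort.
#' @param resolution_deg cell size in degrees (default 0.05).
#' @return object of class `effort_field`: data.frame `ix`, `iy` (cell
#'   indices), `lon`, `lat` (cell centers), `effort`; attribute
#'   `resolution_deg`.
#' @export
build_effort <- function(gps, id_dates, resolution_deg = 0.05) {
  stopifnot(resolution_deg > 0)
  day <- as.Date(format(gps$timestamp, "%Y-%m-%d", tz = "UTC"))
  gps <- gps[day %in% as.Date(id_dates), , drop = FALSE]
  day <- day[day %in% as.Date(id_dates)]
  ix <- floor(gps$lon / resolution_deg)
  iy <- floor(gps$lat / resolution_deg)
  visits <- unique(data.frame(day = day, ix = ix, iy = iy))
  tab <- stats::aggregate(list(effort = rep(1L, nrow(visits))),
                          by = list(ix = visits$ix, iy = visits$iy), FUN = sum)
  tab$lon <- (tab$ix + 0.5) * resolution_deg
  tab$lat <- (tab$iy + 0.5) * resolution_deg
  tab <- tab[order(tab$ix, tab$iy), c("ix", "iy", "lon", "lat", "effort")]
  rownames(tab) <- NULL
  structure(tab, class = c("effort_field", "data.frame"),
            resolution_deg = resolution_deg)
}

#' @rdname build_effort
#' @param lat_range,lon_range numeric length-2 extents of a uniform field.
#' @return `uniform_effort()`: an `effort_field` with weight 1 everywhere.
#' @export
uniform_effort <- function(lat_range, lon_range, resolution_deg = 0.05) {
  ix <- seq(floor(lon_range[1] / resolution_deg),
            floor(lon_range[2] / resolution_deg))
  iy <- seq(floor(lat_range[1] / resolution_deg),
            floor(lat_range[2] / resolution_deg))
  grid <- expand.grid(ix = ix, iy = iy, KEEP.OUT.ATTRS = FALSE)
  grid$lon <- (grid$ix + 0.5) * resolution_deg
  grid$lat <- (grid$iy + 0.5) * resolution_deg
  grid$effort <- 1
  grid <- grid[order(grid$ix, grid$iy), ]
  rownames(grid) <- NULL
  structure(grid, class = c("effort_field", "data.frame"),
            resolution_deg = resolution_deg)
}

#' Kernel density grid of encounter locations
#'
#' Isotropic Gaussian kernel density of fixes on a lat/lon grid, computed in
#' a local planar km frame. Densities are per km^2 and normalised so that
#' the grid integral (density times cell area) equals the number of fixes;
#' the grid is padded by `pad_bw` bandwidths so that mass is conserved to
#' well within 0.1%.
#'
#' @param fixes data.frame with `lat`, `lon`.
#' @param resolution_deg grid resolution in degrees (display default 0.001,
#'   about 100 m).
#' @param bandwidth_km kernel bandwidth; default is Silverman's rule on the
#'   planar coordinates.
#' @param origin projection origin `c(lat, lon)`; default the fix centroid.
#' @param pad_bw grid padding in bandwidths.
#' @return object of class `density_grid`: list with `lon`, `lat` (cell
#'   center vectors), `z` (matrix `length(lon)` x `length(lat)`, per km^2),
#'   `bandwidth_km`, `mass`, `n`.
#' @export
kernel_density <- function(fixes, resolution_deg = 0.001, bandwidth_km = NULL,
                           origin = NULL, pad_bw = 5) {
  if (nrow(fixes) == 0L) {
    warning("no fixes: returning empty density grid", call. = FALSE)
    return(structure(list(lon = numeric(0), lat = numeric(0),
                          z = matrix(numeric(0), 0, 0),
                          bandwidth_km = NA_real_, mass = 0, n = 0L),
                     class = "density_grid"))
  }
  origin <- origin %||% c(mean(fixes$lat), mean(fixes$lon))
  # locally rectangular frame (fixed meridian scale at the origin latitude):
  # the separable-kernel evaluation needs x to depend on longitude only
  coslat0 <- cos(origin[1] * pi / 180)
  xy <- cbind((fixes$lon - origin[2]) * coslat0 * KM_PER_DEG,
              (fixes$lat - origin[1]) * KM_PER_DEG)
  n <- nrow(xy)
  if (is.null(bandwidth_km)) {
    s <- if (n > 1L) sqrt((stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2) else 0
    bandwidth_km <- if (s > 0) s * n^(-1 / 6) else 1
  }
  stopifnot(bandwidth_km > 0)
  coslat <- cos(origin[1] * pi / 180)
  pad_lon <- pad_bw * bandwidth_km / (KM_PER_DEG * coslat)
  pad_lat <- pad_bw * bandwidth_km / KM_PER_DEG
  lon_g <- seq(min(fixes$lon) - pad_lon, max(fixes$lon) + pad_lon,
               by = resolution_deg)
  lat_g <- seq(min(fixes$lat) - pad_lat, max(fixes$lat) + pad_lat,
               by = resolution_deg)
  gx <- (lon_g - origin[2]) * coslat * KM_PER_DEG
  gy <- (lat_g - origin[1]) * KM_PER_DEG
  # separable Gaussian kernel: z = Kx %*% t(Ky) collapses the sum over fixes
  Kx <- exp(-outer(gx, xy[, 1], "-")^2 / (2 * bandwidth_km^2))
  Ky <- exp(-outer(gy, xy[, 2], "-")^2 / (2 * bandwidth_km^2))
  z <- (Kx %*% t(Ky)) / (2 * pi * bandwidth_km^2)
  cell_area <- (resolution_deg * KM_PER_DEG * coslat) * (resolution_deg * KM_PER_DEG)
  structure(list(lon = lon_g, lat = lat_g, z = z,
                 bandwidth_km = bandwidth_km,
                 mass = sum(z) * cell_area, n = n),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Kernel density grid: %d x %d cells, bandwidth %.2f km, %d fixes (grid mass %.3f)\n",
              length(x$lon), length(x$lat), x$bandwidth_km, x$n, x$mass))
  invisible(x)
}

#' @rdname kernel_density
#' @param clan character vector of clan labels, one per fix.
#' @return `kernel_density_by_clan()`: named list of `density_grid`s.
#' @export
kernel_density_by_clan <- function(fixes, clan, ...) {
  lapply(split(fixes, clan), kernel_density, ...)
}

#' Same-island resighting fraction
#'
#' Among individuals photo-identified in at least two distinct calendar
#' years, the fraction whose island labels (nearest island of each sighting)
#' form a singleton set, i.e. that were always resighted off the same island.
#' Reported per clan when a `clan_id` column is present, plus an overall row.
#'
#' @param sightings data.frame with `individual_id`, `date`, `island` and
#'   optionally `clan_id`.
#' @return data.frame `clan_id`, `n_same`, `n_resighted`, `fraction`
#'   (`NA` when no individual was resighted across years).
#' @export
same_island_fraction <- function(sightings) {
  assert_columns(sightings, c("individual_id", "date", "island"), "sightings")
  per_ind <- function(df) {
    spl <- split(df, df$individual_id)
    multi <- vapply(spl, function(s) length(unique(year_of(s$date))) >= 2L, logical(1))
    same <- vapply(spl, function(s) length(unique(s$island)) == 1L, logical(1))
    n_res <- sum(multi)
    c(n_same = sum(same & multi), n_resighted = n_res)
  }
  rows <- list()
  if ("clan_id" %in% names(sightings)) {
    for (cl in sort(unique(sightings$clan_id))) {
      v <- per_ind(sightings[sightings$clan_id == cl, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        clan_id = cl, n_same = v["n_same"], n_resighted = v["n_resighted"])
    }
  }
  v <- per_ind(sightings)
  rows[[length(rows) + 1L]] <- data.frame(
    clan_id = "all", n_same = v["n_same"], n_resighted = v["n_resighted"])
  out <- do.call(rbind, rows)
  out$fraction <- ifelse(out$n_resighted > 0, out$n_same / out$n_resighted, NA_real_)
  rownames(out) <- NULL
  out
}

#' Reference movement and social-scale constants
#'
#' Published summary constants for Eastern Tropical Pacific (ETP) sperm
#' whales (`etp_reference()`) and the corresponding Eastern Caribbean
#' summaries (`ec_reference()`), used only for scale comparisons and plots.
#'
#' @return data.frame `quantity`, `group`, `value`, `unit`.
#' @export
etp_reference <- function() {
  path <- system.file("extdata", "etp_reference.csv", package = "codaclan",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname etp_reference
#' @export
ec_reference <- function() {
  path <- system.file("extdata", "ec_reference.csv", package = "codaclan",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare movement/social scales against a reference population
#'
#' Joins two `quantity`-keyed summary tables (values averaged over groups
#' within each quantity), computes the reference-to-focal ratio per quantity
#' and flags order-of-magnitude differences (ratio >= 10).
#'
#' @param focal data.frame with `quantity` and `value` (e.g. EC estimates).
#' @param reference reference table, default [etp_reference()].
#' @return data.frame `quantity`, `focal`, `reference`, `ratio`, `flagged`.
#' @export
compare_scales <- function(focal, reference = etp_reference()) {
  agg <- function(df) stats::aggregate(list(value = df$value),
                                       by = list(quantity = df$quantity),
                                       FUN = mean)
  f <- agg(focal); r <- agg(reference)
  m <- merge(f, r, by = "quantity", suffixes = c("_focal", "_ref"))
  out <- data.frame(quantity = m$quantity, focal = m$value_focal,
                    reference = m$value_ref,
                    ratio = m$value_ref / m$value_focal)
  out$flagged <- out$ratio >= 10
  out[order(out$quantity), ]
}

#' @rdname write_movement_outputs
#' @param displacements data.frame from [window_displacement()].
#' @export
write_displacements <- function(displacements, path) {
  out <- displacements
  out$start_time <- format(out$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write movement outputs
#'
#' `displacements.csv` and `rms.csv`
#' (`lag_lo,lag_hi,n_pairs,rms_km,jackknife_se_km`) writers.
#'
#' @param rms data.frame from [rms_ml()] / [jackknife_se()].
#' @param path file path.
#' @name write_movement_outputs
#' @export
write_rms <- function(rms, path) {
  cols <- intersect(c("lag_lo", "lag_hi", "lag_mean_days", "n_pairs",
                      "n_individuals", "rms_km", "jackknife_se_km"), names(rms))
  utils::write.csv(rms[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
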