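# Internal helpers shared across modules.

# km subtended by one degree of latitude on a sphere of radius 6371 km
KM_PER_DEG <- pi / 180 * 6371

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise log(sum(exp(m))) without overflow; m is a numeric matrix
logsumexp_rows <- function(m) {
  j <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), j)]
  mx + log(rowSums(exp(m - mx)))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

year_of <- function(d) as.integer(format(as.Date(d), "%Y"))

#' Project geographic coordinates to a local planar frame
#'
#' Sinusoidal (equal-area) projection about a study-area origin: meridian
#' spacing uses each point's own latitude, so distances stay accurate to
#' well under 0.5% across a few-hundred-km study box (the Lesser Antilles
#' arc). Distances come out in km.
#'
#' @param lat,lon coordinates in decimal degrees.
#' @param origin numeric length-2 vector `c(lat, lon)` of the projection
#'   origin. Defaults to the Lesser Antilles study centroid.
#' @return A two-column matrix with columns `x` and `y` in km.
#' @seealso [unproject_planar()]
#' @export
project_planar <- function(lat, lon, origin = c(14.5, -61.0)) {
  x <- (lon - origin[2]) * cos(lat * pi / 180) * KM_PER_DEG
  y <- (lat - origin[1]) * KM_PER_DEG
  cbind(x = x, y = y)
}

#' @rdname project_planar
#' @param x,y planar coordinates in km.
#' @export
unproject_planar <- function(x, y, origin = c(14.5, -61.0)) {
  lat <- origin[1] + y / KM_PER_DEG
  lon <- origin[2] + x / (cos(lat * pi / 180) * KM_PER_DEG)
  cbind(lat = lat, lon = lon)
}
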