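# Effort-corrected maximum-likelihood RMS displacement across resighting
# time lags, with individual jackknife standard errors.
#
# Model, per lag bin: an individual first seen at x and seen again tau days
# later was displaced by an isotropic bivariate Gaussian with per-axis sd s,
# but is only resighted where there was survey effort. The contribution of a
# pair (x -> y) is
#     E(cell(y)) * phi2(y - x; s^2 I) / sum_z E(z) * phi2(z_c - x; s^2 I)
# with the denominator summed over all effort cells z (centers z_c). The
# 1/(2 pi s^2) normalisations cancel between numerator and denominator, and
# log E(cell(y)) is constant in s, so the profile being maximised is
#     sum_pairs [ -d^2/(2 s^2) - logsumexp_z( log E_z - D^2_z/(2 s^2) ) ].
# RMS displacement for the bin is s * sqrt(2).

default_lag_bins <- function() c(1, 2, 5, 10, 30, 90, 180, 365, 500)

# reduce sightings to one record per individual per day (first by time if
# available), project to planar km
prepare_sightings <- function(sightings, origin = NULL) {
  assert_columns(sightings, c("individual_id", "date", "lat", "lon"), "sightings")
  s <- sightings
  if ("time" %in% names(s)) s <- s[order(s$individual_id, s$date, s$time), ]
  else s <- s[order(s$individual_id, s$date), ]
  s <- s[!duplicated(s[, c("individual_id", "date")]), , drop = FALSE]
  origin <- origin %||% c(mean(s$lat), mean(s$lon))
  xy <- project_planar(s$lat, s$lon, origin)
  s$x <- xy[, 1]; s$y <- xy[, 2]
  attr(s, "origin") <- origin
  s
}

# all ordered within-individual sighting pairs with lag > min_lag_days
build_pairs <- function(s, min_lag_days = 1) {
  out <- list()
  for (id in unique(s$individual_id)) {
    si <- s[s$individual_id == id, , drop = FALSE]
    n <- nrow(si)
    if (n < 2L) next
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(a) seq.int(a + 1L, n)))
    tau <- as.numeric(si$date[j] - si$date[i])
    keep <- tau > min_lag_days
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      individual_id = id,
      x1 = si$x[i][keep], y1 = si$y[i][keep],
      x2 = si$x[j][keep], y2 = si$y[j][keep],
      tau = tau[keep])
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# deterministic, RNG-free thinning: evenly spaced rows after a stable sort
thin_pairs <- function(pairs, max_pairs) {
  if (is.null(max_pairs) || nrow(pairs) <= max_pairs) return(pairs)
  pairs <- pairs[order(pairs$individual_id, pairs$tau, pairs$x1, pairs$y1), ]
  idx <- unique(round(seq(1, nrow(pairs), length.out = max_pairs)))
  pairs[idx, , drop = FALSE]
}

# profile log-likelihood (numerator/denominator constants dropped)
rms_profile_ll <- function(s, d2, D2, logE) {
  A <- -d2 / (2 * s^2)
  M <- sweep(-D2 / (2 * s^2), 2L, logE, "+")
  sum(A - logsumexp_rows(M))
}

fit_bin_s <- function(d2, D2, logE, s_bounds) {
  f <- function(ls) -rms_profile_ll(exp(ls), d2, D2, logE)
  opt <- stats::optimize(f, interval = log(s_bounds), tol = 1e-7)
  s_hat <- exp(opt$minimum)
  boundary <- if (opt$minimum < log(s_bounds[1]) + 1e-3) "lower"
  else if (opt$minimum > log(s_bounds[2]) - 1e-3) "upper"
  else ""
  list(s = s_hat, ll = -opt$objective, boundary = boundary)
}

#' Effort-corrected ML estimate of RMS displacement by time lag
#'
#' For each lag bin `(lo, hi]`, collects all within-individual resighting
#' pairs with lag in the bin (lags of at most `min_lag_days` are excluded
#' because within-day and next-day positions of a tracked whale are
#' autocorrelated), and maximises an effort-corrected isotropic-Gaussian
#' displacement likelihood over the per-axis sd `s`. The survey-effort field
#' enters the likelihood denominator, correcting for the uneven spatial
#' distribution of identification effort. RMS displacement is `s * sqrt(2)`.
#'
#' @param sightings data.frame with `individual_id`, `date`, `lat`, `lon`
#'   (one record per individual per day is enforced, keeping the first).
#' @param effort an `effort_field` from [build_effort()] or
#'   [uniform_effort()].
#' @param lag_bins numeric vector of bin edges in days.
#' @param min_lag_days smallest usable lag (default 1 day).
#' @param s_bounds search bounds for `s` in km.
#' @param origin projection origin `c(lat, lon)`; default sighting centroid.
#' @param max_pairs_per_bin optional cap on pairs per bin (deterministic,
#'   evenly spaced thinning; purely computational).
#' @return data.frame of class `rms_estimate`: `lag_lo`, `lag_hi`,
#'   `lag_mean_days`, `n_pairs`, `n_individuals`, `s_km`, `rms_km`,
#'   `boundary`, `loglik`. Bins without pairs are omitted with a warning.
#' @export
rms_ml <- function(sightings, effort, lag_bins = default_lag_bins(),
                   min_lag_days = 1, s_bounds = c(0.1, 5000),
                   origin = NULL, max_pairs_per_bin = NULL) {
  stopifnot(inherits(effort, "effort_field") || all(c("lat", "lon", "effort") %in% names(effort)))
  if (sum(effort$effort) <= 0) stop("degenerate effort field", call. = FALSE)
  s <- prepare_sightings(sightings, origin)
  origin <- attr(s, "origin")
  pairs <- build_pairs(s, min_lag_days)
  if (is.null(pairs)) stop("no resighting pairs beyond min_lag_days", call. = FALSE)
  cells <- project_planar(effort$lat, effort$lon, origin)
  logE <- log(effort$effort[effort$effort > 0])
  cells <- cells[effort$effort > 0, , drop = FALSE]
  out <- list()
  for (b in seq_len(length(lag_bins) - 1L)) {
    lo <- lag_bins[b]; hi <- lag_bins[b + 1L]
    pb <- pairs[pairs$tau > lo & pairs$tau <= hi, , drop = FALSE]
    if (nrow(pb) == 0L) {
      warning(sprintf("no resighting pairs in lag bin (%g, %g]; bin omitted", lo, hi),
              call. = FALSE)
      next
    }
    pb <- thin_pairs(pb, max_pairs_per_bin)
    d2 <- (pb$x2 - pb$x1)^2 + (pb$y2 - pb$y1)^2
    D2 <- outer(pb$x1, cells[, 1], "-")^2 + outer(pb$y1, cells[, 2], "-")^2
    fit <- fit_bin_s(d2, D2, logE, s_bounds)
    out[[length(out) + 1L]] <- data.frame(
      lag_lo = lo, lag_hi = hi, lag_mean_days = mean(pb$tau),
      n_pairs = nrow(pb), n_individuals = length(unique(pb$individual_id)),
      s_km = fit$s, rms_km = fit$s * sqrt(2),
      boundary = fit$boundary, loglik = fit$ll,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no lag bin contained resighting pairs", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rms_estimate", "data.frame")
  attr(res, "origin") <- origin
  res
}

#' Individual jackknife standard errors for RMS displacement
#'
#' Recomputes the per-bin ML RMS displacement leaving each contributing
#' individual out in turn; the standard error is
#' `sqrt(((n - 1)/n) * sum_i (theta_(i) - mean(theta_(.)))^2)` with `n` the
#' number of individuals contributing pairs to the bin. Bins with fewer than
#' two contributing individuals get `NA`.
#'
#' @inheritParams rms_ml
#' @return the [rms_ml()] data.frame with a `jackknife_se_km` column added.
#' @export
jackknife_se <- function(sightings, effort, lag_bins = default_lag_bins(),
                         min_lag_days = 1, s_bounds = c(0.1, 5000),
                         origin = NULL, max_pairs_per_bin = NULL) {
  est <- rms_ml(sightings, effort, lag_bins, min_lag_days, s_bounds,
                origin, max_pairs_per_bin)
  origin <- attr(est, "origin")
  s <- prepare_sightings(sightings, origin)
  pairs <- build_pairs(s, min_lag_days)
  cells <- project_planar(effort$lat, effort$lon, origin)
  logE <- log(effort$effort[effort$effort > 0])
  cells <- cells[effort$effort > 0, , drop = FALSE]
  se <- rep(NA_real_, nrow(est))
  for (b in seq_len(nrow(est))) {
    pb <- pairs[pairs$tau > est$lag_lo[b] & pairs$tau <= est$lag_hi[b], , drop = FALSE]
    pb <- thin_pairs(pb, max_pairs_per_bin)
    inds <- unique(pb$individual_id)
    n <- length(inds)
    if (n < 2L) next
    d2 <- (pb$x2 - pb$x1)^2 + (pb$y2 - pb$y1)^2
    D2 <- outer(pb$x1, cells[, 1], "-")^2 + outer(pb$y1, cells[, 2], "-")^2
    theta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      keep <- pb$individual_id != inds[i]
      if (!any(keep)) next
      fit <- fit_bin_s(d2[keep], D2[keep, , drop = FALSE], logE, s_bounds)
      theta[i] <- fit$s * sqrt(2)
    }
    theta <- theta[!is.na(theta)]
    m <- length(theta)
    if (m < 2L) next
    se[b] <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
  }
  est$jackknife_se_km <- se
  est
}

#' @export
print.rms_estimate <- function(x, ...) {
  cat("Effort-corrected RMS displacement by time lag:\n")
  cols <- intersect(c("lag_lo", "lag_hi", "lag_mean_days", "n_pairs",
                      "n_individuals", "rms_km", "jackknife_se_km", "boundary"),
                    names(x))
  print.data.frame(x[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}
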