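# Independent oracles the tests check the implementation against. These are
# deliberately written from first principles (different formulas, plain
# loops) and never call the code paths they verify.

year_of <- function(d) as.integer(format(as.Date(d), "%Y"))

# spherical law of cosines distance, km (alternative to haversine)
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(1, pmax(-1, ca)))
}

# hand-rolled union-find connected components; returns canonical partition
# string sorted by member id
uf_partition <- function(ids, edges_a, edges_b) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_along(edges_a)) {
    ra <- find(match(edges_a[e], ids))
    rb <- find(match(edges_b[e], ids))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  comps <- split(ids, roots)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  paste(vapply(comps, paste, character(1), collapse = ","), collapse = "|")
}

# canonical partition string of a membership data.frame (group col, id col)
membership_partition <- function(df, group_col, id_col) {
  comps <- split(df[[id_col]], df[[group_col]])
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  paste(vapply(comps, paste, character(1), collapse = ","), collapse = "|")
}

# naive O(n^3) average-linkage agglomeration returning the cophenetic
# distance matrix (which fully determines the dendrogram)
naive_avg_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  C <- matrix(0, n, n)
  while (length(members) > 1L) {
    m <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        h <- mean(D[members[[i]], members[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    C[members[[i]], members[[j]]] <- best[1]
    C[members[[j]], members[[i]]] <- best[1]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }
  C
}

# brute-force two-stage grid search of the full effort-corrected likelihood
# (constants kept; independent of the package's profile/optimize path)
grid_search_s <- function(pairs, eff_xy, logE, s_lo = 0.1, s_hi = 5000,
                          n_coarse = 200, n_fine = 400) {
  ll_of_s <- function(s) {
    tot <- 0
    for (p in seq_len(nrow(pairs))) {
      dx <- pairs$x2[p] - pairs$x1[p]; dy <- pairs$y2[p] - pairs$y1[p]
      lognum <- -(dx^2 + dy^2) / (2 * s^2) - log(2 * pi * s^2)
      d2c <- (eff_xy[, 1] - pairs$x1[p])^2 + (eff_xy[, 2] - pairs$y1[p])^2
      terms <- logE - d2c / (2 * s^2) - log(2 * pi * s^2)
      mx <- max(terms)
      logden <- mx + log(sum(exp(terms - mx)))
      # nearest-cell effort at the resighting position
      d2y <- (eff_xy[, 1] - pairs$x2[p])^2 + (eff_xy[, 2] - pairs$y2[p])^2
      tot <- tot + logE[which.min(d2y)] + lognum - logden
    }
    tot
  }
  coarse <- exp(seq(log(s_lo), log(s_hi), length.out = n_coarse))
  llc <- vapply(coarse, ll_of_s, numeric(1))
  i <- which.max(llc)
  lo <- coarse[max(1, i - 2L)]; hi <- coarse[min(n_coarse, i + 2L)]
  fine <- seq(lo, hi, length.out = n_fine)
  llf <- vapply(fine, ll_of_s, numeric(1))
  fine[which.max(llf)]
}

# Brownian resighting histories with known sigma (independent of gen_tracks)
sim_diffusion_sightings <- function(n_ind, n_days, sigma, n_sight, seed,
                                    origin = c(14.5, -61)) {
  set.seed(seed)
  rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    d <- sort(sample(0:n_days, n_sight))
    steps <- matrix(stats::rnorm(2L * length(d), 0,
                                 sigma * sqrt(c(d[1] + 1, diff(d)))), ncol = 2)
    pos <- apply(steps, 2, cumsum)
    if (length(d) == 1L) pos <- matrix(pos, ncol = 2)
    ll <- unproject_planar(pos[, 1], pos[, 2], origin)
    rows[[i]] <- data.frame(individual_id = sprintf("w%03d", i),
                            date = as.Date("2019-01-01") + d,
                            lat = ll[, 1], lon = ll[, 2])
  }
  do.call(rbind, rows)
}

# clan specs sharing one pooled usage mix: a label-free null world
null_clan_specs <- function() {
  specs <- default_clan_specs()
  mixes <- lapply(specs, `[[`, "usage_mix")
  types <- sort(unique(unlist(lapply(mixes, names))))
  M <- vapply(mixes, function(m) {
    v <- stats::setNames(numeric(length(types)), types)
    v[names(m)] <- m
    v
  }, numeric(length(types)))
  pool <- rowMeans(M)
  pool <- pool / sum(pool)
  lapply(specs, function(s) {
    s$usage_mix <- pool
    s
  })
}

# small photo table used across io tests
tiny_photos <- function() {
  data.frame(
    individual_id = c("A", "B", "A", "C", "B", "D"),
    date = as.Date(c("2019-02-01", "2019-02-01", "2019-02-02",
                     "2019-02-02", "2020-03-05", "2020-03-05")),
    time = c(10 * 3600, 11.5 * 3600, 9 * 3600, 10 * 3600,
             8 * 3600, 8.5 * 3600),
    lat = c(15.4, 15.41, 15.38, 15.39, 13.9, 13.91),
    lon = c(-61.4, -61.41, -61.37, -61.36, -61.0, -61.01),
    quality = c(3L, 4L, 5L, 3L, 4L, 5L))
}
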