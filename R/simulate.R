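# Synthetic-data generators: clan-structured codas, island-resident diffusive
# movement, and effort-biased survey/resighting histories, all with ground
# truth recorded so every pipeline stage can be tested without field data.

#' Default coda type catalogue for the synthetic world
#'
#' Mean ICI patterns (seconds) for the coda types used by the default
#' three-clan generator: regular types `3R`..`11R` and the split patterns
#' `1+3`, `1+1+3`, `2+1+1+1`, `1+4`. Patterns are chosen so that
#' [label_type()] with default parameters reproduces each name.
#'
#' @return named list: label -> numeric vector of mean ICIs.
#' @export
default_coda_types <- function() {
  list(
    "3R" = rep(0.30, 2), "4R" = rep(0.25, 3), "5R" = rep(0.22, 4),
    "6R" = rep(0.20, 5), "7R" = rep(0.18, 6), "8R" = rep(0.16, 7),
    "9R" = rep(0.14, 8), "10R" = rep(0.12, 9), "11R" = rep(0.11, 10),
    "1+3" = c(0.45, 0.15, 0.15),
    "1+1+3" = c(0.40, 0.40, 0.15, 0.15),
    "2+1+1+1" = c(0.15, 0.40, 0.40, 0.40),
    "1+4" = c(0.45, 0.15, 0.15, 0.15))
}

#' Default clan specifications
#'
#' Three vocal clans with paper-shaped usage mixes: clan `ec1` dominated by
#' the `1+1+3` type (54% of its codas), clan `ec2` by `5R` plus `2+1+1+1`
#' (combining to 61%), and clan `ec3` by long regular codas `9R`/`10R`/`11R`
#' (combining to 57%). Each clan also has minor identity types (10 planted
#' identity types in total) and shares low-level background types (`3R`,
#' `4R`, `6R`) with the other clans. `leakage` is the usage each foreign
#' identity type receives outside its own clan; background usage absorbs the
#' remainder so every mix sums to 1.
#'
#' @param leakage per-type foreign identity usage (default 0.01; 0 makes
#'   identity types perfectly exclusive).
#' @param sd_ici Gaussian sd of each ICI about its type mean, seconds.
#' @return list of clan specs: `clan_id`, `usage_mix` (named numeric),
#'   `identity_labels`, `sd_ici`.
#' @export
default_clan_specs <- function(leakage = 0.01, sd_ici = 0.01) {
  # minor identity types sit clearly above the default detection usage
  # threshold (0.05): an identity coda used right at the threshold is not
  # "used consistently" in any meaningful sense
  identity <- list(
    ec1 = c("1+1+3" = 0.54, "1+3" = 0.08, "7R" = 0.08),
    ec2 = c("5R" = 0.35, "2+1+1+1" = 0.26, "1+4" = 0.08),
    ec3 = c("9R" = 0.20, "10R" = 0.20, "11R" = 0.17, "8R" = 0.08))
  background <- list(
    ec1 = c("4R" = 0.12, "3R" = 0.11, "6R" = 0.05),
    ec2 = c("4R" = 0.10, "3R" = 0.09, "6R" = 0.08),
    ec3 = c("4R" = 0.11, "3R" = 0.10, "6R" = 0.11))
  lapply(names(identity), function(cl) {
    own <- identity[[cl]]
    foreign <- unlist(unname(identity[setdiff(names(identity), cl)]))
    leak <- stats::setNames(rep(leakage, length(foreign)), names(foreign))
    bg <- background[[cl]]
    bg_mass <- 1 - sum(own) - sum(leak)
    if (bg_mass < 0) stop("leakage too large for a valid usage mix", call. = FALSE)
    bg <- bg / sum(bg) * bg_mass
    mix <- c(own, bg, leak)
    mix <- mix[mix > 0]
    stopifnot(abs(sum(mix) - 1) < 1e-12)
    list(clan_id = cl, usage_mix = mix, identity_labels = names(own),
         sd_ici = sd_ici)
  })
}

survey_season_days <- function() {
  c(seq(as.Date("2019-02-01"), as.Date("2019-04-15"), by = "day"),
    seq(as.Date("2020-01-10"), as.Date("2020-03-25"), by = "day"))
}

#' Generate clan-structured codas with ground truth
#'
#' Draws, for each group and recording day, a Poisson number of codas
#' (mean `coda_day_mean`); a fraction `p_subthreshold` of days are
#' deliberately sub-threshold (5--24 codas) to exercise the repertoire-size
#' filter. Coda types are drawn from the group's clan usage mix and click
#' times are built from Gaussian ICIs about the type means (truncated
#' positive, written to 0.1 ms).
#'
#' @param clan_specs list from [default_clan_specs()].
#' @param n_groups_per_clan integer vector, one entry per clan.
#' @param days_per_group recording days per group.
#' @param coda_day_mean Poisson mean of codas per (group, day).
#' @param p_subthreshold fraction of sub-threshold days.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list: `codas` (data.frame in the standard coda schema plus
#'   `n_clicks`) and `truth` (list with `coda_types`, `group_clans`,
#'   `cells` = per-repertoire bookkeeping, `identity_types`, `usage_mix`).
#' @export
gen_codas <- function(clan_specs = default_clan_specs(),
                      n_groups_per_clan = c(18, 14, 10),
                      days_per_group = 4L, coda_day_mean = 120,
                      p_subthreshold = 0.05, seed = 42L) {
  stopifnot(length(n_groups_per_clan) == length(clan_specs))
  set.seed(seed)
  types <- default_coda_types()
  days <- survey_season_days()
  codas <- list(); truth_type <- list(); cells <- list(); groups <- list()
  counter <- 0L
  for (ci in seq_along(clan_specs)) {
    spec <- clan_specs[[ci]]
    if (abs(sum(spec$usage_mix) - 1) > 1e-8) {
      stop(sprintf("usage mix of clan %s does not sum to 1", spec$clan_id),
           call. = FALSE)
    }
    if (!all(names(spec$usage_mix) %in% names(types))) {
      stop("usage mix references unknown coda types", call. = FALSE)
    }
    for (g in seq_len(n_groups_per_clan[ci])) {
      group_id <- sprintf("%s_g%02d", spec$clan_id, g)
      groups[[group_id]] <- spec$clan_id
      gdays <- sort(sample(days, days_per_group))
      for (d in seq_along(gdays)) {
        sub <- stats::runif(1) < p_subthreshold
        n <- if (sub) sample(5:24, 1L) else stats::rpois(1L, coda_day_mean)
        sub <- n < 25L
        labs <- sample(names(spec$usage_mix), n, replace = TRUE,
                       prob = spec$usage_mix)
        ct <- vapply(labs, function(l) {
          ici <- pmax(stats::rnorm(length(types[[l]]), types[[l]], spec$sd_ici), 0.02)
          paste(sprintf("%.4f", cumsum(c(0, ici))), collapse = ";")
        }, character(1))
        ids <- sprintf("c%07d", counter + seq_len(n))
        counter <- counter + n
        codas[[length(codas) + 1L]] <- data.frame(
          coda_id = ids, source = "survey", date = gdays[d],
          group_id = group_id, click_times = unname(ct),
          n_clicks = lengths(types[labs]) + 1L,
          stringsAsFactors = FALSE)
        truth_type[[length(truth_type) + 1L]] <- data.frame(
          coda_id = ids, label = labs, stringsAsFactors = FALSE)
        cells[[length(cells) + 1L]] <- data.frame(
          repertoire_id = paste(group_id, as.character(gdays[d]), sep = "@"),
          group_id = group_id, date = gdays[d], clan_id = spec$clan_id,
          n_codas = n, subthreshold = sub, stringsAsFactors = FALSE)
      }
    }
  }
  codas <- do.call(rbind, codas); rownames(codas) <- NULL
  truth_type <- do.call(rbind, truth_type); rownames(truth_type) <- NULL
  cells <- do.call(rbind, cells); rownames(cells) <- NULL
  idt <- do.call(rbind, lapply(clan_specs, function(s)
    data.frame(clan_id = s$clan_id, label = s$identity_labels,
               stringsAsFactors = FALSE)))
  mix <- lapply(clan_specs, `[[`, "usage_mix")
  names(mix) <- vapply(clan_specs, `[[`, character(1), "clan_id")
  list(codas = codas,
       truth = list(coda_types = truth_type,
                    group_clans = data.frame(group_id = names(groups),
                                             clan_id = unlist(groups),
                                             row.names = NULL,
                                             stringsAsFactors = FALSE),
                    cells = cells, identity_types = idt, usage_mix = mix))
}

#' Default clan home islands for the synthetic world
#'
#' @return named list clan_id -> character vector of island names (see
#'   [lesser_antilles_gazetteer()]).
#' @export
default_clan_islands <- function() {
  list(ec1 = c("StKitts", "Guadeloupe", "Dominica", "StVincent"),
       ec2 = c("Martinique", "StLucia"),
       ec3 = "Martinique")
}

#' Generate island-resident diffusive tracks
#'
#' Daily positions follow a mean-reverting (Ornstein--Uhlenbeck-like) 2-D
#' walk about a home island centroid: per-axis daily innovation sd `sigma_d`
#' (km/day^0.5), pull `attraction` toward home per day, and a small
#' probability of switching home island within the clan's island set.
#' `attraction = 0, switch_prob = 0` gives pure diffusion with per-axis sd
#' `sigma_d * sqrt(lag)`.
#'
#' @param n_individuals_per_clan integer vector, one entry per clan.
#' @param n_days number of simulated days.
#' @param sigma_d per-axis daily innovation sd, km/day^0.5.
#' @param attraction daily pull toward the home island, in [0, 1).
#' @param switch_prob daily probability of switching home island.
#' @param clan_islands named list from [default_clan_islands()].
#' @param seed integer seed.
#' @param start_date `Date` of day 0.
#' @param ids optional character vector of track ids (recycled across clans
#'   in order); default `"<clan>_w<i>"`.
#' @param origin projection origin for the lat/lon columns.
#' @return data.frame `individual_id`, `clan_id`, `home_island`, `day`,
#'   `date`, `x`, `y`, `lat`, `lon`; attributes record `sigma_d`,
#'   `attraction`, `switch_prob`.
#' @export
gen_tracks <- function(n_individuals_per_clan = c(18, 14, 10), n_days = 420L,
                       sigma_d = 10, attraction = 0.1, switch_prob = 0.002,
                       clan_islands = default_clan_islands(), seed = 1L,
                       start_date = as.Date("2019-02-01"), ids = NULL,
                       origin = c(14.5, -61.0)) {
  stopifnot(sigma_d > 0, attraction >= 0, attraction < 1)
  set.seed(seed)
  gaz <- lesser_antilles_gazetteer()
  gxy <- project_planar(gaz$lat, gaz$lon, origin)
  rownames(gxy) <- gaz$island
  clans <- rep(names(clan_islands), n_individuals_per_clan)
  n <- length(clans)
  if (is.null(ids)) {
    ids <- unlist(lapply(names(clan_islands), function(cl)
      sprintf("%s_w%03d", cl, seq_len(n_individuals_per_clan[[match(cl, names(clan_islands))]]))))
  }
  stopifnot(length(ids) == n)
  home_isl <- vapply(clans, function(cl) {
    isl <- clan_islands[[cl]]
    if (length(isl) == 1L) isl else sample(isl, 1L)
  }, character(1))
  home <- gxy[home_isl, , drop = FALSE]
  # start at the stationary spread of the mean-reverting walk (at home for
  # pure diffusion)
  init_sd <- if (attraction > 0) sigma_d / sqrt(1 - (1 - attraction)^2) else 0
  pos <- home + matrix(stats::rnorm(2L * n, 0, init_sd), ncol = 2L)
  X <- matrix(NA_real_, n_days * n, 2L)
  isl_rec <- character(n_days * n)
  for (t in seq_len(n_days)) {
    if (switch_prob > 0) {
      sw <- which(stats::runif(n) < switch_prob)
      for (i in sw) {
        isl <- clan_islands[[clans[i]]]
        if (length(isl) > 1L) {
          home_isl[i] <- sample(setdiff(isl, home_isl[i]), 1L)
          home[i, ] <- gxy[home_isl[i], ]
        }
      }
    }
    pos <- pos + attraction * (home - pos) +
      matrix(stats::rnorm(2L * n, 0, sigma_d), ncol = 2L)
    rows <- (t - 1L) * n + seq_len(n)
    X[rows, ] <- pos
    isl_rec[rows] <- home_isl
  }
  ll <- unproject_planar(X[, 1], X[, 2], origin)
  out <- data.frame(
    individual_id = rep(ids, n_days), clan_id = rep(clans, n_days),
    home_island = isl_rec, day = rep(seq_len(n_days) - 1L, each = n),
    date = rep(start_date + seq_len(n_days) - 1L, each = n),
    x = X[, 1], y = X[, 2], lat = ll[, 1], lon = ll[, 2],
    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$day), ]
  rownames(out) <- NULL
  attr(out, "sigma_d") <- sigma_d
  attr(out, "attraction") <- attraction
  attr(out, "switch_prob") <- switch_prob
  attr(out, "origin") <- origin
  out
}

#' Correlated random walk track at 5-min resolution
#'
#' A vessel-like (or whale-following) track: constant cruise speed with a
#' random-walk heading, sampled every `fix_minutes`. Used to emulate the
#' survey platform and fine-scale whale-following legs.
#'
#' @param lat0,lon0 start position, degrees.
#' @param hours track duration.
#' @param speed_kmh cruise speed (default 7.408 km/h = 4 knots).
#' @param turn_sd heading random-walk sd per step, radians.
#' @param heading0 initial heading, radians (0 = north); default random.
#' @param start_time `POSIXct` of the first fix.
#' @param track_id track label.
#' @param fix_minutes fix interval.
#' @return GPS data.frame (`timestamp`, `lat`, `lon`, `track_id`).
#' @export
gen_crw_track <- function(lat0, lon0, hours, speed_kmh = 7.408, turn_sd = 0.3,
                          heading0 = NULL,
                          start_time = as.POSIXct("2019-02-01 06:00:00", tz = "UTC"),
                          track_id = "T1", fix_minutes = 5) {
  n <- round(hours * 60 / fix_minutes)
  step <- speed_kmh * fix_minutes / 60
  heading <- cumsum(c(heading0 %||% stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n - 1L, 0, turn_sd)))
  dx <- c(0, step * sin(heading[-n]))
  dy <- c(0, step * cos(heading[-n]))
  origin <- c(lat0, lon0)
  ll <- unproject_planar(cumsum(dx), cumsum(dy), origin)
  data.frame(timestamp = start_time + (seq_len(n) - 1L) * fix_minutes * 60,
             lat = ll[, 1], lon = ll[, 2], track_id = track_id,
             stringsAsFactors = FALSE)
}

#' Simulate a photo-identification survey over simulated tracks
#'
#' The vessel patrols leeward transect segments (day-center latitudes drawn
#' with extra weight on the central islands, so identification effort is
#' spatially uneven by design). Platforms (groups or individuals) whose
#' daily position lies within `detection_km` of the vessel track that day
#' are encountered (at most `max_encounters_per_day`, nearest first); each
#' member is photographed with probability `p_photo`, with quality drawn
#' from `quality_probs` and a photo time inside the platform's staggered
#' encounter window (windows 4 h apart, so co-detected platforms do not
#' cross-associate under the 2-h rule).
#'
#' @param tracks daily-position data.frame from [gen_tracks()] (platform
#'   ids in `individual_id`).
#' @param members optional data.frame (`platform_id`, `individual_id`)
#'   expanding each platform into member whales; default one member per
#'   platform with the platform's id.
#' @param seed integer seed.
#' @param n_survey_days integer vector: survey days per season present.
#' @param detection_km detection radius.
#' @param p_photo per-member detection/photograph probability.
#' @param quality_probs probabilities of quality scores 1..5.
#' @param max_encounters_per_day vessel capacity per day.
#' @param lat_weights transect day-center weights over the gazetteer
#'   islands (north to south).
#' @return list: `photos` (standard photo schema plus `island`), `gps`
#'   (vessel fixes), `encounters` (`date`, `platform_id`, `clan_id`).
#' @export
gen_survey <- function(tracks, members = NULL, seed = 1L,
                       n_survey_days = c(24L, 32L), detection_km = 10,
                       p_photo = 0.9, quality_probs = rep(0.2, 5),
                       max_encounters_per_day = 3L, lat_weights = c(1, 1, 2, 3, 3, 3, 1, 1)) {
  set.seed(seed)
  gaz <- lesser_antilles_gazetteer()
  if (is.null(members)) {
    members <- data.frame(platform_id = unique(tracks$individual_id),
                          individual_id = unique(tracks$individual_id),
                          stringsAsFactors = FALSE)
  }
  dates <- sort(unique(tracks$date))
  seasons <- split(dates, year_of(dates))
  survey_days <- as.Date(unlist(lapply(seq_along(seasons), function(i) {
    d <- seasons[[i]]
    k <- min(n_survey_days[min(i, length(n_survey_days))], length(d))
    sort(sample(d, k))
  })), origin = "1970-01-01")
  photos <- list(); gps <- list(); enc <- list()
  for (sd_i in seq_along(survey_days)) {
    d <- survey_days[sd_i]
    lat_c <- gaz$lat[sample.int(nrow(gaz), 1L, prob = lat_weights)]
    lon_c <- gaz$lon[which.min(abs(gaz$lat - lat_c))] - 0.25
    v <- gen_crw_track(lat_c - 0.4, lon_c, hours = 12, turn_sd = 0.15,
                       heading0 = 0,
                       start_time = as.POSIXct(paste(d, "06:00:00"), tz = "UTC"),
                       track_id = paste0("V", format(d, "%Y%m%d")))
    gps[[length(gps) + 1L]] <- v
    day_pos <- tracks[tracks$date == d, , drop = FALSE]
    if (nrow(day_pos) == 0L) next
    dmin <- vapply(seq_len(nrow(day_pos)), function(i)
      min(great_circle_km(day_pos$lat[i], day_pos$lon[i], v$lat, v$lon)),
      numeric(1))
    hit <- which(dmin <= detection_km)
    if (length(hit) == 0L) next
    hit <- hit[order(dmin[hit])][seq_len(min(length(hit), max_encounters_per_day))]
    for (k in seq_along(hit)) {
      p <- day_pos[hit[k], ]
      enc[[length(enc) + 1L]] <- data.frame(
        date = d, platform_id = p$individual_id, clan_id = p$clan_id,
        stringsAsFactors = FALSE)
      mem <- members$individual_id[members$platform_id == p$individual_id]
      shot <- mem[stats::runif(length(mem)) < p_photo]
      if (length(shot) == 0L) next
      t0 <- 6 * 3600 + (k - 1L) * 4 * 3600  # staggered 4-h encounter windows
      photos[[length(photos) + 1L]] <- data.frame(
        individual_id = shot, date = d,
        time = t0 + stats::runif(length(shot), 0, 3600),
        lat = p$lat + stats::rnorm(length(shot), 0, 0.005),
        lon = p$lon + stats::rnorm(length(shot), 0, 0.005),
        quality = sample.int(5L, length(shot), replace = TRUE, prob = quality_probs),
        stringsAsFactors = FALSE)
    }
  }
  photos <- if (length(photos) > 0L) do.call(rbind, photos) else
    data.frame(individual_id = character(0), date = as.Date(character(0)),
               time = numeric(0), lat = numeric(0), lon = numeric(0),
               quality = integer(0))
  if (nrow(photos) > 0L) photos <- assign_island(photos)
  gps <- do.call(rbind, gps)
  enc <- if (length(enc) > 0L) do.call(rbind, enc) else
    data.frame(date = as.Date(character(0)), platform_id = character(0),
               clan_id = character(0))
  rownames(photos) <- rownames(gps) <- rownames(enc) <- NULL
  list(photos = photos, gps = gps, encounters = enc)
}

#' Generate a complete synthetic dataset bundle
#'
#' Runs [gen_codas()], simulates one movement track per group with
#' [gen_tracks()], expands groups into member whales, and runs
#' [gen_survey()] over them. The truth manifest records everything the
#' acceptance tests need: clan labels, coda type labels, identity types,
#' the movement sd, and unit (group) memberships.
#'
#' @param seed integer seed driving every draw.
#' @param n_groups_per_clan,days_per_group passed to [gen_codas()].
#' @param sigma_d,attraction,switch_prob passed to [gen_tracks()].
#' @param mean_members_per_group Poisson-ish mean group size per clan.
#' @param ... passed to [gen_survey()].
#' @return list: `codas`, `photos`, `gps`, `encounters`, `truth` (adds
#'   `unit_members` and `sigma_d` to the [gen_codas()] truth).
#' @export
gen_all <- function(seed = 42L, n_groups_per_clan = c(18, 14, 10),
                    days_per_group = 4L, sigma_d = 10, attraction = 0.1,
                    switch_prob = 0.002,
                    mean_members_per_group = c(7, 8, 10), ...) {
  acoustic <- gen_codas(n_groups_per_clan = n_groups_per_clan,
                        days_per_group = days_per_group, seed = seed)
  gc <- acoustic$truth$group_clans
  n_days <- as.integer(max(survey_season_days()) - min(survey_season_days())) + 1L
  tracks <- gen_tracks(
    n_individuals_per_clan = n_groups_per_clan, n_days = n_days,
    sigma_d = sigma_d, attraction = attraction, switch_prob = switch_prob,
    seed = seed + 1L, start_date = min(survey_season_days()),
    ids = gc$group_id)
  set.seed(seed + 2L)
  clan_idx <- match(gc$clan_id, unique(gc$clan_id))
  sizes <- pmax(3L, stats::rpois(nrow(gc), mean_members_per_group[clan_idx]))
  members <- data.frame(
    platform_id = rep(gc$group_id, sizes),
    individual_id = unlist(lapply(seq_len(nrow(gc)), function(i)
      sprintf("%s_w%02d", gc$group_id[i], seq_len(sizes[i])))),
    stringsAsFactors = FALSE)
  survey <- gen_survey(tracks, members = members, seed = seed + 3L, ...)
  truth <- acoustic$truth
  truth$unit_members <- members
  truth$sigma_d <- sigma_d
  list(codas = acoustic$codas, photos = survey$photos, gps = survey$gps,
       encounters = survey$encounters, truth = truth)
}

#' Coda table with the published bookkeeping margins
#'
#' A generator preset whose output reproduces the bookkeeping structure of
#' the combined Eastern Caribbean coda dataset: per-source totals (survey
#' 5558, long-term archive 11375, historical archive 2106; 19039 codas in
#' all), 163 overlong codas (>11 clicks) placed in large repertoires, 813
#' codas confined to sub-threshold (<25 coda) repertoires, and 151
#' analysable repertoires left after both filters. Click trains are regular
#' placeholders; this fixture exercises the filter arithmetic, not typing.
#'
#' @param n_by_source named integer vector of per-source coda counts.
#' @param n_overlong number of >11-click codas.
#' @param n_small total codas in sub-threshold repertoires.
#' @param n_large_repertoires number of analysable repertoires.
#' @param seed integer seed (layout is deterministic; the seed only feeds
#'   the click-time jitter).
#' @return coda data.frame with `n_clicks`.
#' @export
gen_bookkeeping_codas <- function(n_by_source = c(survey = 5558,
                                                  archive_longterm = 11375,
                                                  archive_historical = 2106),
                                  n_overlong = 163L, n_small = 813L,
                                  n_large_repertoires = 151L, seed = 1L) {
  set.seed(seed)
  total <- sum(n_by_source)
  n_large <- total - n_overlong - n_small
  # sub-threshold repertoires: as many 24-coda repertoires as fit, plus one
  # remainder repertoire of 5..23 codas
  n24 <- n_small %/% 24L
  rem <- n_small - 24L * n24
  small_sizes <- c(rep(24L, n24), if (rem >= 5L) rem)
  if (rem > 0L && rem < 5L) small_sizes[1] <- small_sizes[1] + rem
  base <- n_large %/% n_large_repertoires
  extra <- n_large - base * n_large_repertoires
  large_sizes <- rep(base, n_large_repertoires) + c(rep(1L, extra),
                                                    rep(0L, n_large_repertoires - extra))
  stopifnot(all(large_sizes >= 25L))
  rep_sizes <- c(large_sizes, small_sizes)
  rep_ids <- c(sprintf("L%03d", seq_along(large_sizes)),
               sprintf("S%03d", seq_along(small_sizes)))
  group_id <- rep(rep_ids, rep_sizes)
  date <- rep(as.Date("2005-01-01") + seq_along(rep_sizes), rep_sizes)
  n_clicks <- rep(rep(3:11, length.out = length(rep_sizes)), rep_sizes)
  # overlong codas ride on the large repertoires, one per repertoire cycling
  over_rep <- rep_ids[rep(seq_along(large_sizes), length.out = n_overlong)]
  over_dates <- date[match(over_rep, group_id)]
  group_id <- c(group_id, over_rep)
  date <- c(date, over_dates)
  n_clicks <- c(n_clicks, rep(12:15, length.out = n_overlong))
  click_strings <- vapply(3:15, function(k)
    paste(sprintf("%.4f", (seq_len(k) - 1L) * 0.2), collapse = ";"), character(1))
  codas <- data.frame(
    coda_id = sprintf("b%05d", seq_along(group_id)),
    source = rep(names(n_by_source), times = n_by_source),
    date = date, group_id = group_id,
    click_times = click_strings[n_clicks - 2L],
    n_clicks = n_clicks, stringsAsFactors = FALSE)
  rownames(codas) <- NULL
  codas
}
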