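#' Default metier specifications for the synthetic fleet
#'
#' Three Mediterranean-style metiers with gear-specific behaviour:
#' * `OTB_DES` (bottom otter trawl, demersal): fishing at uniform 2.5-4.5 kn
#'   over grounds at 80-400 m, catches concentrated on hake/mullet/shrimp.
#' * `PS_SPF` (purse seine, small pelagics): bimodal activity - searching at
#'   about 8 kn, setting/hauling near 0.3 kn (the fishing state) over 20-100 m
#'   grounds, catching sardine/anchovy/mackerel.
#' * `PTM_SPF` (pelagic pair trawl): 2.5-4.5 kn over 100-300 m, blue
#'   whiting/horse mackerel/bogue.
#'
#' Steaming is N(10, 1) kn (truncated to 7-13) for all gears, so fishing and
#' steaming speed regimes do not overlap. The Dirichlet concentration vectors
#' have disjoint supports, so the mean catch compositions are mutually at
#' Bray-Curtis dissimilarity 1.
#'
#' @return Named list of metier spec lists.
#' @export
default_metier_specs <- function() {
  list(
    OTB_DES = list(gear = "OTB", v_fish = c(2.5, 4.5),
                   depth_fish = c(80, 400), depth_thresh = c(50, 450),
                   fish_h = c(4, 10), alpha = c(HKE = 12, MUT = 6, DPS = 6, NEP = 3),
                   catch_kg_day = 250, style = "trawl"),
    PS_SPF = list(gear = "PS", v_fish = c(0, 1.5), v_search = 8,
                  depth_fish = c(20, 100), depth_thresh = c(5, 120),
                  fish_h = c(5, 9), alpha = c(PIL = 15, ANE = 9, MAC = 3),
                  catch_kg_day = 400, style = "seine"),
    PTM_SPF = list(gear = "PTM", v_fish = c(2.5, 4.5),
                   depth_fish = c(100, 300), depth_thresh = c(50, 350),
                   fish_h = c(4, 9), alpha = c(WHB = 12, HMM = 6, BOG = 2),
                   catch_kg_day = 300, style = "trawl"))
}

#' Describe a synthetic fleet scenario
#'
#' The default scenario mirrors a small-sample study setting: 13 vessels
#' active through June 2012 with a native ping cadence of about 2 hours, two
#' harbours on the edge of a rectangular landmass, and bathymetry deepening
#' linearly (5 m per km) with distance from the coast. Error-injection rates
#' are per-ping Bernoulli probabilities.
#'
#' @param n_vessels Number of vessels (default 13).
#' @param start Start date (UTC, default 2012-06-01).
#' @param days Span in days (default 30).
#' @param ping_interval_min Native cadence in minutes (default 120).
#' @param metier_specs See [default_metier_specs()].
#' @param rates Named list of error-injection probabilities: `duplicate`,
#'   `on_land`, `bad_speed`, `bad_heading`, `gap` (all in `[0, 1]`).
#' @param noise_deg SD of Gaussian position noise on sea pings (degrees).
#' @param lb_jitter_h Uniform jitter half-width (hours) applied to logbook
#'   interval edges.
#' @param seed Integer seed; simulation is deterministic given the scenario.
#' @return Object of class `fleet_scenario`.
#' @export
fleet_scenario <- function(n_vessels = 13,
                           start = "2012-06-01",
                           days = 30,
                           ping_interval_min = 120,
                           metier_specs = default_metier_specs(),
                           rates = list(duplicate = 0.02, on_land = 0.01,
                                        bad_speed = 0.01, bad_heading = 0.01,
                                        gap = 0),
                           noise_deg = 5e-4,
                           lb_jitter_h = 0.5,
                           seed = 1) {
  stopifnot(n_vessels >= 1, days >= 1, ping_interval_min > 0,
            all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  structure(list(
    n_vessels = n_vessels,
    start = as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
    days = days,
    ping_interval_min = ping_interval_min,
    metier_specs = metier_specs,
    rates = rates, noise_deg = noise_deg, lb_jitter_h = lb_jitter_h,
    # geometry: sea west of the coast meridian, land rectangle east of it
    coast_lon = 11.5, lon_min = 9.8, lon_max = 12.5,
    lat_min = 42, lat_max = 44,
    slope_m_per_km = 5,
    harbour_lats = c(42.7, 43.3),
    seed = seed), class = "fleet_scenario")
}

.scn_harbours <- function(scn) {
  data.frame(id = paste0("HB", seq_along(scn$harbour_lats)),
             name = paste0("Harbour ", seq_along(scn$harbour_lats)),
             lon = scn$coast_lon, lat = scn$harbour_lats,
             stringsAsFactors = FALSE)
}

.scn_coastline <- function(scn) {
  data.frame(id = "LAND",
             lon = c(scn$coast_lon, scn$lon_max, scn$lon_max, scn$coast_lon),
             lat = c(scn$lat_min, scn$lat_min, scn$lat_max, scn$lat_max),
             stringsAsFactors = FALSE)
}

.scn_depth <- function(scn, lon, lat) {
  km <- (scn$coast_lon - lon) * 111.19493 * cos(lat * pi / 180)
  ifelse(lon >= scn$coast_lon, 50, -scn$slope_m_per_km * pmax(km, 0))
}

.scn_bathy <- function(scn, cell = 0.05) {
  lon <- seq(scn$lon_min, scn$lon_max, by = cell)
  lat <- seq(scn$lat_min, scn$lat_max, by = cell)
  z <- outer(lat, lon, function(la, lo) .scn_depth(scn, lo, la))
  bathy_grid(lon, lat, z)
}

#' Fishing thresholds implied by a scenario's metier specs
#'
#' One row per metier with the spec's fishing speed range and the (wider)
#' depth threshold band, directly usable by [mark_fishing()].
#'
#' @param scn A [fleet_scenario()].
#' @return Threshold data frame, see [default_thresholds()].
#' @export
scenario_thresholds <- function(scn) {
  specs <- scn$metier_specs
  data.frame(metier = names(specs),
             vmin = vapply(specs, function(s) s$v_fish[1], 0),
             vmax = vapply(specs, function(s) s$v_fish[2], 0),
             dmin = vapply(specs, function(s) s$depth_thresh[1], 0),
             dmax = vapply(specs, function(s) s$depth_thresh[2], 0),
             min_harbour_km = NA_real_, stringsAsFactors = FALSE)
}

#' Reference catch profiles of a scenario
#'
#' The Dirichlet mean composition of each metier, as a labelled profile
#' matrix over the scenario's species universe. Useful for assigning DCF
#' labels to discovered medoids (the "metier editing" step).
#'
#' @param scn A [fleet_scenario()].
#' @return Numeric matrix, one row per metier (rownames = metier names).
#' @export
reference_profiles <- function(scn) {
  specs <- scn$metier_specs
  sp <- sort(unique(unlist(lapply(specs, function(s) names(s$alpha)))))
  out <- matrix(0, length(specs), length(sp),
                dimnames = list(names(specs), sp))
  for (i in seq_along(specs)) {
    a <- specs[[i]]$alpha
    out[i, names(a)] <- a / sum(a)
  }
  out
}

# Truncated normal draw.
.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Build the leg table (t0, t1 seconds, lon0/lat0 -> lon1/lat1, speed kn,
# state code 1=harbour 2=steam 3=fishing, trip) for one vessel.
.vessel_legs <- function(scn, harbour, spec, t_start, t_end, trip_id_start) {
  legs <- list()
  add <- function(t0, t1, p0, p1, speed, state, trip)
    legs[[length(legs) + 1L]] <<- c(t0, t1, p0[1], p0[2], p1[1], p1[2],
                                    speed, state, if (is.na(trip)) NA_real_ else trip)
  hpos <- c(harbour$lon, harbour$lat)
  km_h <- function(p, q) gc_dist_km(p[1], p[2], q[1], q[2])
  tc <- t_start
  trip <- trip_id_start
  trips <- list()
  repeat {
    dwell <- stats::runif(1, 5, 10) * 3600
    # plan the trip
    vs <- .rtnorm(1, 10, 1, 7, 13)
    tdep <- stats::runif(1, spec$depth_fish[1], spec$depth_fish[2])
    glat <- harbour$lat + stats::runif(1, -0.25, 0.25)
    glon <- scn$coast_lon -
      tdep / (scn$slope_m_per_km * 111.19493 * cos(glat * pi / 180))
    gpos <- c(glon, glat)
    steam_h <- km_h(hpos, gpos) / (vs * 1.852)
    fish_h <- stats::runif(1, spec$fish_h[1], spec$fish_h[2])
    trip_len <- (2 * steam_h + fish_h + 1) * 3600
    if (tc + dwell + trip_len > t_end) break
    add(tc, tc + dwell, hpos, hpos, 0, 1, NA)
    tc <- tc + dwell
    t_depart <- tc
    add(tc, tc + steam_h * 3600, hpos, gpos, vs, 2, trip)
    tc <- tc + steam_h * 3600
    pos <- gpos
    spent <- 0
    while (spent < fish_h) {
      if (spec$style == "seine") {
        # search burst to a new point, then a slow set/haul (the fishing state)
        npos <- gpos + c(stats::runif(1, -0.03, 0.03) /
                           cos(glat * pi / 180), stats::runif(1, -0.05, 0.05))
        sh <- max(km_h(pos, npos) / (spec$v_search * 1.852), 0.05)
        add(tc, tc + sh * 3600, pos, npos, spec$v_search, 2, trip)
        tc <- tc + sh * 3600; pos <- npos; spent <- spent + sh
        set_h <- stats::runif(1, 0.5, 1)
        vset <- 0.3
        ang <- stats::runif(1, 0, 2 * pi)
        dkm <- vset * 1.852 * set_h
        npos <- pos + c(dkm * sin(ang) / (111.19493 * cos(pos[2] * pi / 180)),
                        dkm * cos(ang) / 111.19493)
        add(tc, tc + set_h * 3600, pos, npos, vset, 3, trip)
        tc <- tc + set_h * 3600; pos <- npos; spent <- spent + set_h
      } else {
        vf <- stats::runif(1, spec$v_fish[1] + 0.05, spec$v_fish[2] - 0.05)
        npos <- gpos + c(stats::runif(1, -0.02, 0.02) /
                           cos(glat * pi / 180), stats::runif(1, -0.06, 0.06))
        d0 <- km_h(pos, npos)
        leg_h <- max(min(d0 / (vf * 1.852), fish_h - spent + 0.3), 0.05)
        npos2 <- if (d0 > 0) pos + (npos - pos) * (vf * 1.852 * leg_h) / d0 else pos
        add(tc, tc + leg_h * 3600, pos, npos2, vf, 3, trip)
        tc <- tc + leg_h * 3600; pos <- npos2; spent <- spent + leg_h
      }
    }
    back_h <- km_h(pos, hpos) / (vs * 1.852)
    add(tc, tc + back_h * 3600, pos, hpos, vs, 2, trip)
    tc <- tc + back_h * 3600
    trips[[length(trips) + 1L]] <- c(trip, t_depart, tc)
    trip <- trip + 1L
  }
  if (tc < t_end) add(tc, t_end, hpos, hpos, 0, 1, NA)
  legm <- do.call(rbind, legs)
  colnames(legm) <- c("t0", "t1", "lon0", "lat0", "lon1", "lat1",
                      "speed", "state", "trip")
  tripm <- if (length(trips)) do.call(rbind, trips) else NULL
  if (!is.null(tripm)) colnames(tripm) <- c("trip", "t_depart", "t_return")
  list(legs = as.data.frame(legm), trips = tripm)
}

#' Simulate a synthetic fishing fleet with full ground truth
#'
#' Generates, deterministically for the scenario seed, a mixed fleet whose
#' vessels alternate harbour dwell, steaming at cruise speed, and
#' gear-specific fishing bouts; VMS pings are sampled at the native cadence
#' (with small timing jitter and Gaussian position noise) and one logbook
#' record per trip draws its catch composition from the metier's Dirichlet
#' profile scaled by trip length. Erroneous pings (duplicates, on-land
#' positions, bad speed/heading values, gaps) are injected at the scenario
#' rates, and every ping and trip is recorded in ground-truth tables.
#'
#' @param scn A [fleet_scenario()].
#' @return List with elements `pings` (with `ping_id`), `logbook` (wide, as
#'   from [read_logbook()]), `harbours`, `coastline`, `bathy`, `thresholds`,
#'   `truth_pings` (ping_id, trip, state, injected), `truth_trips` (trip,
#'   vessel, metier, true interval) and the scenario.
#' @export
simulate_fleet <- function(scn) {
  stopifnot(inherits(scn, "fleet_scenario"))
  set.seed(scn$seed)
  harbours <- .scn_harbours(scn)
  specs <- scn$metier_specs
  t0 <- as.numeric(scn$start)
  t1 <- t0 + scn$days * 86400
  step <- scn$ping_interval_min * 60
  ping_rows <- list()
  trip_rows <- list()
  next_trip <- 1L
  for (v in seq_len(scn$n_vessels)) {
    vid <- sprintf("V%03d", v)
    spec_name <- names(specs)[(v - 1L) %% length(specs) + 1L]
    spec <- specs[[spec_name]]
    hb <- harbours[(v - 1L) %% nrow(harbours) + 1L, ]
    sim <- .vessel_legs(scn, hb, spec, t0, t1, next_trip)
    legs <- sim$legs
    if (!is.null(sim$trips)) {
      tr <- as.data.frame(sim$trips)
      tr$vessel_id <- vid
      tr$metier <- spec_name
      tr$harbour <- hb$id
      trip_rows[[v]] <- tr
      next_trip <- next_trip + nrow(tr)
    }
    phase <- stats::runif(1, 0, step)
    tt <- seq(t0 + phase, t1, by = step)
    tt <- sort(tt + stats::runif(length(tt), -300, 300))
    tt <- tt[tt >= t0 & tt <= t1]
    li <- findInterval(tt, legs$t0)
    li[li < 1L] <- 1L
    frac <- (tt - legs$t0[li]) / pmax(legs$t1[li] - legs$t0[li], 1)
    frac <- pmin(pmax(frac, 0), 1)
    lon <- legs$lon0[li] + frac * (legs$lon1[li] - legs$lon0[li])
    lat <- legs$lat0[li] + frac * (legs$lat1[li] - legs$lat0[li])
    state <- c("harbour", "steam", "fishing")[legs$state[li]]
    sea <- state != "harbour"
    lon[sea] <- lon[sea] + stats::rnorm(sum(sea), 0, scn$noise_deg)
    lat[sea] <- lat[sea] + stats::rnorm(sum(sea), 0, scn$noise_deg)
    hdg <- ifelse(legs$lon0[li] == legs$lon1[li] & legs$lat0[li] == legs$lat1[li],
                  0, bearing_deg(legs$lon0[li], legs$lat0[li],
                                 legs$lon1[li], legs$lat1[li]))
    ping_rows[[v]] <- data.frame(
      vessel_id = vid, timestamp = tt, lon = lon, lat = lat,
      speed = legs$speed[li], heading = hdg,
      trip = as.integer(legs$trip[li]), state = state, stringsAsFactors = FALSE)
  }
  pings <- do.call(rbind, ping_rows)
  trips <- do.call(rbind, trip_rows)

  # --- error injection -------------------------------------------------
  n <- nrow(pings)
  pings$injected <- ""
  sea_idx <- which(pings$state != "harbour")
  pick <- function(pool, rate) {
    if (rate <= 0 || !length(pool)) return(integer(0))
    pool[stats::runif(length(pool)) < rate]
  }
  used <- integer(0)
  i_land <- pick(setdiff(intersect(sea_idx,
                                   which(pings$lon >= 11.0 & pings$lon < scn$coast_lon)),
                         used), scn$rates$on_land)
  used <- c(used, i_land)
  pings$lon[i_land] <- scn$coast_lon + 0.05
  pings$injected[i_land] <- "ON_LAND"
  i_speed <- pick(setdiff(sea_idx, used), scn$rates$bad_speed)
  used <- c(used, i_speed)
  pings$speed[i_speed] <- ifelse(stats::runif(length(i_speed)) < 0.5,
                                 -stats::runif(length(i_speed), 1, 3),
                                 26 + stats::runif(length(i_speed), 0, 3))
  pings$injected[i_speed] <- "BAD_SPEED"
  i_head <- pick(setdiff(sea_idx, used), scn$rates$bad_heading)
  used <- c(used, i_head)
  pings$heading[i_head] <- 360 + stats::runif(length(i_head), 0, 40)
  pings$injected[i_head] <- "BAD_HEADING"
  i_dup <- pick(setdiff(seq_len(n), used), scn$rates$duplicate)
  dup <- pings[i_dup, , drop = FALSE]
  at_sea_dup <- dup$state != "harbour"   # transmitter-echo jitter, sea only
  dup$lon[at_sea_dup] <- dup$lon[at_sea_dup] +
    stats::rnorm(sum(at_sea_dup), 0, 1e-4)
  dup$injected <- rep("DUPLICATE", nrow(dup))
  pings <- rbind(pings, dup)
  if (scn$rates$gap > 0) {
    anchors <- pick(setdiff(sea_idx, used), scn$rates$gap / 7)
    kill <- unique(unlist(lapply(anchors, function(a) a:(a + 6L))))
    kill <- kill[kill <= n]
    if (length(kill)) pings <- pings[-kill, , drop = FALSE]
  }
  # stable sort keeps each original before its appended duplicate copy
  pings <- pings[order(pings$vessel_id, pings$timestamp), , drop = FALSE]
  pings$ping_id <- seq_len(nrow(pings))

  truth_pings <- data.frame(ping_id = pings$ping_id,
                            vessel_id = pings$vessel_id,
                            timestamp = as.POSIXct(pings$timestamp,
                                                   origin = "1970-01-01", tz = "UTC"),
                            trip = pings$trip, state = pings$state,
                            injected = pings$injected,
                            stringsAsFactors = FALSE)

  # --- logbook ---------------------------------------------------------
  sp_all <- sort(unique(unlist(lapply(specs, function(s) names(s$alpha)))))
  catch <- matrix(0, nrow(trips), length(sp_all),
                  dimnames = list(NULL, sp_all))
  for (i in seq_len(nrow(trips))) {
    spec <- specs[[trips$metier[i]]]
    a <- spec$alpha
    g <- stats::rgamma(length(a), shape = a)
    prof <- g / sum(g)
    days_at_sea <- (trips$t_return[i] - trips$t_depart[i]) / 86400
    total <- spec$catch_kg_day * days_at_sea * stats::rlnorm(1, 0, 0.3)
    catch[i, names(a)] <- round(prof * total, 1)
  }
  jit <- scn$lb_jitter_h * 3600
  dep <- trips$t_depart - stats::runif(nrow(trips), 0, 0.25) * 3600 +
    (if (jit > 0) stats::runif(nrow(trips), -jit, jit) else 0)
  arr <- trips$t_return + stats::runif(nrow(trips), 0, 0.25) * 3600 +
    (if (jit > 0) stats::runif(nrow(trips), -jit, jit) else 0)
  logbook <- data.frame(trip_id = trips$trip, vessel_id = trips$vessel_id,
                        departure = as.POSIXct(dep, origin = "1970-01-01", tz = "UTC"),
                        arrival = as.POSIXct(arr, origin = "1970-01-01", tz = "UTC"),
                        gear = NA_character_, metier = NA_character_,
                        stringsAsFactors = FALSE)
  logbook <- cbind(logbook, as.data.frame(catch))
  attr(logbook, "species") <- sp_all

  truth_trips <- data.frame(trip = trips$trip, vessel_id = trips$vessel_id,
                            metier = trips$metier,
                            t_depart = as.POSIXct(trips$t_depart,
                                                  origin = "1970-01-01", tz = "UTC"),
                            t_return = as.POSIXct(trips$t_return,
                                                  origin = "1970-01-01", tz = "UTC"),
                            stringsAsFactors = FALSE)

  out_pings <- as_vms_pings(data.frame(
    vessel_id = pings$vessel_id,
    timestamp = as.POSIXct(pings$timestamp, origin = "1970-01-01", tz = "UTC"),
    lon = pings$lon, lat = pings$lat,
    speed = pings$speed, heading = pings$heading,
    stringsAsFactors = FALSE))
  out_pings$ping_id <- pings$ping_id
  rownames(out_pings) <- NULL
  list(pings = out_pings, logbook = logbook, harbours = harbours,
       coastline = .scn_coastline(scn), bathy = .scn_bathy(scn),
       thresholds = scenario_thresholds(scn),
       truth_pings = truth_pings, truth_trips = truth_trips,
       scenario = scn)
}

#' Write a simulated fleet to the loader file formats
#'
#' Emits `vms.csv` (vessel, timestamp, lon, lat, speed, heading), long-form
#' `logbook.csv`, `harbours.csv`, `coastline.csv` and `bathy.xyz` into a
#' directory, readable by [read_vms()], [read_logbook()],
#' [read_points_layer()], [read_polygons_layer()] and [read_bathy_xyz()].
#'
#' @param sim Output of [simulate_fleet()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fleet_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$pings
  utils::write.table(data.frame(vessel = p$vessel_id,
                                timestamp = format(p$timestamp, .TIME_FMT, tz = "UTC"),
                                lon = p$lon, lat = p$lat,
                                speed = p$speed, heading = p$heading),
                     file.path(dir, "vms.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  lb <- sim$logbook
  sp <- logbook_species(lb)
  long <- do.call(rbind, lapply(seq_len(nrow(lb)), function(i) {
    pos <- sp[lb[i, sp] > 0]
    data.frame(vessel = lb$vessel_id[i],
               departure = format(lb$departure[i], .TIME_FMT, tz = "UTC"),
               arrival = format(lb$arrival[i], .TIME_FMT, tz = "UTC"),
               species = pos, quantity = as.numeric(lb[i, pos]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, file.path(dir, "logbook.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_layer(sim$harbours, file.path(dir, "harbours.csv"))
  write_layer(sim$coastline, file.path(dir, "coastline.csv"))
  write_bathy_xyz(sim$bathy, file.path(dir, "bathy.xyz"))
  invisible(dir)
}

#' Score pipeline outputs against the simulation ground truth
#'
#' Axes:
#' * `track_recovery`: fraction of true trips recovered by exactly one track
#'   whose native sea pings belong to that trip alone;
#' * `metier_agreement`: chance-adjusted agreement (adjusted Rand index)
#'   between the tracks' assigned metier labels and the true trip metiers;
#' * `fishing_precision` / `fishing_recall` of the `is_fishing` mark on
#'   native sea pings against the true activity state;
#' * `match_recovery`: fraction of true trips whose track is linked to the
#'   correct logbook record.
#'
#' @param pings Pipeline ping data frame (with `ping_id`, `track_id`,
#'   `is_fishing`).
#' @param tracks Track summary with `lb_trip_id` and a metier column.
#' @param sim Output of [simulate_fleet()].
#' @return Named list of scores in `[0, 1]` (`NA` where not computable).
#' @export
truth_compare <- function(pings, tracks, sim) {
  tp <- sim$truth_pings
  native <- pings[pings$source == "native" & !is.na(pings$ping_id), , drop = FALSE]
  trip_of <- tp$trip[match(native$ping_id, tp$ping_id)]
  state_of <- tp$state[match(native$ping_id, tp$ping_id)]
  trips_all <- sim$truth_trips$trip

  # track -> trip incidence from sea pings (harbour pings carry no trip)
  sea <- !is.na(trip_of) & !is.na(native$track_id)
  tab <- table(native$track_id[sea], trip_of[sea])
  pure <- rowSums(tab > 0) == 1L                       # track touches 1 trip
  touch <- colSums(tab > 0)                            # tracks touching trip
  one <- touch == 1L
  track_of_trip <- rep(NA_integer_, ncol(tab))
  track_of_trip[one] <- as.integer(rownames(tab))[
    apply(tab[, one, drop = FALSE] > 0, 2, which.max)]
  recovered <- one & pure[match(track_of_trip, as.integer(rownames(tab)))]
  recovered[is.na(recovered)] <- FALSE
  rec_trips <- as.integer(colnames(tab))[recovered]
  rec_tracks <- track_of_trip[recovered]
  track_recovery <- length(rec_trips) / length(trips_all)

  # metier agreement over recovered trips
  metier_col <- if ("metier_pred" %in% names(tracks)) "metier_pred" else "metier"
  pred <- tracks[[metier_col]][match(rec_tracks, tracks$track_id)]
  true <- sim$truth_trips$metier[match(rec_trips, trips_all)]
  ok <- !is.na(pred)
  metier_agreement <- if (sum(ok) > 1 && length(unique(true[ok])) > 1)
    mclust::adjustedRandIndex(pred[ok], true[ok]) else NA_real_

  # fishing state on native sea pings that were marked
  marked <- sea & !is.na(native$is_fishing)
  truth_fish <- state_of[marked] == "fishing"
  pred_fish <- native$is_fishing[marked]
  fishing_precision <- if (any(pred_fish)) mean(truth_fish[pred_fish]) else NA_real_
  fishing_recall <- if (any(truth_fish)) mean(pred_fish[truth_fish]) else NA_real_

  # matching: the track recovering trip t should link to logbook record t
  linked <- tracks$lb_trip_id[match(rec_tracks, tracks$track_id)]
  match_recovery <- if (length(rec_trips))
    mean(!is.na(linked) & linked == rec_trips) else NA_real_
  list(track_recovery = track_recovery,
       metier_agreement = metier_agreement,
       fishing_precision = fishing_precision,
       fishing_recall = fishing_recall,
       match_recovery = match_recovery)
}
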