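# One synthetic sea trip bracketed by harbour dwells, built by hand.
bracketed_trip <- function(vessel = "V1", t0 = 0) {
  t <- t0 + (0:9) * 7200
  p <- mk_pings(vessel, t = t,
                lon = c(10, 10, 9.9, 9.8, 9.7, 9.8, 9.9, 10, 10, 10),
                lat = 42.5, speed = c(0, 0, 8, 4, 4, 4, 8, 0, 0, 0))
  p$flags[c(1, 2, 8, 9, 10)] <- "IN_HARBOUR"
  p$harbour_id[c(1, 2, 8, 9, 10)] <- "HB1"
  p
}

test_that("harbour runs are trimmed to one boundary ping at each end", {
  p <- bracketed_trip()
  ct <- cut_tracks(p)
  expect_equal(attr(ct, "n_tracks"), 1L)
  inh <- has_flag(ct, "IN_HARBOUR")
  expect_equal(nrow(ct), 7L)          # 5 sea + 2 boundary harbour pings
  expect_equal(inh, c(TRUE, rep(FALSE, 5), TRUE))
  expect_true(all(diff(as.numeric(ct$timestamp)) > 0))
})

test_that("gaps above the threshold cut tracks and short fragments are dropped", {
  t <- c(0:3 * 7200, 30 * 3600 + 0:3 * 7200)   # 30 h gap in a sea sequence
  p <- mk_pings(t = t, lon = seq(9, 9.7, by = 0.1), lat = 42.5)
  ct <- cut_tracks(p, max_gap_h = 12)
  expect_equal(attr(ct, "n_tracks"), 2L)
  expect_equal(as.integer(table(ct$track_id)), c(4L, 4L))
  # a fragment with < 3 pings is discarded and counted
  p2 <- mk_pings(t = c(0, 7200, 40 * 3600), lon = c(9, 9.1, 9.5), lat = 42.5)
  ct2 <- cut_tracks(p2, max_gap_h = 12)
  expect_equal(attr(ct2, "n_tracks"), 0L)
  expect_gte(attr(ct2, "n_short_discarded"), 1L)
})

test_that("track partition recovers the generator's trips exactly", {
  scn <- fleet_scenario(n_vessels = 6, days = 15, seed = 9,
                        rates = list(duplicate = 0, on_land = 0, bad_speed = 0,
                                     bad_heading = 0, gap = 0))
  sim <- simulate_fleet(scn)
  p <- apply_policy(clean_pings(sim$pings, sim$harbours, sim$coastline))
  ct <- cut_tracks(p)
  expect_equal(attr(ct, "n_tracks"), nrow(sim$truth_trips))
  # partition property: every retained sea ping is in exactly one track
  expect_true(all(!is.na(ct$track_id)))
  expect_equal(anyDuplicated(ct$ping_id), 0L)
})

test_that("harbour inference uses flags at endpoints and nearest-harbour otherwise", {
  p <- bracketed_trip()
  ct <- cut_tracks(p)
  tr <- infer_harbours(ct, data.frame(id = c("HB1", "HB2"),
                                      name = c("a", "b"),
                                      lon = c(10, 11), lat = c(42.5, 42.5)))
  expect_equal(tr$departure_harbour, "HB1")
  expect_equal(tr$arrival_harbour, "HB1")
  # unflagged endpoints fall back to the nearest harbour
  sea <- mk_pings(t = 0:3 * 7200, lon = c(10.05, 10.2, 10.5, 10.9), lat = 42.5)
  ct2 <- cut_tracks(sea)
  tr2 <- infer_harbours(ct2, data.frame(id = c("HB1", "HB2"),
                                        name = c("a", "b"),
                                        lon = c(10, 11), lat = c(42.5, 42.5)))
  expect_equal(tr2$departure_harbour, "HB1")
  expect_equal(tr2$arrival_harbour, "HB2")
})

test_that("focal point is the mean of native coordinates, order-invariant", {
  p <- mk_pings(t = 0:4 * 7200, lon = c(9, 9.5, 10, 8.5, 9.2),
                lat = c(42, 42.4, 42.8, 42.2, 42.6))
  p$track_id <- 1L
  ts <- track_summary(p)
  expect_equal(ts$focal_lon, mean(p$lon))
  expect_equal(ts$focal_lat, mean(p$lat))
  perm <- p[sample(nrow(p)), ]
  expect_equal(track_summary(perm), ts)
})

test_that("interpolation reproduces natives exactly and aligns to the epoch grid", {
  set.seed(31)
  p <- mk_pings(t = 555 + 0:4 * 7200,
                lon = 10 + cumsum(runif(5, 0, 0.05)),
                lat = 42 + cumsum(runif(5, -0.02, 0.02)),
                speed = runif(5, 2, 6), heading = runif(5, 0, 359))
  p$track_id <- 1L
  ip <- interpolate_tracks(p, freq_min = 10)
  nat <- ip[ip$source == "native", ]
  expect_equal(nat$lon, p$lon)
  expect_equal(nat$lat, p$lat)
  expect_equal(as.numeric(nat$timestamp), as.numeric(p$timestamp))
  gridt <- as.numeric(ip$timestamp[ip$source == "interpolated"])
  expect_true(all(gridt %% 600 == 0))
  expect_equal(length(gridt),
               length(setdiff(seq(ceiling(555 / 600) * 600,
                                  555 + 4 * 7200, by = 600),
                              as.numeric(p$timestamp))))
  # two vessels share the interpolated instants
  q <- mk_pings("V2", t = 123 + 0:4 * 7200, lon = 10.5, lat = 42.5)
  q$track_id <- 2L
  iq <- interpolate_tracks(q, freq_min = 10)
  common <- intersect(as.numeric(ip$timestamp[ip$source == "interpolated"]),
                      as.numeric(iq$timestamp[iq$source == "interpolated"]))
  expect_gt(length(common), 30)
})

test_that("Hermite reduces to linear motion on constant-velocity tracks", {
  lat0 <- 43
  r <- 1.2e-5  # deg of longitude per second, eastbound
  spd_kn <- r * 6371008.8 * pi / 180 * cos(lat0 * pi / 180) / (1852 / 3600)
  t <- 600 * (0:5) * 12 + 300
  p <- mk_pings(t = t, lon = 10 + r * (t - t[1]), lat = lat0,
                speed = spd_kn, heading = 90)
  p$track_id <- 1L
  ip <- interpolate_tracks(p, freq_min = 10)
  t_abs0 <- as.numeric(p$timestamp[1])
  expect_lt(max(abs(ip$lon - (10 + r * (as.numeric(ip$timestamp) - t_abs0)))),
            1e-6)
  expect_lt(max(abs(ip$lat - lat0)), 1e-9)
  expect_lt(max(abs(ip$speed - spd_kn)), 1e-9)
  expect_lt(max(abs(ip$heading - 90)), 1e-9)
})

test_that("interpolated paths are continuous at the coherence ceiling", {
  scn <- fleet_scenario(n_vessels = 3, days = 8, seed = 13)
  sim <- simulate_fleet(scn)
  p <- apply_policy(clean_pings(sim$pings, sim$harbours, sim$coastline))
  ip <- interpolate_tracks(cut_tracks(p), freq_min = 10)
  max_step_km <- 30 * 1.852 * (10 / 60)  # ceiling speed over one 10-min step
  for (tid in unique(ip$track_id)) {
    tr <- ip[ip$track_id == tid, ]
    d <- gc_dist_km(head(tr$lon, -1), head(tr$lat, -1),
                    tr$lon[-1], tr$lat[-1])
    expect_lt(max(d), max_step_km * 1.5)  # Hermite overshoot margin
  }
})

test_that("short tracks are skipped with a warning", {
  p <- mk_pings(t = 0, lon = 10, lat = 42)
  p$track_id <- 1L
  expect_warning(ip <- interpolate_tracks(p, 10), "skip")
  expect_null(ip)
})
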