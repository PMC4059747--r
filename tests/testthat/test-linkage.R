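mk_tracks <- function(vessel, start_h, end_h) {
  data.frame(track_id = seq_along(vessel), vessel_id = vessel,
             start = utc("2012-06-01") + start_h * 3600,
             end = utc("2012-06-01") + end_h * 3600,
             n_pings = 5, focal_lon = 10, focal_lat = 42,
             stringsAsFactors = FALSE)
}

mk_lb <- function(vessel, dep_h, arr_h, metier = NA) {
  lb <- data.frame(trip_id = seq_along(vessel), vessel_id = vessel,
                   departure = utc("2012-06-01") + dep_h * 3600,
                   arrival = utc("2012-06-01") + arr_h * 3600,
                   gear = NA_character_, metier = metier,
                   HKE = 10, stringsAsFactors = FALSE)
  attr(lb, "species") <- "HKE"
  lb
}

test_that("interval overlap is the clipped intersection, symmetric", {
  s <- utc("2012-06-01")
  expect_equal(interval_overlap_h(s, s + 36000, s, s + 43200), 10)
  expect_equal(interval_overlap_h(s, s + 3600, s + 3600, s + 7200), 0)  # touching
  expect_equal(interval_overlap_h(s, s + 10 * 3600, s + 2 * 3600, s + 5 * 3600), 3)
  expect_equal(interval_overlap_h(s + 2 * 3600, s + 5 * 3600, s, s + 10 * 3600), 3)
  expect_equal(interval_overlap_h(s, s + 7200, s, s + 7200), 2)
})

test_that("tracks couple with the largest-overlap record of the same vessel", {
  tr <- mk_tracks("V1", 0, 10)
  lb <- mk_lb(c("V1", "V1", "V2"), c(8, 3, 0), c(12, 10, 10),
              metier = c("OTB", "PS", "PTM"))
  out <- match_trips(tr, lb)
  expect_equal(out$lb_trip_id, 2L)     # overlap 7 h beats 2 h
  expect_equal(out$overlap_h, 7)
  expect_equal(out$metier, "PS")       # copied from the record
  expect_equal(attr(out, "match_rate_pct"), 100)
  # several tracks may absorb the same record
  tr2 <- mk_tracks(c("V1", "V1"), c(0, 5), c(4, 9))
  out2 <- match_trips(tr2, mk_lb("V1", 0, 9, metier = "OTB"))
  expect_equal(out2$lb_trip_id, c(1L, 1L))
  # exact overlap ties: earliest record start, then id
  tr3 <- mk_tracks("V1", 4, 6)
  lb3 <- mk_lb(c("V1", "V1"), c(2, 4), c(6, 8), metier = c("A", "B"))
  expect_equal(match_trips(tr3, lb3)$lb_trip_id, 1L)
})

test_that("matching is stable under non-overlapping additions", {
  tr <- mk_tracks(c("V1", "V2"), c(0, 0), c(10, 8))
  lb <- mk_lb(c("V1", "V2"), c(1, 1), c(9, 9))
  base <- match_trips(tr, lb)
  lb_more <- rbind(lb, mk_lb("V1", 100, 110))
  lb_more$trip_id <- seq_len(nrow(lb_more))
  attr(lb_more, "species") <- "HKE"
  again <- match_trips(tr, lb_more)
  expect_equal(again$lb_trip_id, base$lb_trip_id)
  # unmatched bookkeeping
  expect_equal(attr(again, "unmatched_trips"), 3L)
})

test_that("true pairs are recovered exactly under bounded logbook jitter", {
  scn <- fleet_scenario(n_vessels = 8, days = 20, seed = 27,
                        lb_jitter_h = 1,   # < half the >= 5 h inter-trip dwell
                        rates = list(duplicate = 0, on_land = 0, bad_speed = 0,
                                     bad_heading = 0, gap = 0))
  sim <- simulate_fleet(scn)
  p <- cut_tracks(apply_policy(clean_pings(sim$pings, sim$harbours)))
  tr <- match_trips(infer_harbours(p, sim$harbours), sim$logbook)
  # every track must link to the logbook record of its own trip
  tp <- sim$truth_pings
  maj <- vapply(tr$track_id, function(tid) {
    ids <- p$ping_id[p$track_id == tid]
    trips <- tp$trip[match(ids, tp$ping_id)]
    as.integer(names(sort(table(trips), decreasing = TRUE))[1])
  }, integer(1))
  expect_equal(tr$lb_trip_id, maj)
  expect_equal(attr(tr, "match_rate_pct"), 100)
})

test_that("track features are fixed-length, order-invariant descriptors", {
  set.seed(28)
  p <- mk_pings(t = 0:20 * 600, lon = 10 + 0:20 * 0.01, lat = 42,
                speed = runif(21, 0, 12), heading = 90)
  p$track_id <- 1L
  p$depth <- -runif(21, 50, 200)
  f <- track_features(p)
  expect_equal(dim(f), c(1L, 29L))
  expect_equal(f, track_features(p[sample(21), ]))
  # constant speed collapses the quantile block
  pc <- mk_pings(t = 0:9 * 600, lon = 10, lat = 42, speed = 4.2)
  pc$track_id <- 2L
  fc <- track_features(pc)
  expect_true(all(fc[1, paste0("q", seq(0, 100, 10))] == 4.2))
  expect_equal(unname(fc[1, "bin4_5"]), 1)
})

test_that("the neural net separates metiers with disjoint speed regimes", {
  scn <- fleet_scenario(n_vessels = 10, days = 25, seed = 29,
                        metier_specs = default_metier_specs()[c("OTB_DES", "PS_SPF")],
                        rates = list(duplicate = 0, on_land = 0, bad_speed = 0,
                                     bad_heading = 0, gap = 0))
  sim <- simulate_fleet(scn)
  p <- cut_tracks(apply_policy(clean_pings(sim$pings, sim$harbours)))
  ip <- assign_depth(interpolate_tracks(p, 20), sim$bathy)
  tr <- infer_harbours(ip, sim$harbours)
  truth_met <- sim$truth_trips$metier[match(
    vapply(tr$track_id, function(tid) {
      ids <- ip$ping_id[ip$track_id == tid & !is.na(ip$ping_id)]
      tt <- sim$truth_pings$trip[match(ids, sim$truth_pings$ping_id)]
      as.integer(names(sort(table(tt), decreasing = TRUE))[1])
    }, integer(1)), sim$truth_trips$trip)]
  tr$metier <- truth_met
  tr$metier[seq(1, nrow(tr), by = 3)] <- NA  # hide a third of the labels
  out <- predict_metier(ip, tr, seed = 5)
  expect_gte(attr(out, "heldout_accuracy"), 0.9)
  expect_equal(out$metier_pred[!is.na(tr$metier)],
               tr$metier[!is.na(tr$metier)])
  hidden <- is.na(tr$metier)
  expect_gt(mean(out$metier_pred[hidden] == truth_met[hidden]), 0.9)
  # seeded determinism
  out2 <- predict_metier(ip, tr, seed = 5)
  expect_identical(out$metier_pred, out2$metier_pred)
  expect_error(predict_metier(ip, within(tr, metier <- "OTB_DES")), "2 metier")
})

test_that("fishing marks respect speed, depth and harbour-distance conjunction", {
  th <- data.frame(metier = "OTB", vmin = 2.5, vmax = 4.5,
                   dmin = 50, dmax = 450, min_harbour_km = NA,
                   stringsAsFactors = FALSE)
  p <- mk_pings(t = 1:5 * 600, lon = 10, lat = 42,
                speed = c(3.4, 3.4, 4.5, 2.4, 3.0))
  p$metier <- "OTB_DES_>=40_0_0"      # matched through the gear prefix
  p$depth <- c(-100, -900, -450, -100, NA)
  out <- mark_fishing(p, th)
  expect_equal(out$is_fishing, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # metier without thresholds stays unmarked and is counted
  p2 <- p; p2$metier <- "GNS"
  out2 <- mark_fishing(p2, th)
  expect_true(all(is.na(out2$is_fishing)))
  expect_equal(attr(out2, "n_unmarked"), 5L)
  # harbour-distance rule
  th3 <- within(th, min_harbour_km <- 5)
  hb <- data.frame(id = "H", name = "h", lon = 10, lat = 42)
  p3 <- p; p3$depth <- -100
  p3$lon <- c(10, 10.001, 10.2, 10.2, 10.2)
  out3 <- mark_fishing(p3, th3, harbours = hb)
  expect_equal(out3$is_fishing, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_error(mark_fishing(p3, th3), "harbours")
})

test_that("widening any threshold range never unmarks a fishing ping", {
  set.seed(33)
  p <- mk_pings(t = 1:50 * 600, lon = 10, lat = 42,
                speed = runif(50, 0, 12))
  p$metier <- "OTB"
  p$depth <- -runif(50, 0, 600)
  th <- data.frame(metier = "OTB", vmin = 2.5, vmax = 4.5, dmin = 50,
                   dmax = 450, min_harbour_km = NA, stringsAsFactors = FALSE)
  narrow <- mark_fishing(p, th)$is_fishing
  wide <- mark_fishing(p, within(th, {vmin <- 1; vmax <- 6; dmin <- 10;
                                      dmax <- 500}))$is_fishing
  expect_true(all(wide[narrow]))
})
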