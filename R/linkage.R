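#' Overlap between two time intervals, in hours
#'
#' `max(0, min(ends) - max(starts))`; symmetric, zero for touching or
#' disjoint intervals. Vectorised.
#'
#' @param start1,end1,start2,end2 POSIXct vectors.
#' @return Numeric hours, `>= 0`.
#' @export
interval_overlap_h <- function(start1, end1, start2, end2) {
  pmax(0, (pmin(as.numeric(end1), as.numeric(end2)) -
             pmax(as.numeric(start1), as.numeric(start2))) / 3600)
}

#' Match VMS tracks to logbook records by temporal overlap
#'
#' Candidate pairs need the same vessel and strictly positive overlap between
#' the track's time span and the logbook record's departure-arrival interval.
#' One logbook record may absorb several tracks; a track overlapping several
#' records is coupled with the largest overlap, exact ties resolved by
#' earliest record departure then lowest trip id. Metier and gear are copied
#' from the matched record onto the track.
#'
#' @param tracks Track summary (see [track_summary()]).
#' @param lb Logbook data frame (see [read_logbook()]).
#' @return `tracks` with columns `lb_trip_id`, `overlap_h`, `metier`, `gear`
#'   added (`NA` for unmatched tracks); attributes `match_rate_pct`
#'   (percentage of tracks matched) and `unmatched_tracks`,
#'   `unmatched_trips` (ids).
#' @export
match_trips <- function(tracks, lb) {
  n <- nrow(tracks)
  tracks$lb_trip_id <- rep(NA_integer_, n)
  tracks$overlap_h <- rep(NA_real_, n)
  tracks$metier <- rep(NA_character_, n)
  tracks$gear <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- which(lb$vessel_id == tracks$vessel_id[i])
    if (!length(cand)) next
    ov <- interval_overlap_h(tracks$start[i], tracks$end[i],
                             lb$departure[cand], lb$arrival[cand])
    cand <- cand[ov > 0]; ov <- ov[ov > 0]
    if (!length(cand)) next
    o <- order(-ov, as.numeric(lb$departure[cand]), lb$trip_id[cand])
    pick <- cand[o[1]]
    tracks$lb_trip_id[i] <- lb$trip_id[pick]
    tracks$overlap_h[i] <- ov[o[1]]
    tracks$metier[i] <- as.character(lb$metier[pick])
    tracks$gear[i] <- as.character(lb$gear[pick])
  }
  matched <- !is.na(tracks$lb_trip_id)
  attr(tracks, "match_rate_pct") <- 100 * mean(matched)
  attr(tracks, "unmatched_tracks") <- tracks$track_id[!matched]
  attr(tracks, "unmatched_trips") <- setdiff(lb$trip_id, tracks$lb_trip_id)
  tracks
}

#' Behavioural feature vector per track
#'
#' A fixed-order numeric descriptor of each track, computed from its
#' (interpolated) pings: the 11 speed quantiles (0, 10, ..., 100%), the
#' fraction of pings in each 1-knot speed bin from 0 to 15 kn (15 bins, the
#' last closed above), trip duration in hours, mean absolute depth in metres
#' (0 when no depth is available) and the fraction of night pings (UTC hour
#' before 06:00 or from 18:00). Invariant to ping order.
#'
#' @param pings Ping data frame with `track_id` assigned.
#' @return Numeric matrix, one row per track (rownames = track ids),
#'   29 columns.
#' @export
track_features <- function(pings) {
  pings <- pings[!is.na(pings$track_id), , drop = FALSE]
  ids <- sort(unique(pings$track_id))
  qs <- seq(0, 1, by = 0.1)
  bins <- 0:15
  feats <- t(vapply(ids, function(tid) {
    p <- pings[pings$track_id == tid, , drop = FALSE]
    sp <- p$speed[!is.na(p$speed)]
    if (!length(sp)) sp <- 0
    qv <- stats::quantile(sp, qs, names = FALSE)
    bc <- hist(pmin(pmax(sp, 0), 15), breaks = bins, plot = FALSE)$counts
    dur <- as.numeric(difftime(max(p$timestamp), min(p$timestamp), units = "hours"))
    dep <- mean(abs(p$depth), na.rm = TRUE)
    if (!is.finite(dep)) dep <- 0
    hrs <- as.integer(format(p$timestamp, "%H", tz = "UTC"))
    night <- mean(hrs < 6 | hrs >= 18)
    c(qv, bc / length(sp), dur, dep, night)
  }, numeric(11 + 15 + 3)))
  rownames(feats) <- ids
  colnames(feats) <- c(paste0("q", seq(0, 100, 10)),
                       paste0("bin", head(bins, -1), "_", bins[-1]),
                       "duration_h", "mean_abs_depth_m", "night_frac")
  feats
}

#' Predict metiers for unlabelled tracks with a neural network
#'
#' Trains a single-hidden-layer feed-forward classifier (32 units, seeded
#' initialisation) on the standardised [track_features()] of the tracks whose
#' metier is known (e.g. from logbook matching). A stratified 80/20 split of
#' the labelled tracks reports held-out accuracy; the final network is then
#' refitted on all labelled tracks and applied to the unlabelled ones.
#'
#' @param pings Interpolated ping data frame with `track_id` (depth optional).
#' @param tracks Track summary with a `metier` column (`NA` = unlabelled).
#' @param hidden Hidden-layer size (default 32).
#' @param seed Integer seed controlling the split and the weight
#'   initialisation.
#' @param maxit Training iterations.
#' @return `tracks` with `metier_pred` (known label where present, predicted
#'   otherwise) and `metier_conf` columns; attribute `heldout_accuracy`.
#' @export
predict_metier <- function(pings, tracks, hidden = 32, seed = 1, maxit = 300) {
  labelled <- !is.na(tracks$metier)
  classes <- unique(tracks$metier[labelled])
  if (length(classes) < 2L)
    stop("need at least 2 metier classes in the labelled tracks")
  feats <- track_features(pings)
  feats <- feats[match(as.character(tracks$track_id), rownames(feats)), ,
                 drop = FALSE]
  mu <- colMeans(feats[labelled, , drop = FALSE])
  sdv <- apply(feats[labelled, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  z <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  y <- factor(tracks$metier, levels = sort(classes))

  set.seed(seed)
  lab_idx <- which(labelled)
  test <- unlist(lapply(split(lab_idx, y[lab_idx]), function(ix)
    if (length(ix) >= 5L) sample(ix, max(1L, round(0.2 * length(ix))))
    else integer(0)))
  train <- setdiff(lab_idx, test)
  fit_net <- function(idx) {
    nnet::nnet(z[idx, , drop = FALSE], nnet::class.ind(y[idx]),
               size = hidden, softmax = TRUE, maxit = maxit,
               MaxNWts = 100000, trace = FALSE)
  }
  acc <- NA_real_
  if (length(test)) {
    net0 <- fit_net(train)
    pred0 <- colnames(net0$fitted.values)[max.col(
      predict(net0, z[test, , drop = FALSE]), ties.method = "first")]
    acc <- mean(pred0 == as.character(y[test]))
  }
  set.seed(seed)
  net <- fit_net(lab_idx)
  prob <- predict(net, z)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  conf <- prob[cbind(seq_len(nrow(prob)), max.col(prob, ties.method = "first"))]
  tracks$metier_pred <- ifelse(labelled, tracks$metier, pred)
  tracks$metier_conf <- ifelse(labelled, 1, conf)
  attr(tracks, "heldout_accuracy") <- acc
  tracks
}

#' Fishing threshold table helpers
#'
#' A threshold table has one row per metier with columns `metier`, `vmin`,
#' `vmax` (knots), `dmin`, `dmax` (metres, `NA` = no depth rule) and
#' `min_harbour_km` (`NA` = no distance rule). `default_thresholds()` ships
#' the conventional towed-gear preset (OTB/TBB/PTM at 2.5-4.5 kn).
#'
#' @return A threshold data frame.
#' @export
default_thresholds <- function() {
  data.frame(metier = c("OTB", "TBB", "PTM"),
             vmin = 2.5, vmax = 4.5,
             dmin = NA_real_, dmax = NA_real_,
             min_harbour_km = NA_real_, stringsAsFactors = FALSE)
}

#' @rdname default_thresholds
#' @param path File path.
#' @param sep Field separator.
#' @export
read_thresholds <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("metier", "vmin", "vmax") %in% names(d)))
  for (nm in c("dmin", "dmax", "min_harbour_km"))
    if (is.null(d[[nm]])) d[[nm]] <- NA_real_
  bad <- d$vmin > d$vmax |
    (!is.na(d$dmin) & !is.na(d$dmax) & d$dmin > d$dmax)
  if (any(bad)) stop("invalid threshold range for metier ",
                     paste(d$metier[bad], collapse = ", "))
  d
}

#' @rdname default_thresholds
#' @param thresholds Threshold data frame.
#' @export
write_thresholds <- function(thresholds, path, sep = ",") {
  utils::write.table(thresholds, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Mark fishing set positions
#'
#' A ping is a fishing set position when its reported speed lies inside its
#' metier's `[vmin, vmax]` range (inclusive at both ends) AND, where a depth
#' range is given, its absolute depth lies in `[dmin, dmax]` AND, where a
#' harbour-distance rule is given, its distance to the nearest harbour is at
#' least `min_harbour_km`. A missing depth fails an active depth rule. Pings
#' whose metier has no threshold row keep `is_fishing = NA` and are counted.
#'
#' @param pings Ping data frame with `metier` filled (track-level labels
#'   propagated to pings).
#' @param thresholds Threshold table, see [default_thresholds()]. Matching is
#'   by exact metier string, falling back to the gear prefix before the first
#'   underscore (so `OTB_DES_>=40_0_0` finds the `OTB` row).
#' @param harbours Point layer; only needed when a distance rule is active.
#' @return Pings with `is_fishing` set; attribute `n_unmarked` counts pings
#'   without an applicable threshold.
#' @export
mark_fishing <- function(pings, thresholds = default_thresholds(),
                         harbours = NULL) {
  row_for <- function(met) {
    if (is.na(met)) return(NA_integer_)
    i <- match(met, thresholds$metier)
    if (is.na(i)) i <- match(sub("_.*$", "", met), thresholds$metier)
    i
  }
  ti <- vapply(pings$metier, row_for, integer(1), USE.NAMES = FALSE)
  pings$is_fishing <- rep(NA, nrow(pings))
  ok <- !is.na(ti)
  if (any(ok)) {
    th <- thresholds[ti[ok], , drop = FALSE]
    fish <- !is.na(pings$speed[ok]) &
      pings$speed[ok] >= th$vmin & pings$speed[ok] <= th$vmax
    dep_rule <- !is.na(th$dmin) | !is.na(th$dmax)
    if (any(dep_rule)) {
      ad <- abs(pings$depth[ok])
      dep_ok <- !is.na(ad) &
        (is.na(th$dmin) | ad >= th$dmin) & (is.na(th$dmax) | ad <= th$dmax)
      fish <- fish & (!dep_rule | dep_ok)
    }
    har_rule <- !is.na(th$min_harbour_km)
    if (any(har_rule)) {
      if (is.null(harbours))
        stop("harbour-distance rule active but no harbours supplied")
      dmat <- vapply(seq_len(nrow(harbours)), function(j)
        gc_dist_km(pings$lon[ok], pings$lat[ok],
                   harbours$lon[j], harbours$lat[j]), numeric(sum(ok)))
      dmin_h <- apply(matrix(dmat, nrow = sum(ok)), 1, min)
      fish <- fish & (!har_rule | dmin_h >= th$min_harbour_km)
    }
    pings$is_fishing[ok] <- fish
  }
  attr(pings, "n_unmarked") <- sum(!ok)
  pings
}

#' Propagate track-level metier labels onto pings
#' @param pings Ping data frame with `track_id`.
#' @param tracks Track summary with a metier column.
#' @param column Which column of `tracks` to use (default `metier_pred`,
#'   falling back to `metier`).
#' @return Pings with `metier` filled.
#' @export
label_pings <- function(pings, tracks, column = NULL) {
  if (is.null(column))
    column <- if ("metier_pred" %in% names(tracks)) "metier_pred" else "metier"
  pings$metier <- tracks[[column]][match(pings$track_id, tracks$track_id)]
  pings
}
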