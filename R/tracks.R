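#' Cut per-vessel ping streams into harbour-to-harbour tracks
#'
#' Walks each vessel's (cleaned, time-sorted) pings and starts a new track
#' after a maximal run of in-harbour pings or after a temporal gap larger than
#' `max_gap_h`. Within a track only the last in-harbour ping of the preceding
#' harbour dwell and the first of the following one are retained, so a track
#' carries at most one in-harbour ping at each end. Tracks with fewer than 3
#' pings are discarded and counted.
#'
#' @param pings Ping data frame after cleaning (in-harbour pings retained).
#' @param max_gap_h Gap threshold in hours (default 12).
#' @return The retained pings with `track_id` assigned (integer, unique across
#'   vessels); attribute `n_short_discarded` counts discarded short tracks.
#' @export
cut_tracks <- function(pings, max_gap_h = 12) {
  stopifnot(max_gap_h > 0)
  pings <- pings[order(pings$vessel_id, pings$timestamp), , drop = FALSE]
  inh <- has_flag(pings, "IN_HARBOUR")
  keep_rows <- integer(0)
  track_of <- integer(0)
  next_id <- 1L
  n_short <- 0L
  for (v in unique(pings$vessel_id)) {
    idx <- which(pings$vessel_id == v)
    h <- inh[idx]
    tt <- as.numeric(pings$timestamp[idx])
    # candidate segments: runs of sea pings, extended by one harbour ping each side
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in seq_along(r$values)) {
      if (r$values[s]) next                       # harbour run, not a track core
      seg <- starts[s]:ends[s]
      if (s > 1L) seg <- c(ends[s - 1L], seg)     # last ping of previous dwell
      if (s < length(r$values)) seg <- c(seg, starts[s + 1L])  # first of next
      # split further on gaps
      gaps <- which(diff(tt[seg]) > max_gap_h * 3600)
      bounds <- c(0L, gaps, length(seg))
      for (b in seq_len(length(bounds) - 1L)) {
        part <- seg[(bounds[b] + 1L):bounds[b + 1L]]
        if (length(part) < 3L) { n_short <- n_short + 1L; next }
        keep_rows <- c(keep_rows, idx[part])
        track_of <- c(track_of, rep(next_id, length(part)))
        next_id <- next_id + 1L
      }
    }
  }
  out <- pings[keep_rows, , drop = FALSE]
  out$track_id <- track_of
  rownames(out) <- NULL
  attr(out, "n_short_discarded") <- n_short
  attr(out, "n_tracks") <- next_id - 1L
  out
}

#' Per-track summary table
#'
#' One row per track with its time span and focal point (the arithmetic mean
#' of the member pings' coordinates, native pings only).
#'
#' @param pings Ping data frame with `track_id` assigned.
#' @return Data frame: track_id, vessel_id, start, end, n_pings, focal_lon,
#'   focal_lat.
#' @export
track_summary <- function(pings) {
  pings <- pings[!is.na(pings$track_id), , drop = FALSE]
  native <- pings[pings$source == "native", , drop = FALSE]
  ids <- sort(unique(native$track_id))
  g <- match(native$track_id, ids)
  data.frame(
    track_id = ids,
    vessel_id = native$vessel_id[match(ids, native$track_id)],
    start = as.POSIXct(as.vector(tapply(as.numeric(native$timestamp), g, min)),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(as.vector(tapply(as.numeric(native$timestamp), g, max)),
                     origin = "1970-01-01", tz = "UTC"),
    n_pings = as.vector(tapply(g, g, length)),
    focal_lon = as.vector(tapply(native$lon, g, mean)),
    focal_lat = as.vector(tapply(native$lat, g, mean)),
    stringsAsFactors = FALSE)
}

#' Infer departure and arrival harbours for each track
#'
#' If an endpoint ping is flagged `IN_HARBOUR` its recorded harbour id is
#' used; otherwise the harbour nearest to the endpoint position is taken.
#'
#' @param pings Ping data frame with `track_id` assigned.
#' @param harbours Point layer of harbours.
#' @return Track summary (see [track_summary()]) with columns
#'   `departure_harbour` and `arrival_harbour` added.
#' @export
infer_harbours <- function(pings, harbours) {
  stopifnot(nrow(harbours) > 0)
  harbours <- harbours[order(as.character(harbours$id)), , drop = FALSE]
  ts <- track_summary(pings)
  nearest_id <- function(lon, lat) {
    d <- gc_dist_km(lon, lat, harbours$lon, harbours$lat)
    as.character(harbours$id)[which.min(d)]
  }
  dep <- arr <- character(nrow(ts))
  inh <- has_flag(pings, "IN_HARBOUR")
  for (i in seq_len(nrow(ts))) {
    rows <- which(pings$track_id == ts$track_id[i] & pings$source == "native")
    rows <- rows[order(pings$timestamp[rows])]
    first <- rows[1]; last <- rows[length(rows)]
    dep[i] <- if (inh[first] && !is.na(pings$harbour_id[first]))
      pings$harbour_id[first] else nearest_id(pings$lon[first], pings$lat[first])
    arr[i] <- if (inh[last] && !is.na(pings$harbour_id[last]))
      pings$harbour_id[last] else nearest_id(pings$lon[last], pings$lat[last])
  }
  ts$departure_harbour <- dep
  ts$arrival_harbour <- arr
  ts
}

# Cubic Hermite evaluation on one segment, normalized parameter u in [0,1].
# p0,p1 values; m0,m1 tangents in value units per second; h segment length (s).
.hermite <- function(u, p0, p1, m0, m1, h) {
  u2 <- u * u; u3 <- u2 * u
  (2 * u3 - 3 * u2 + 1) * p0 + (u3 - 2 * u2 + u) * h * m0 +
    (-2 * u3 + 3 * u2) * p1 + (u3 - u2) * h * m1
}
.hermite_deriv <- function(u, p0, p1, m0, m1, h) {
  u2 <- u * u
  ((6 * u2 - 6 * u) * p0 + (3 * u2 - 4 * u + 1) * h * m0 +
     (-6 * u2 + 6 * u) * p1 + (3 * u2 - 2 * u) * h * m1) / h
}

# Velocity tangents (deg/s) for one track from reported speed and heading,
# per segment, converted at the segment's mean latitude. Falls back to the
# chord slope where speed or heading is unusable.
.track_tangents <- function(lon, lat, tsec, speed, heading) {
  n <- length(lon)
  ok <- !is.na(speed) & speed >= 0 & !is.na(heading) & heading >= 0 & heading < 360
  v_ms <- ifelse(ok, speed * .kn_to_ms, NA_real_)
  vn <- v_ms * cos(heading * pi / 180)   # northward m/s
  ve <- v_ms * sin(heading * pi / 180)   # eastward m/s
  nseg <- n - 1L
  m_lon0 <- m_lat0 <- m_lon1 <- m_lat1 <- numeric(nseg)
  for (s in seq_len(nseg)) {
    mlat <- (lat[s] + lat[s + 1]) / 2
    m_per_deg_lon <- .m_per_deg_lat * cos(mlat * pi / 180)
    h <- tsec[s + 1] - tsec[s]
    chord_lon <- (lon[s + 1] - lon[s]) / h
    chord_lat <- (lat[s + 1] - lat[s]) / h
    if (ok[s]) {
      m_lon0[s] <- ve[s] / m_per_deg_lon; m_lat0[s] <- vn[s] / .m_per_deg_lat
    } else {
      m_lon0[s] <- chord_lon; m_lat0[s] <- chord_lat
    }
    if (ok[s + 1]) {
      m_lon1[s] <- ve[s + 1] / m_per_deg_lon; m_lat1[s] <- vn[s + 1] / .m_per_deg_lat
    } else {
      m_lon1[s] <- chord_lon; m_lat1[s] <- chord_lat
    }
  }
  list(m_lon0 = m_lon0, m_lat0 = m_lat0, m_lon1 = m_lon1, m_lat1 = m_lat1)
}

#' Interpolate tracks onto the shared epoch-anchored time grid
#'
#' For every track the output timestamps are exactly the multiples of
#' `freq_min` minutes since 1970-01-01T00:00Z that fall inside the track's
#' time span, plus the native pings themselves. Because the grid is anchored
#' at the Unix epoch, tracks of different vessels interpolated at the same
#' frequency share their interpolated instants, giving a fleet-wide
#' "snapshot" at any grid time. Positions come from a cubic Hermite spline
#' per coordinate whose endpoint tangents are the velocity vectors implied by
#' the reported speed and heading (`v * (sin h, cos h)`, knots converted to
#' degrees per second at the segment's mean latitude); where speed or heading
#' is unusable the chord slope is used for that tangent. Speed and heading of
#' interpolated pings come from the spline's first derivative. No tuning
#' parameter beyond the frequency is involved.
#'
#' @param pings Ping data frame with `track_id` assigned (native pings).
#' @param freq_min Grid step in minutes.
#' @return Ping data frame containing, per track, the union of native and
#'   interpolated pings in time order, `source` distinguishing the two.
#'   Tracks with fewer than two native pings are skipped with a warning.
#' @export
interpolate_tracks <- function(pings, freq_min) {
  stopifnot(freq_min > 0)
  pings <- pings[!is.na(pings$track_id), , drop = FALSE]
  step <- freq_min * 60
  out <- vector("list", length(unique(pings$track_id)))
  k <- 0L
  skipped <- 0L
  for (tid in sort(unique(pings$track_id))) {
    tr <- pings[pings$track_id == tid & pings$source == "native", , drop = FALSE]
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (nrow(tr) < 2L) { skipped <- skipped + 1L; next }
    tsec <- as.numeric(tr$timestamp)
    grid <- seq(ceiling(tsec[1] / step) * step,
                floor(tsec[nrow(tr)] / step) * step, by = step)
    grid <- grid[grid >= tsec[1] & grid <= tsec[nrow(tr)]]
    newt <- setdiff(grid, tsec)
    tan <- .track_tangents(tr$lon, tr$lat, tsec, tr$speed, tr$heading)
    if (length(newt)) {
      seg <- findInterval(newt, tsec, rightmost.closed = TRUE)
      h <- tsec[seg + 1] - tsec[seg]
      u <- (newt - tsec[seg]) / h
      ilon <- .hermite(u, tr$lon[seg], tr$lon[seg + 1],
                       tan$m_lon0[seg], tan$m_lon1[seg], h)
      ilat <- .hermite(u, tr$lat[seg], tr$lat[seg + 1],
                       tan$m_lat0[seg], tan$m_lat1[seg], h)
      dlon <- .hermite_deriv(u, tr$lon[seg], tr$lon[seg + 1],
                             tan$m_lon0[seg], tan$m_lon1[seg], h)
      dlat <- .hermite_deriv(u, tr$lat[seg], tr$lat[seg + 1],
                             tan$m_lat0[seg], tan$m_lat1[seg], h)
      ve <- dlon * .m_per_deg_lat * cos(ilat * pi / 180)
      vn <- dlat * .m_per_deg_lat
      ispeed <- sqrt(ve^2 + vn^2) / .kn_to_ms
      iheading <- (atan2(ve, vn) * 180 / pi + 360) %% 360
      add <- tr[rep(1L, length(newt)), , drop = FALSE]
      add$timestamp <- as.POSIXct(newt, origin = "1970-01-01", tz = "UTC")
      add$lon <- ilon; add$lat <- ilat
      add$speed <- ispeed; add$heading <- iheading
      add$flags <- ""
      add$source <- "interpolated"
      add$harbour_id <- NA_character_
      add$depth <- NA_real_
      add$is_fishing <- NA
      if ("ping_id" %in% names(add)) add$ping_id <- NA_integer_
      tr <- rbind(tr, add)
    }
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    k <- k + 1L
    out[[k]] <- tr
  }
  if (skipped) warning(skipped, " track(s) too short to interpolate; skipped")
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
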