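#' Flag duplicate pings
#'
#' A duplicate group is all pings sharing (vessel_id, timestamp): two
#' positions reported at one instant are physically impossible, so position is
#' not required to match. All but the first occurrence of each group receive
#' the `DUPLICATE` code. Idempotent.
#'
#' @param pings Ping data frame sorted by (vessel, timestamp).
#' @return Pings with flags updated.
#' @export
flag_duplicates <- function(pings) {
  key <- paste(pings$vessel_id, as.numeric(pings$timestamp), sep = "\r")
  pings$flags <- add_flag(pings$flags, "DUPLICATE", duplicated(key))
  pings
}

#' Flag pings positioned on land
#'
#' Points strictly inside any coastline polygon are flagged `ON_LAND`;
#' boundary points are not flagged.
#'
#' @param pings Ping data frame.
#' @param coastline Polygon layer (data frame id/lon/lat, see
#'   [read_polygons_layer()]).
#' @return Pings with flags updated.
#' @export
flag_on_land <- function(pings, coastline) {
  hit <- locate_in_polygons(pings$lon, pings$lat, coastline, boundary = "exclude")
  pings$flags <- add_flag(pings$flags, "ON_LAND", !is.na(hit))
  pings
}

#' Flag unreasonable speed and heading values
#'
#' `BAD_SPEED` when speed is negative, missing, or above `max_speed`
#' (inclusive boundary: a speed exactly at `max_speed` is clean).
#' `BAD_HEADING` when heading is missing or outside the half-open compass
#' range `[0, 360)`.
#'
#' @param pings Ping data frame.
#' @param max_speed Ceiling in knots (default 25).
#' @return Pings with flags updated.
#' @export
flag_speed_heading <- function(pings, max_speed = 25) {
  stopifnot(max_speed > 0)
  bad_sp <- is.na(pings$speed) | pings$speed < 0 | pings$speed > max_speed
  bad_hd <- is.na(pings$heading) | pings$heading < 0 | pings$heading >= 360
  pings$flags <- add_flag(pings$flags, "BAD_SPEED", bad_sp)
  pings$flags <- add_flag(pings$flags, "BAD_HEADING", bad_hd)
  pings
}

#' Flag kinematically incoherent pings
#'
#' Walks each vessel's pings in time order and flags `NOT_COHERENT` any ping
#' whose great-circle implied speed from the previous retained ping strictly
#' exceeds `ceiling_kn` (a ping exactly at the ceiling is clean). Flagged and
#' duplicate pings are not used as reference points, so one bad fix does not
#' cascade. Intended to run after [flag_duplicates()].
#'
#' @param pings Ping data frame, time-sorted per vessel.
#' @param ceiling_kn Physical speed ceiling in knots (default 30).
#' @return Pings with flags updated.
#' @export
flag_not_coherent <- function(pings, ceiling_kn = 30) {
  stopifnot(ceiling_kn > 0)
  pings$flags <- sub("(^|,)NOT_COHERENT(,|$)", "\\1\\2", pings$flags)  # recompute
  pings$flags <- gsub("(^,)|(,$)", "", gsub(",,", ",", pings$flags))
  dup <- has_flag(pings, "DUPLICATE")
  flag <- logical(nrow(pings))
  for (v in unique(pings$vessel_id)) {
    idx <- which(pings$vessel_id == v & !dup)
    if (length(idx) < 2L) next
    prev <- idx[1]
    for (i in idx[-1]) {
      dt_h <- as.numeric(difftime(pings$timestamp[i], pings$timestamp[prev],
                                  units = "hours"))
      if (dt_h <= 0) next
      d_km <- gc_dist_km(pings$lon[prev], pings$lat[prev],
                         pings$lon[i], pings$lat[i])
      if (d_km / dt_h / 1.852 > ceiling_kn + 1e-9) flag[i] <- TRUE else prev <- i
    }
  }
  pings$flags <- add_flag(pings$flags, "NOT_COHERENT", flag)
  pings
}

#' Flag pings inside harbour buffers
#'
#' A ping within `radius_km` (inclusive) great-circle distance of any harbour
#' is flagged `IN_HARBOUR` and annotated with the nearest such harbour's id;
#' equidistant ties are broken lexicographically by harbour id.
#'
#' @param pings Ping data frame.
#' @param harbours Point layer (data frame id/name/lon/lat).
#' @param radius_km Buffer radius in km (default 2, the conventional harbour
#'   buffer).
#' @return Pings with flags and `harbour_id` updated.
#' @export
flag_in_harbour <- function(pings, harbours, radius_km = 2) {
  stopifnot(radius_km > 0)
  if (is.null(harbours) || nrow(harbours) == 0L) stop("empty harbour list")
  harbours <- harbours[order(as.character(harbours$id)), , drop = FALSE]
  dmat <- vapply(seq_len(nrow(harbours)), function(j)
    gc_dist_km(pings$lon, pings$lat, harbours$lon[j], harbours$lat[j]),
    numeric(nrow(pings)))
  dmat <- matrix(dmat, nrow = nrow(pings))
  nearest <- max.col(-dmat, ties.method = "first")  # lowest id on ties (sorted)
  dist_min <- dmat[cbind(seq_len(nrow(pings)), nearest)]
  inside <- dist_min <= radius_km
  pings$flags <- add_flag(pings$flags, "IN_HARBOUR", inside)
  pings$harbour_id[inside] <- as.character(harbours$id)[nearest[inside]]
  pings
}

#' Default flag retention policy
#'
#' Drops `DUPLICATE`, `ON_LAND`, `NOT_COHERENT` and `OUT_OF_RANGE` pings and
#' keeps everything else; `IN_HARBOUR` pings are kept because track cutting
#' needs them.
#'
#' @return Named logical vector over [warning_codes()], `TRUE` = keep.
#' @export
default_flag_policy <- function() {
  keep <- stats::setNames(rep(TRUE, length(warning_codes())), warning_codes())
  keep[c("DUPLICATE", "ON_LAND", "NOT_COHERENT", "OUT_OF_RANGE")] <- FALSE
  keep
}

#' Apply a per-code retention policy
#'
#' A ping is dropped when it carries at least one code whose policy entry is
#' `FALSE` (OR semantics over its codes). Flagging itself never deletes data;
#' this is the single place where removal happens.
#'
#' @param pings Ping data frame.
#' @param policy Named logical vector (code -> keep), e.g.
#'   [default_flag_policy()].
#' @return Filtered pings; attribute `dropped` holds the per-code drop tally.
#' @export
apply_policy <- function(pings, policy = default_flag_policy()) {
  present <- warning_codes()[colSums(vapply(warning_codes(),
    function(cd) has_flag(pings, cd), logical(nrow(pings)))) > 0]
  missing <- setdiff(present, names(policy))
  if (length(missing))
    stop("policy does not cover code(s): ", paste(missing, collapse = ", "))
  drop_codes <- names(policy)[!policy]
  drop <- logical(nrow(pings))
  tally <- stats::setNames(integer(length(drop_codes)), drop_codes)
  for (cd in drop_codes) {
    hit <- has_flag(pings, cd)
    tally[cd] <- sum(hit)
    drop <- drop | hit
  }
  out <- pings[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- tally
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Run the full cleaning pass
#'
#' Convenience wrapper: duplicates, speed/heading checks, optional on-land
#' test, harbour buffers, then the coherence check (which by design runs after
#' duplicate flagging). Prints a per-code tally when `verbose`.
#'
#' @param pings Ping data frame sorted by (vessel, timestamp).
#' @param harbours Point layer of harbours.
#' @param coastline Optional polygon layer for the on-land test.
#' @param max_speed,ceiling_kn,radius_km Thresholds, see the individual
#'   flagging functions.
#' @param verbose Print the tally.
#' @return Flagged pings (nothing dropped; use [apply_policy()]).
#' @export
clean_pings <- function(pings, harbours, coastline = NULL,
                        max_speed = 25, ceiling_kn = 30, radius_km = 2,
                        verbose = FALSE) {
  pings <- flag_duplicates(pings)
  pings <- flag_speed_heading(pings, max_speed)
  if (!is.null(coastline)) pings <- flag_on_land(pings, coastline)
  pings <- flag_in_harbour(pings, harbours, radius_km)
  pings <- flag_not_coherent(pings, ceiling_kn)
  if (verbose) {
    tally <- flag_counts(pings)
    n <- nrow(pings)
    for (cd in names(tally))
      message(sprintf("Found %d (%.2f%% of total) %s pings",
                      tally[cd], 100 * tally[cd] / max(n, 1), tolower(cd)))
  }
  pings
}
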