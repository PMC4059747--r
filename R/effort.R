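#' Spherical area of a graticule cell
#'
#' Closed form `R^2 * dlambda * |sin(phi2) - sin(phi1)|` on the sphere of
#' radius 6371.0088 km.
#'
#' @param lon_min,lon_max,lat_min,lat_max Cell bounds in decimal degrees
#'   (vectorised).
#' @return Area in km^2.
#' @export
cell_area_km2 <- function(lon_min, lon_max, lat_min, lat_max) {
  r <- 6371.0088
  r^2 * (lon_max - lon_min) * pi / 180 *
    abs(sin(lat_max * pi / 180) - sin(lat_min * pi / 180))
}

#' Build a regular effort grid
#'
#' Rectangular lon/lat grid of square cells of `cell_deg` degrees, cells
#' numbered row-major from the south-west corner (id 1 = SW cell).
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid extent in decimal degrees.
#' @param cell_deg Cell size in degrees.
#' @return Object of class `effort_grid`: a list with a `cells` data frame
#'   (id, lon_min, lon_max, lat_min, lat_max, area_km2, count, effort_h),
#'   the extent, the cell size and the interpolation interval (initially
#'   `NA`).
#' @export
make_effort_grid <- function(lon_min, lon_max, lat_min, lat_max, cell_deg) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, cell_deg > 0)
  nx <- ceiling((lon_max - lon_min) / cell_deg - 1e-9)
  ny <- ceiling((lat_max - lat_min) / cell_deg - 1e-9)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  cells <- data.frame(
    id = seq_len(nx * ny),
    lon_min = lon_min + (ix - 1) * cell_deg,
    lon_max = lon_min + ix * cell_deg,
    lat_min = lat_min + (iy - 1) * cell_deg,
    lat_max = lat_min + iy * cell_deg)
  cells$area_km2 <- cell_area_km2(cells$lon_min, cells$lon_max,
                                  cells$lat_min, cells$lat_max)
  cells$count <- 0L
  cells$effort_h <- 0
  structure(list(cells = cells, nx = nx, ny = ny,
                 lon_min = lon_min, lat_min = lat_min, cell_deg = cell_deg,
                 interval_min = NA_real_, n_outside = 0L),
            class = "effort_grid")
}

#' @export
print.effort_grid <- function(x, ...) {
  cat("effort grid:", x$nx, "x", x$ny, "cells of", x$cell_deg, "deg;",
      sum(x$cells$count), "fishing positions,",
      sum(x$cells$effort_h), "effort hours\n")
  invisible(x)
}

#' Accumulate fishing positions onto a grid
#'
#' Counts the fishing-marked pings per cell and converts counts to effort
#' hours as `count * interval_min / 60` (each interpolated fishing position
#' stands for one interpolation interval of fishing activity). Points
#' exactly on a shared cell boundary go to the lowest-id adjacent cell;
#' points outside the extent are counted in `n_outside`, so
#' `sum(counts) + n_outside` equals the number of fishing pings.
#'
#' @param pings Ping data frame with `is_fishing` set (only `TRUE` rows
#'   count).
#' @param grid An [make_effort_grid()] grid.
#' @param interval_min Interpolation interval in minutes backing the
#'   hours conversion.
#' @return The grid with counts and effort hours filled.
#' @export
grid_effort <- function(pings, grid, interval_min = 10) {
  stopifnot(inherits(grid, "effort_grid"), interval_min > 0)
  p <- pings[!is.na(pings$is_fishing) & pings$is_fishing, , drop = FALSE]
  # boundary points belong to the lower-index (hence lowest-id) cell
  ix <- ceiling((p$lon - grid$lon_min) / grid$cell_deg - 1e-12)
  iy <- ceiling((p$lat - grid$lat_min) / grid$cell_deg - 1e-12)
  ix[p$lon == grid$lon_min] <- 1L
  iy[p$lat == grid$lat_min] <- 1L
  inside <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
  id <- (iy[inside] - 1L) * grid$nx + ix[inside]
  tab <- tabulate(id, nbins = grid$nx * grid$ny)
  grid$cells$count <- as.integer(tab)
  grid$cells$effort_h <- tab * interval_min / 60
  grid$interval_min <- interval_min
  grid$n_outside <- sum(!inside)
  grid
}

#' DCF pressure indicator 5: distribution of fishing activities
#'
#' Total area (km^2) of the grid cells in which any fishing effort is
#' allocated (count > 0).
#'
#' @param grid A populated [grid_effort()] grid.
#' @return Area in km^2.
#' @export
dcf_indicator5 <- function(grid) {
  stopifnot(inherits(grid, "effort_grid"))
  sum(grid$cells$area_km2[grid$cells$count > 0])
}

#' DCF pressure indicator 6: aggregation of fishing activities
#'
#' Total area (km^2) of the smallest set of cells accumulating at least a
#' fraction `q` (default 90%) of the total fishing effort: cells are sorted
#' by decreasing effort (ties by cell id) and accumulated until the target is
#' reached, the crossing cell included.
#'
#' @param grid A populated [grid_effort()] grid.
#' @param q Effort fraction in (0, 1].
#' @return Area in km^2; always `<= dcf_indicator5(grid)` and equal to it at
#'   `q = 1`.
#' @export
dcf_indicator6 <- function(grid, q = 0.9) {
  stopifnot(inherits(grid, "effort_grid"), q > 0, q <= 1)
  eff <- grid$cells$effort_h
  total <- sum(eff)
  if (total <= 0) stop("zero total effort: indicator 6 undefined")
  o <- order(-eff, grid$cells$id)
  o <- o[eff[o] > 0]
  cum <- cumsum(eff[o])
  n_in <- which(cum >= q * total - 1e-12)[1]
  sum(grid$cells$area_km2[o[seq_len(n_in)]])
}

#' Trawled area of a track
#'
#' Sums, over the consecutive ping pairs of each track in which both pings
#' are fishing positions, the great-circle segment length multiplied by the
#' vessel's overall gear width (OWG, km) evaluated at the segment's mean
#' depth. The gear table gives OWG per vessel as
#' `owg = owg_km + owg_per_m * |depth_m|` (set `owg_per_m` to 0 for a
#' constant width). Tracks of vessels without a gear row are skipped and
#' counted.
#'
#' @param pings Ping data frame with `track_id` and `is_fishing` set.
#' @param gear Data frame with columns `vessel_id`, `owg_km` and optionally
#'   `owg_per_m`.
#' @return Data frame (track_id, vessel_id, trawled_km2); attribute
#'   `n_skipped` counts tracks without gear data.
#' @export
trawled_area <- function(pings, gear) {
  stopifnot(all(c("vessel_id", "owg_km") %in% names(gear)))
  if (is.null(gear$owg_per_m)) gear$owg_per_m <- 0
  pings <- pings[!is.na(pings$track_id), , drop = FALSE]
  ids <- sort(unique(pings$track_id))
  out <- data.frame(track_id = ids, vessel_id = NA_character_,
                    trawled_km2 = NA_real_, stringsAsFactors = FALSE)
  skipped <- 0L
  for (i in seq_along(ids)) {
    p <- pings[pings$track_id == ids[i], , drop = FALSE]
    p <- p[order(p$timestamp), , drop = FALSE]
    out$vessel_id[i] <- p$vessel_id[1]
    g <- gear[gear$vessel_id == p$vessel_id[1], , drop = FALSE]
    if (!nrow(g)) { skipped <- skipped + 1L; next }
    fish <- !is.na(p$is_fishing) & p$is_fishing
    seg <- which(fish[-nrow(p)] & fish[-1])
    if (!length(seg)) { out$trawled_km2[i] <- 0; next }
    len <- gc_dist_km(p$lon[seg], p$lat[seg], p$lon[seg + 1], p$lat[seg + 1])
    mdep <- abs((ifelse(is.na(p$depth[seg]), 0, p$depth[seg]) +
                   ifelse(is.na(p$depth[seg + 1]), 0, p$depth[seg + 1])) / 2)
    owg <- g$owg_km[1] + g$owg_per_m[1] * mdep
    out$trawled_km2[i] <- sum(len * owg)
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Export / re-import an effort grid as CSV
#'
#' Writes one row per cell: id, bounds, area, count, effort hours, plus any
#' user-supplied per-cell attribute columns. An attribute column whose name
#' collides with a standard field is renamed with the suffix `_1`. Counts
#' round-trip bit-exactly and floating-point fields to full printed
#' precision.
#'
#' @param grid An `effort_grid`.
#' @param path File path.
#' @param extra Optional data frame of per-cell attributes (same row order
#'   as the cells).
#' @return `read_effort_csv` returns the cells data frame.
#' @export
export_effort_csv <- function(grid, path, extra = NULL) {
  stopifnot(inherits(grid, "effort_grid"))
  cells <- grid$cells
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(cells))
    clash <- names(extra) %in% names(cells)
    names(extra)[clash] <- paste0(names(extra)[clash], "_1")
    cells <- cbind(cells, extra)
  }
  num <- vapply(cells, is.double, logical(1))
  cells[num] <- lapply(cells[num], function(v) sprintf("%.12g", v))
  utils::write.table(cells, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_effort_csv
#' @export
read_effort_csv <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Split pings by calendar month
#'
#' Helper for monthly stratification of the pressure indicators.
#'
#' @param pings Ping data frame.
#' @return Named list of ping data frames, one per `YYYY-MM` stratum.
#' @export
split_by_month <- function(pings) {
  split(pings, format(pings$timestamp, "%Y-%m", tz = "UTC"))
}
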