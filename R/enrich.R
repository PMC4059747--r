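#' Bathymetry grid constructor
#'
#' @param lon,lat Strictly increasing regular axes (decimal degrees).
#' @param z Elevation matrix in metres (negative below sea level), dimensions
#'   `length(lat)` x `length(lon)` (rows = latitudes).
#' @return Object of class `bathy_grid`.
#' @export
bathy_grid <- function(lon, lat, z) {
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0),
            nrow(z) == length(lat), ncol(z) == length(lon))
  structure(list(lon = lon, lat = lat, z = z), class = "bathy_grid")
}

#' Read bathymetry from lon,lat,z delimited text
#'
#' Accepts any file of `lon,lat,z` triples sampling a full regular grid.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A [bathy_grid()].
#' @export
read_bathy_xyz <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("lon", "lat", "z") %in% names(d)))
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  if (nrow(d) != length(lon) * length(lat))
    stop("xyz file does not sample a full regular grid")
  z <- matrix(NA_real_, length(lat), length(lon))
  z[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$z
  bathy_grid(lon, lat, z)
}

#' Read bathymetry from an ESRI ASCII raster
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by the value matrix
#' (first data row = northernmost). Cell-centre registration is assumed.
#'
#' @param path File path.
#' @return A [bathy_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  z <- z[rev(seq_len(hdr$nrows)), , drop = FALSE]  # south-up for ascending lat
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + cs / 2 + cs * (seq_len(hdr$ncols) - 1)
  lat <- hdr$yllcorner + cs / 2 + cs * (seq_len(hdr$nrows) - 1)
  bathy_grid(lon, lat, z)
}

#' Write a bathymetry grid as lon,lat,z text
#' @param grid A [bathy_grid()].
#' @param path File path.
#' @param sep Field separator.
#' @export
write_bathy_xyz <- function(grid, path, sep = ",") {
  d <- expand.grid(lat = grid$lat, lon = grid$lon)
  d$z <- as.vector(grid$z)
  utils::write.table(d[c("lon", "lat", "z")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign sea-bottom depth to pings by bilinear interpolation
#'
#' Depth at each ping is the bilinear interpolation of the four surrounding
#' grid nodes (exact for any plane sampled on the grid). Pings outside the
#' grid's bounding box get `NA` and are counted.
#'
#' @param pings Ping data frame.
#' @param grid A [bathy_grid()].
#' @return Pings with `depth` filled (metres, negative below sea level);
#'   attribute `n_outside_grid` counts pings outside the grid.
#' @export
assign_depth <- function(pings, grid) {
  stopifnot(inherits(grid, "bathy_grid"))
  inside <- pings$lon >= grid$lon[1] & pings$lon <= grid$lon[length(grid$lon)] &
    pings$lat >= grid$lat[1] & pings$lat <= grid$lat[length(grid$lat)]
  depth <- rep(NA_real_, nrow(pings))
  if (any(inside))
    depth[inside] <- pracma::interp2(grid$lon, grid$lat, grid$z,
                                     pings$lon[inside], pings$lat[inside],
                                     method = "linear")
  pings$depth <- depth
  attr(pings, "n_outside_grid") <- sum(!inside)
  pings
}

#' Assign tracks to management areas via their focal point
#'
#' The focal point (mean coordinates of the track's native pings) is tested
#' against the area polygons; a track is assigned to the polygon containing
#' it, boundary included. With overlapping polygons the first id in
#' increasing order wins and a warning is issued. Because only the focal
#' point matters, the result is invariant to ping order and interpolation
#' frequency.
#'
#' @param tracks Track summary from [track_summary()] / [infer_harbours()].
#' @param areas Polygon layer (data frame id/lon/lat).
#' @return Tracks with an `area` column (`NA` when the focal point is in no
#'   polygon); attribute `n_unassigned`.
#' @export
assign_area <- function(tracks, areas) {
  validate_polygons(areas)
  ids <- sort(unique(as.character(areas$id)))
  hits <- matrix(FALSE, nrow(tracks), length(ids))
  for (j in seq_along(ids)) {
    ring <- areas[as.character(areas$id) == ids[j], ]
    hits[, j] <- sp::point.in.polygon(tracks$focal_lon, tracks$focal_lat,
                                      ring$lon, ring$lat) >= 1L
  }
  if (any(rowSums(hits) > 1L))
    warning("focal point(s) inside overlapping polygons; first id used")
  area <- rep(NA_character_, nrow(tracks))
  any_hit <- rowSums(hits) > 0L
  area[any_hit] <- ids[apply(hits[any_hit, , drop = FALSE], 1, which.max)]
  tracks$area <- area
  attr(tracks, "n_unassigned") <- sum(!any_hit)
  tracks
}
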