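#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean Earth
#' radius). All arguments are recycled to a common length.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' gc_dist_km(0, 0, 1, 0)  # one degree of longitude at the equator
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371.0088))
}

# Metres of arc per degree of latitude on the reference sphere.
.m_per_deg_lat <- 6371008.8 * pi / 180
.kn_to_ms <- 1852 / 3600

#' Initial bearing between points
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in degrees in `[0, 360)`.
#' @keywords internal
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  b <- geosphere::bearing(cbind(rep_len(lon1, n), rep_len(lat1, n)),
                          cbind(rep_len(lon2, n), rep_len(lat2, n)))
  (b + 360) %% 360
}

#' Test points against a polygon layer
#'
#' @param lon,lat Point coordinates.
#' @param polys Polygon layer: a data frame with columns `id`, `lon`, `lat`
#'   where consecutive rows sharing an `id` form one closed ring (the closing
#'   edge is implicit).
#' @param boundary One of `"exclude"` (strict interior only, the default) or
#'   `"include"` (boundary points count as inside).
#' @return Character vector: the id of the first polygon (in increasing id
#'   order) containing each point, or `NA` if none.
#' @export
locate_in_polygons <- function(lon, lat, polys, boundary = c("exclude", "include")) {
  boundary <- match.arg(boundary)
  validate_polygons(polys)
  out <- rep(NA_character_, length(lon))
  for (id in sort(unique(as.character(polys$id)))) {
    ring <- polys[as.character(polys$id) == id, , drop = FALSE]
    hit <- sp::point.in.polygon(lon, lat, ring$lon, ring$lat)
    inside <- if (boundary == "exclude") hit == 1L else hit >= 1L
    out[is.na(out) & inside] <- id
  }
  out
}

#' @keywords internal
validate_polygons <- function(polys) {
  stopifnot(is.data.frame(polys), all(c("id", "lon", "lat") %in% names(polys)))
  for (id in unique(polys$id)) {
    ring <- polys[polys$id == id, ]
    if (nrow(ring) < 3L)
      stop("polygon '", id, "' has fewer than 3 vertices")
    if (anyNA(ring$lon) || anyNA(ring$lat))
      stop("polygon '", id, "' has missing coordinates")
  }
  invisible(polys)
}

#' Parse coordinates in degrees-minutes-seconds notation
#'
#' Accepts strings such as `"41°54'10\"N"`, `"41 54 10 N"` or `"41d54m10sE"`;
#' the hemisphere letter (N/S/E/W) fixes the sign. Decimal minutes/seconds are
#' allowed and trailing components may be omitted.
#'
#' @param x Character vector.
#' @return Numeric decimal degrees (`NA` where unparseable).
#' @export
#' @examples
#' parse_dms("41°54′10″N")  # 41.9028
parse_dms <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  hem <- toupper(sub(".*?([NSEWnsew])\\s*$", "\\1", x))
  hem[!hem %in% c("N", "S", "E", "W")] <- NA
  for (i in seq_along(x)) {
    nums <- regmatches(x[i], gregexpr("[0-9]+(\\.[0-9]+)?", x[i]))[[1]]
    if (length(nums) < 1L || length(nums) > 3L) next
    v <- as.numeric(nums)
    dd <- v[1] + (if (length(v) >= 2) v[2] / 60 else 0) +
      (if (length(v) >= 3) v[3] / 3600 else 0)
    if (!is.na(hem[i]) && hem[i] %in% c("S", "W")) dd <- -dd
    out[i] <- dd
  }
  out
}

#' Read a point layer (e.g. harbours) from delimited text
#'
#' Expected columns: `id`, `name` (optional), `lon`, `lat`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame with columns id, name, lon, lat.
#' @export
read_points_layer <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "lon", "lat") %in% names(d)))
  if (is.null(d$name)) d$name <- as.character(d$id)
  d$id <- as.character(d$id)
  if (anyDuplicated(d$id)) stop("duplicate ids in point layer")
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180))
    stop("point layer coordinates out of range")
  d[c("id", "name", "lon", "lat")]
}

#' Read a polygon layer from delimited text
#'
#' One vertex per row, columns `id`, `lon`, `lat`; rows with the same `id`
#' form one ring in order.
#'
#' @inheritParams read_points_layer
#' @return Data frame with columns id, lon, lat.
#' @export
read_polygons_layer <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "lon", "lat") %in% names(d)))
  d$id <- as.character(d$id)
  validate_polygons(d)
  d[c("id", "lon", "lat")]
}

#' Write point / polygon layers
#' @param layer Data frame as returned by the corresponding reader.
#' @param path File path.
#' @param sep Field separator.
#' @export
write_layer <- function(layer, path, sep = ",") {
  utils::write.table(layer, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
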