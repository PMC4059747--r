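# Shared fixture builders; everything is generated in code.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Quick ping frame from parallel vectors.
mk_pings <- function(vessel = "V1", t, lon, lat, speed = 5, heading = 90) {
  n <- max(length(t), length(lon), length(lat))
  as_vms_pings(data.frame(
    vessel_id = rep_len(vessel, n),
    timestamp = if (inherits(t, "POSIXct")) rep_len(t, n)
                else utc("2012-06-01") + rep_len(t, n),
    lon = rep_len(lon, n), lat = rep_len(lat, n),
    speed = rep_len(speed, n), heading = rep_len(heading, n),
    stringsAsFactors = FALSE))
}

# Default VMS loader config matching write_vms_csv() below.
vms_cfg <- function(sep = ",", coord_format = "decimal") {
  loader_config(c(vessel_id = "vessel", timestamp = "timestamp",
                  lon = "lon", lat = "lat", speed = "speed",
                  heading = "heading"),
                sep = sep, datetime_format = "%Y-%m-%d %H:%M:%S",
                coord_format = coord_format)
}

write_vms_csv <- function(rows, path, sep = ",") {
  header <- paste(c("vessel", "timestamp", "lon", "lat", "speed", "heading"),
                  collapse = sep)
  writeLines(c(header, vapply(rows, paste, "", collapse = sep)), path)
  path
}

lb_cfg <- function(sep = ",") {
  loader_config(c(vessel_id = "vessel", departure = "departure",
                  arrival = "arrival", species = "species",
                  quantity = "quantity"),
                sep = sep, datetime_format = "%Y-%m-%d %H:%M:%S")
}

write_lb_csv <- function(rows, path, sep = ",") {
  header <- paste(c("vessel", "departure", "arrival", "species", "quantity"),
                  collapse = sep)
  writeLines(c(header, vapply(rows, paste, "", collapse = sep)), path)
  path
}

# Dirichlet profile sampler used by the metier tests.
rdirichlet_profiles <- function(n, alpha, total = 100) {
  t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(alpha), shape = alpha)
    total * g / sum(g)
  }, numeric(length(alpha))))
}

# Exhaustive k-medoids oracle (global optimum cost).
exhaustive_kmedoids_cost <- function(dmat, k) {
  combs <- utils::combn(nrow(dmat), k)
  min(apply(combs, 2, function(m)
    sum(apply(dmat[, m, drop = FALSE], 1, min))))
}
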