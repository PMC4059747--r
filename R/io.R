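#' Loader configuration for delimited VMS / logbook files
#'
#' A loader config maps canonical field names onto source column names and
#' records the separator, datetime format and coordinate notation of a file
#' dialect. A timestamp field may be split across several source columns; map
#' it as a space-separated list of column names (e.g. `"SI_DATE SI_TIME"`).
#'
#' Canonical VMS fields: `vessel_id`, `timestamp`, `lon`, `lat`, `speed`
#' (knots), `heading` (degrees). Canonical logbook fields: `vessel_id`,
#' `departure`, `arrival`, `species` (FAO 3-alpha code), `quantity` (kg), plus
#' optional `gear` and `metier`.
#'
#' @param fields Named character vector, canonical field -> source column.
#' @param sep Field separator: `","`, `";"` or `"\t"`.
#' @param datetime_format A [strptime()] format for the (joined) timestamp
#'   columns.
#' @param coord_format `"decimal"` for decimal degrees or `"dms"` for
#'   degrees-minutes-seconds strings with hemisphere letters.
#' @param dialect Preset name: `"custom"`, `"TACSAT2"` or `"EFLALO"`.
#' @return An object of class `loader_config`.
#' @export
#' @examples
#' cfg <- loader_config(c(vessel_id = "vessel", timestamp = "time",
#'                        lon = "lon", lat = "lat",
#'                        speed = "speed", heading = "heading"))
loader_config <- function(fields,
                          sep = ",",
                          datetime_format = "%Y-%m-%d %H:%M:%S",
                          coord_format = c("decimal", "dms"),
                          dialect = "custom") {
  coord_format <- match.arg(coord_format)
  if (!sep %in% c(",", ";", "\t")) stop("sep must be comma, semicolon or tab")
  stopifnot(is.character(fields), !is.null(names(fields)), all(names(fields) != ""))
  structure(list(fields = fields, sep = sep,
                 datetime_format = datetime_format,
                 coord_format = coord_format, dialect = dialect),
            class = "loader_config")
}

#' Preset loader configurations
#'
#' `TACSAT2` and `EFLALO` presets are pure column-name mappings onto the ICES
#' community formats (no semantic validation beyond the canonical checks).
#'
#' @param dialect `"TACSAT2"` (VMS) or `"EFLALO"` (logbook).
#' @return A [loader_config()].
#' @export
loader_preset <- function(dialect = c("TACSAT2", "EFLALO")) {
  dialect <- match.arg(dialect)
  if (dialect == "TACSAT2") {
    loader_config(c(vessel_id = "VE_REF", timestamp = "SI_DATE SI_TIME",
                    lon = "SI_LONG", lat = "SI_LATI",
                    speed = "SI_SP", heading = "SI_HE"),
                  sep = ",", datetime_format = "%d/%m/%Y %H:%M",
                  dialect = "TACSAT2")
  } else {
    loader_config(c(vessel_id = "VE_REF",
                    departure = "FT_DDAT FT_DTIME", arrival = "FT_LDAT FT_LTIME",
                    species = "LE_SPE", quantity = "LE_KG", gear = "LE_GEAR"),
                  sep = ",", datetime_format = "%d/%m/%Y %H:%M",
                  dialect = "EFLALO")
  }
}

#' Save / load a loader config as a flat key-value text file
#' @param config A [loader_config()].
#' @param path File path.
#' @return `read_loader_config` returns a `loader_config`; saving returns the
#'   path invisibly. Configs round-trip unchanged.
#' @export
save_loader_config <- function(config, path) {
  stopifnot(inherits(config, "loader_config"))
  sep_name <- c("," = "comma", ";" = "semicolon", "\t" = "tab")[[config$sep]]
  lines <- c(paste0("sep=", sep_name),
             paste0("datetime_format=", config$datetime_format),
             paste0("coord_format=", config$coord_format),
             paste0("dialect=", config$dialect),
             paste0("field.", names(config$fields), "=", config$fields))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_loader_config
#' @export
read_loader_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  fld <- startsWith(keys, "field.")
  fields <- stats::setNames(vals[fld], sub("^field\\.", "", keys[fld]))
  sep <- c(comma = ",", semicolon = ";", tab = "\t")[[vals[keys == "sep"]]]
  loader_config(fields, sep = sep,
                datetime_format = vals[keys == "datetime_format"],
                coord_format = vals[keys == "coord_format"],
                dialect = vals[keys == "dialect"])
}

# Paste together the source columns mapped to one canonical field.
.joined_column <- function(raw, spec) {
  cols <- strsplit(spec, "[ +]+")[[1]]
  missing <- setdiff(cols, names(raw))
  if (length(missing))
    stop("mapped column(s) not present in file: ", paste(missing, collapse = ", "))
  if (length(cols) == 1L) as.character(raw[[cols]])
  else do.call(paste, lapply(cols, function(cn) as.character(raw[[cn]])))
}

.parse_utc <- function(x, fmt) {
  as.POSIXct(x, format = fmt, tz = "UTC")
}

#' Canonical VMS ping data frame
#'
#' Ensures the canonical ping columns exist with the right types; extra
#' columns are preserved untouched.
#'
#' @param df Data frame with at least vessel_id, timestamp, lon, lat, speed,
#'   heading.
#' @return Data frame with canonical columns
#'   (vessel_id, timestamp, lon, lat, speed, heading, flags, source, track_id,
#'   harbour_id, depth, metier, is_fishing) first.
#' @export
as_vms_pings <- function(df) {
  need <- c("vessel_id", "timestamp", "lon", "lat", "speed", "heading")
  stopifnot(all(need %in% names(df)))
  n <- nrow(df)
  defaults <- list(flags = "", source = "native", track_id = NA_integer_,
                   harbour_id = NA_character_, depth = NA_real_,
                   metier = NA_character_, is_fishing = NA)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], n)
  df$vessel_id <- as.character(df$vessel_id)
  stopifnot(inherits(df$timestamp, "POSIXct"))
  attr(df$timestamp, "tzone") <- "UTC"
  canonical <- c(need, names(defaults))
  df[c(canonical, setdiff(names(df), canonical))]
}

#' Read VMS pings from a delimited text file
#'
#' Parsing is total: every input row either yields one ping or is rejected
#' under a named category; `rows_in = emitted + rejected` always holds in the
#' attached report. Rows whose timestamp cannot be parsed or whose coordinates
#' are missing are rejected; latitude/longitude outside the valid range are
#' kept but flagged `OUT_OF_RANGE`; missing speed/heading values are kept (as
#' `NA`) and tallied.
#'
#' @param path File path (an empty file yields an empty ping set).
#' @param config A [loader_config()] mapping all six mandatory VMS fields.
#' @return Ping data frame (see [as_vms_pings()]) with a `report` attribute:
#'   a named integer vector of tallies.
#' @export
read_vms <- function(path, config) {
  stopifnot(inherits(config, "loader_config"))
  need <- c("vessel_id", "timestamp", "lon", "lat", "speed", "heading")
  missing <- setdiff(need, names(config$fields))
  if (length(missing))
    stop("loader config does not map mandatory field(s): ",
         paste(missing, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = config$sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  n <- nrow(raw)
  report <- c(rows_in = n, emitted = 0L, rejected = 0L,
              bad_timestamp = 0L, missing_coordinates = 0L,
              lat_out_of_range = 0L, lon_out_of_range = 0L,
              na_speed = 0L, na_heading = 0L)
  if (n == 0L) {
    out <- as_vms_pings(data.frame(vessel_id = character(),
                                   timestamp = as.POSIXct(character(), tz = "UTC"),
                                   lon = numeric(), lat = numeric(),
                                   speed = numeric(), heading = numeric()))
    attr(out, "report") <- report
    return(out)
  }
  ts <- .parse_utc(.joined_column(raw, config$fields[["timestamp"]]),
                   config$datetime_format)
  parse_coord <- function(x) {
    if (config$coord_format == "dms") parse_dms(x)
    else suppressWarnings(as.numeric(x))
  }
  lon <- parse_coord(.joined_column(raw, config$fields[["lon"]]))
  lat <- parse_coord(.joined_column(raw, config$fields[["lat"]]))
  speed <- suppressWarnings(as.numeric(.joined_column(raw, config$fields[["speed"]])))
  heading <- suppressWarnings(as.numeric(.joined_column(raw, config$fields[["heading"]])))

  bad_ts <- is.na(ts)
  bad_xy <- !bad_ts & (is.na(lon) | is.na(lat))
  keep <- !bad_ts & !bad_xy
  report["bad_timestamp"] <- sum(bad_ts)
  report["missing_coordinates"] <- sum(bad_xy)
  report["rejected"] <- sum(!keep)
  report["emitted"] <- sum(keep)

  df <- data.frame(vessel_id = .joined_column(raw, config$fields[["vessel_id"]])[keep],
                   timestamp = ts[keep], lon = lon[keep], lat = lat[keep],
                   speed = speed[keep], heading = heading[keep],
                   stringsAsFactors = FALSE)
  df <- as_vms_pings(df)
  out_lat <- !is.na(df$lat) & (df$lat < -90 | df$lat > 90)
  out_lon <- !is.na(df$lon) & (df$lon < -180 | df$lon > 180)
  df$flags <- add_flag(df$flags, "OUT_OF_RANGE", out_lat | out_lon)
  report["lat_out_of_range"] <- sum(out_lat)
  report["lon_out_of_range"] <- sum(out_lon)
  report["na_speed"] <- sum(is.na(df$speed))
  report["na_heading"] <- sum(is.na(df$heading))
  attr(df, "report") <- report
  df
}

#' Read logbook records from long-form delimited text
#'
#' Input rows carry one (trip, species) catch each; trips are keyed by
#' (vessel, departure, arrival). Rows are pivoted to one record per trip with
#' one column per FAO 3-alpha species code; repeated (trip, species) rows are
#' summed. Rows with unparseable times, `arrival <= departure`, a species code
#' that is not three uppercase letters, or a missing/negative quantity are
#' rejected and tallied.
#'
#' @param path File path.
#' @param config A [loader_config()] mapping vessel_id, departure, arrival,
#'   species and quantity (gear/metier optional).
#' @return Data frame with columns `trip_id`, `vessel_id`, `departure`,
#'   `arrival`, `gear`, `metier` followed by one numeric column per species
#'   code (kg); attributes `species` (code vector) and `report` (tallies).
#' @export
read_logbook <- function(path, config) {
  stopifnot(inherits(config, "loader_config"))
  need <- c("vessel_id", "departure", "arrival", "species", "quantity")
  missing <- setdiff(need, names(config$fields))
  if (length(missing))
    stop("loader config does not map mandatory field(s): ",
         paste(missing, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = config$sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  n <- nrow(raw)
  report <- c(rows_in = n, used = 0L, rejected = 0L, bad_times = 0L,
              nonpositive_interval = 0L, bad_species = 0L, bad_quantity = 0L,
              empty_trip = 0L)
  empty <- function() {
    lb <- data.frame(trip_id = integer(), vessel_id = character(),
                     departure = as.POSIXct(character(), tz = "UTC"),
                     arrival = as.POSIXct(character(), tz = "UTC"),
                     gear = character(), metier = character(),
                     stringsAsFactors = FALSE)
    attr(lb, "species") <- character()
    attr(lb, "report") <- report
    lb
  }
  if (n == 0L) return(empty())

  dep <- .parse_utc(.joined_column(raw, config$fields[["departure"]]),
                    config$datetime_format)
  arr <- .parse_utc(.joined_column(raw, config$fields[["arrival"]]),
                    config$datetime_format)
  species <- toupper(trimws(.joined_column(raw, config$fields[["species"]])))
  qty <- suppressWarnings(as.numeric(.joined_column(raw, config$fields[["quantity"]])))
  vessel <- .joined_column(raw, config$fields[["vessel_id"]])
  gear <- if ("gear" %in% names(config$fields))
    .joined_column(raw, config$fields[["gear"]]) else rep(NA_character_, n)
  metier <- if ("metier" %in% names(config$fields))
    .joined_column(raw, config$fields[["metier"]]) else rep(NA_character_, n)

  bad_times <- is.na(dep) | is.na(arr)
  bad_int <- !bad_times & arr <= dep
  bad_sp <- !grepl("^[A-Z]{3}$", species)
  bad_q <- is.na(qty) | qty < 0
  keep <- !(bad_times | bad_int | bad_sp | bad_q)
  report["bad_times"] <- sum(bad_times)
  report["nonpositive_interval"] <- sum(bad_int)
  report["bad_species"] <- sum(bad_sp & !bad_times & !bad_int)
  report["bad_quantity"] <- sum(bad_q & !bad_sp & !bad_times & !bad_int)
  report["rejected"] <- sum(!keep)
  report["used"] <- sum(keep)
  if (!any(keep)) return(empty())

  key <- paste(vessel, format(dep, "%Y-%m-%dT%H:%M:%S"),
               format(arr, "%Y-%m-%dT%H:%M:%S"), sep = "\r")[keep]
  ukey <- unique(key)
  trip <- match(key, ukey)
  sp_all <- sort(unique(species[keep]))
  catch <- matrix(0, nrow = length(ukey), ncol = length(sp_all),
                  dimnames = list(NULL, sp_all))
  cellkey <- paste(trip, match(species[keep], sp_all), sep = "\r")
  agg <- rowsum(qty[keep], group = cellkey)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  catch[cbind(as.integer(vapply(parts, `[`, "", 1)),
              as.integer(vapply(parts, `[`, "", 2)))] <- agg[, 1]
  first <- match(ukey, key)
  idx <- which(keep)[first]
  lb <- data.frame(trip_id = seq_along(ukey),
                   vessel_id = vessel[idx], departure = dep[idx],
                   arrival = arr[idx], gear = gear[idx], metier = metier[idx],
                   stringsAsFactors = FALSE)
  lb <- cbind(lb, as.data.frame(catch))
  nonzero <- rowSums(catch) > 0
  report["empty_trip"] <- sum(!nonzero)
  lb <- lb[nonzero, , drop = FALSE]
  lb$trip_id <- seq_len(nrow(lb))
  rownames(lb) <- NULL
  attr(lb, "species") <- sp_all
  attr(lb, "report") <- report
  lb
}

#' Species columns of a logbook data frame
#' @param lb Logbook data frame from [read_logbook()] or [simulate_fleet()].
#' @return Character vector of FAO 3-alpha codes.
#' @export
logbook_species <- function(lb) {
  sp <- attr(lb, "species")
  if (!is.null(sp)) return(sp)
  grep("^[A-Z]{3}$", names(lb), value = TRUE)
}

#' Extract the catch-profile matrix from a logbook data frame
#' @inheritParams logbook_species
#' @return Numeric matrix, one row per trip, one column per species (kg).
#' @export
catch_matrix <- function(lb) {
  as.matrix(lb[, logbook_species(lb), drop = FALSE])
}

.SCHEMA_VERSION <- "1"
.TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Save pings or logbook records to a single-file SQLite store
#'
#' The store holds one table per entity (`vms_pings`, `logbook`) plus a
#' `meta` table carrying the schema version. Round-tripping through the store
#' is lossless field-for-field, including warning flags.
#'
#' @param x Ping or logbook data frame.
#' @param path Database file path.
#' @param what `"vms"` or `"logbook"`; inferred from the columns when missing.
#' @return The path, invisibly.
#' @export
store_save <- function(x, path, what = c("auto", "vms", "logbook")) {
  what <- match.arg(what)
  if (what == "auto")
    what <- if ("trip_id" %in% names(x) && !"timestamp" %in% names(x)) "logbook" else "vms"
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "meta",
                    data.frame(key = "schema_version", value = .SCHEMA_VERSION),
                    overwrite = TRUE)
  d <- as.data.frame(x)
  for (nm in names(d)) {
    if (inherits(d[[nm]], "POSIXct")) d[[nm]] <- format(d[[nm]], .TIME_FMT, tz = "UTC")
    if (is.logical(d[[nm]])) d[[nm]] <- as.integer(d[[nm]])
  }
  tbl <- if (what == "vms") "vms_pings" else "logbook"
  DBI::dbWriteTable(con, tbl, d, overwrite = TRUE)
  if (what == "logbook")
    DBI::dbWriteTable(con, "logbook_species",
                      data.frame(code = logbook_species(x)), overwrite = TRUE)
  invisible(path)
}

#' Load pings or logbook records from an SQLite store
#'
#' @param path Database file path.
#' @param what `"vms"` or `"logbook"`.
#' @param vessels Optional character vector: restrict to these vessel ids.
#' @return The stored collection, field-for-field identical to what was saved.
#' @export
store_load <- function(path, what = c("vms", "logbook"), vessels = NULL) {
  what <- match.arg(what)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbReadTable(con, "meta")
  ver <- meta$value[meta$key == "schema_version"]
  if (!identical(ver, .SCHEMA_VERSION))
    stop("store schema version mismatch: file has '", ver,
         "', this package reads '", .SCHEMA_VERSION, "'")
  tbl <- if (what == "vms") "vms_pings" else "logbook"
  d <- DBI::dbReadTable(con, tbl)
  if (!is.null(vessels)) d <- d[d$vessel_id %in% vessels, , drop = FALSE]
  rownames(d) <- NULL
  if (what == "vms") {
    d$timestamp <- .parse_utc(d$timestamp, .TIME_FMT)
    if ("is_fishing" %in% names(d)) d$is_fishing <- as.logical(d$is_fishing)
    if ("track_id" %in% names(d)) d$track_id <- as.integer(d$track_id)
    as_vms_pings(d)
  } else {
    d$departure <- .parse_utc(d$departure, .TIME_FMT)
    d$arrival <- .parse_utc(d$arrival, .TIME_FMT)
    attr(d, "species") <- DBI::dbReadTable(con, "logbook_species")$code
    d
  }
}
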