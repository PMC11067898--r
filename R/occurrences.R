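#' Read occurrence records from a Darwin-Core-like CSV
#'
#' Expects one row per occurrence with taxon name, WGS84 longitude and
#' latitude, and optionally a coordinate uncertainty (metres) and an event
#' date. Rows whose coordinates cannot be parsed or violate the valid
#' lon/lat ranges are rejected and reported by row index; missing
#' uncertainty and date are preserved as `NA`.
#'
#' @param path CSV file path.
#' @param column_map named list mapping the internal field names `taxon`,
#'   `lon`, `lat`, `uncertainty_m`, `event_date` to column names in the
#'   file. Defaults follow Darwin Core (`species`, `decimalLongitude`,
#'   `decimalLatitude`, `coordinateUncertaintyInMeters`, `eventDate`);
#'   `uncertainty_m` and `event_date` columns may be absent.
#' @return A data frame of class `occurrence_df` with columns `taxon`,
#'   `lon`, `lat`, `uncertainty_m`, `event_date` (Date). Rejected row
#'   indices are attached as attribute `rejected` and reported via a
#'   warning.
#' @export
read_occurrences <- function(path,
                             column_map = list(
                               taxon = "species",
                               lon = "decimalLongitude",
                               lat = "decimalLatitude",
                               uncertainty_m = "coordinateUncertaintyInMeters",
                               event_date = "eventDate")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  need <- c("taxon", "lon", "lat")
  for (f in need) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(df))
      stop("missing mapped column for `", f, "`: ", column_map[[f]])
  }
  out <- data.frame(
    taxon = as.character(df[[column_map$taxon]]),
    lon = suppressWarnings(as.numeric(df[[column_map$lon]])),
    lat = suppressWarnings(as.numeric(df[[column_map$lat]])),
    stringsAsFactors = FALSE)
  ucol <- column_map$uncertainty_m
  out$uncertainty_m <- if (!is.null(ucol) && ucol %in% names(df))
    suppressWarnings(as.numeric(df[[ucol]])) else NA_real_
  dcol <- column_map$event_date
  out$event_date <- if (!is.null(dcol) && dcol %in% names(df))
    as.Date(as.character(df[[dcol]]), optional = TRUE) else as.Date(NA)

  bad <- is.na(out$lon) | is.na(out$lat) |
    out$lon < -180 | out$lon > 180 | out$lat < -90 | out$lat > 90 |
    (!is.na(out$uncertainty_m) & out$uncertainty_m < 0)
  if (any(bad))
    warning(sum(bad), " row(s) rejected (unparseable or out-of-range ",
            "coordinates / negative uncertainty): rows ",
            paste(head(which(bad), 20), collapse = ", "))
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- which(bad)
  class(res) <- c("occurrence_df", "data.frame")
  res
}

#' Build an occurrence data frame in memory
#'
#' Convenience constructor mirroring [read_occurrences()] for
#' programmatically generated records.
#'
#' @param taxon,lon,lat,uncertainty_m,event_date vectors, recycled to a
#'   common length.
#' @return An `occurrence_df` data frame.
#' @export
occurrence_df <- function(taxon, lon, lat, uncertainty_m = NA_real_,
                          event_date = as.Date(NA)) {
  df <- data.frame(taxon = as.character(taxon), lon = as.numeric(lon),
                   lat = as.numeric(lat),
                   uncertainty_m = as.numeric(uncertainty_m),
                   event_date = as.Date(event_date),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$lon >= -180 & df$lon <= 180),
            all(df$lat >= -90 & df$lat <= 90),
            all(is.na(df$uncertainty_m) | df$uncertainty_m >= 0))
  class(df) <- c("occurrence_df", "data.frame")
  df
}

#' Write occurrence records to CSV with Darwin-Core column names
#' @param occ an `occurrence_df`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  out <- data.frame(species = occ$taxon,
                    decimalLongitude = occ$lon,
                    decimalLatitude = occ$lat,
                    coordinateUncertaintyInMeters = occ$uncertainty_m,
                    eventDate = as.character(occ$event_date))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
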