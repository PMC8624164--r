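#' Read an occurrence table from CSV
#'
#' Reads point occurrence records (one row per locality) from a
#' comma-separated, UTF-8, headered CSV. Rows whose coordinates do not parse
#' as decimal numbers, or that fall outside valid WGS84 bounds
#' (longitude \[-180, 180\], latitude \[-90, 90\]), are skipped with a warning
#' reporting the count. The reader performs no deduplication or filtering
#' beyond dropping unparseable rows — cleaning happens in
#' [clean_and_split()].
#'
#' @param path CSV file path.
#' @param lon_col,lat_col names of the longitude/latitude columns.
#' @param taxon_col optional name of a taxon column; if absent, `taxon` is
#'   used for all records.
#' @param taxon fallback taxon label when `taxon_col` is missing.
#' @return an `occurrence_table`: data.frame with columns `taxon`,
#'   `longitude`, `latitude`, and attribute `source` (the file path).
#' @export
read_occurrences <- function(path, lon_col = "longitude",
                             lat_col = "latitude", taxon_col = "taxon",
                             taxon = "unknown") {
  if (!file.exists(path)) stop(sprintf("occurrence file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(lon_col, lat_col), names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("column(s) %s not found; file has columns: %s",
                 paste(sQuote(missing_cols), collapse = ", "),
                 paste(names(df), collapse = ", ")))
  lon <- suppressWarnings(as.numeric(df[[lon_col]]))
  lat <- suppressWarnings(as.numeric(df[[lat_col]]))
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_skip <- sum(!ok)
  if (n_skip > 0L)
    warning(sprintf("skipped %d malformed or out-of-range row(s) in %s",
                    n_skip, path))
  if (!any(ok)) stop(sprintf("zero valid rows in %s", path))
  tax <- if (taxon_col %in% names(df)) as.character(df[[taxon_col]][ok])
         else rep(taxon, sum(ok))
  occurrence_table(tax, lon[ok], lat[ok], source = path)
}

#' Construct an occurrence table
#'
#' @param taxon character vector (recycled) of taxon labels.
#' @param longitude,latitude numeric coordinates, decimal degrees WGS84.
#' @param source free-text provenance note.
#' @return data.frame of class `occurrence_table`.
#' @export
occurrence_table <- function(taxon, longitude, latitude, source = "") {
  stopifnot(length(longitude) == length(latitude))
  if (any(longitude < -180 | longitude > 180, na.rm = TRUE) ||
      any(latitude < -90 | latitude > 90, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  df <- data.frame(taxon = rep_len(as.character(taxon), length(longitude)),
                   longitude = as.numeric(longitude),
                   latitude = as.numeric(latitude),
                   stringsAsFactors = FALSE)
  attr(df, "source") <- source
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Write an occurrence table to CSV
#'
#' @param occ an `occurrence_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("taxon", "longitude", "latitude")],
                   path, row.names = FALSE)
  invisible(path)
}
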