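#' Read a long-format spectra table
#'
#' Reads a CSV with columns `station_id`, `depth_m`, `component`,
#' `wavelength_nm`, `value` into a named list of `spectrum` objects (one
#' per station/depth/component record). Malformed rows are reported with
#' their line numbers; duplicated or non-monotone wavelengths within a
#' record are an error naming the record.
#'
#' @param path CSV file.
#' @return named list of `spectrum` objects; names are
#'   `station_id:depth_m:component`.
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("station_id", "depth_m", "component", "wavelength_nm",
                "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing columns ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$wavelength_nm) | !is.finite(df$value))
  if (length(bad))
    stop("malformed rows (line numbers incl. header): ",
         paste(bad + 1L, collapse = ", "))
  key <- paste(df$station_id, df$depth_m, df$component, sep = ":")
  out <- lapply(split(df, key), function(rec) {
    rec <- rec[order(rec$wavelength_nm), ]
    if (any(duplicated(rec$wavelength_nm)))
      stop(sprintf("duplicated wavelength in record %s:%s:%s",
                   rec$station_id[1], rec$depth_m[1], rec$component[1]))
    kind <- rec$component[1]
    if (!kind %in% c("a_CDOM", "a_p", "a_phi", "a_nap", "b_p", "b_b",
                     "SIOP", "R", "Rrs"))
      kind <- "SIOP"
    optical_spectrum(rec$wavelength_nm, rec$value, kind)
  })
  out
}

#' Write spectra as a long-format table
#'
#' Inverse of [read_spectra_table()]; the write is atomic (temp file then
#' rename) and values are written at full precision so a write-read
#' round-trip is lossless.
#'
#' @param spectra named list of `spectrum` objects; names
#'   `station_id:depth_m:component` (a bare name is used as station id with
#'   depth 0 and the spectrum's kind).
#' @param path output CSV.
#' @export
write_spectra_table <- function(spectra, path) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  nm <- names(spectra)
  if (is.null(nm)) nm <- sprintf("spec%03d", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    parts <- strsplit(nm[i], ":", fixed = TRUE)[[1]]
    data.frame(station_id = parts[1],
               depth_m = if (length(parts) >= 2) as.numeric(parts[2]) else 0,
               component = if (length(parts) >= 3) parts[3] else sp$kind,
               wavelength_nm = sp$wavelength, value = sp$value)
  })
  df <- do.call(rbind, rows)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines("station_id,depth_m,component,wavelength_nm,value", con)
  writeLines(sprintf("%s,%.17g,%s,%.17g,%.17g", df$station_id, df$depth_m,
                     df$component, df$wavelength_nm, df$value), con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Write fitted CDOM parameters as a one-row-per-spectrum CSV
#'
#' @param fits named list of `cdom_model` objects (names become station
#'   ids).
#' @param path output CSV.
#' @export
write_cdom_fits <- function(fits, path) {
  nm <- names(fits)
  if (is.null(nm)) nm <- sprintf("spec%03d", seq_along(fits))
  df <- data.frame(
    station_id = nm,
    a412 = vapply(fits, function(f) f$a_ref, numeric(1)),
    `S_nm.1` = vapply(fits, function(f) f$S, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    rmse = vapply(fits, function(f) f$rmse, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    check.names = FALSE)
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
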