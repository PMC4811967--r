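#' Recording container file format
#'
#' Recordings are stored in a single-file binary container with a versioned,
#' self-describing schema:
#' \preformatted{
#'   bytes 1-8   : magic "HDMEAREC"
#'   bytes 9-12  : int32 (little-endian) header length in bytes
#'   header      : UTF-8 JSON with fields
#'                 version, n_rows, n_cols, pitch, electrode_size,
#'                 stim_sites (n x 2 or null), sampling_rate, duration,
#'                 n_samples, n_electrodes, roi (or null)
#'   trace block : n_electrodes * n_samples float64, little-endian,
#'                 electrode-major (electrode 1's samples, then 2's, ...)
#' }
#' Doubles are written bit-exactly, so `read_recording(write_recording(r))`
#' reproduces `r` exactly.
#'
#' @param recording an [mea_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  g <- recording$geometry
  n_samp <- round(recording$sampling_rate * recording$duration)
  header <- list(
    version = 1L,
    n_rows = g$n_rows, n_cols = g$n_cols, pitch = g$pitch,
    electrode_size = g$electrode_size,
    stim_sites = if (is.null(g$stim_sites)) NULL else unclass(g$stim_sites),
    sampling_rate = recording$sampling_rate,
    duration = recording$duration,
    n_samples = n_samp,
    n_electrodes = n_electrodes(g),
    roi = recording$roi
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                                      digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HDMEAREC"), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (tr in recording$traces)
    writeBin(as.numeric(tr), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a recording container
#'
#' Reads a file written by [write_recording()], validating the schema and the
#' recording invariants. Missing header fields or a trace block whose size
#' disagrees with the header raise an error naming the failing field.
#'
#' @param path file path.
#' @return an [mea_recording()].
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "HDMEAREC"))
    stop("not a recording container (bad magic)")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stop("schema error: corrupt header length")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  required <- c("version", "n_rows", "n_cols", "pitch", "sampling_rate",
                "duration", "n_samples", "n_electrodes")
  missing <- setdiff(required, names(header))
  if (length(missing))
    stop("schema error: missing field(s) ", paste(missing, collapse = ", "))
  n_el <- header$n_electrodes
  n_samp <- header$n_samples
  if (n_el != header$n_rows * header$n_cols)
    stop("schema error: n_electrodes disagrees with grid dimensions")
  if (n_samp != round(header$sampling_rate * header$duration))
    stop("schema error: n_samples disagrees with sampling_rate * duration")
  block <- readBin(con, "numeric", n_el * n_samp, size = 8L, endian = "little")
  if (length(block) != n_el * n_samp)
    stop("schema error: trace block truncated (field traces)")
  if (length(readBin(con, "raw", 1L)) != 0L)
    stop("schema error: trailing bytes after trace block")
  geom <- array_geometry(
    n_rows = header$n_rows, n_cols = header$n_cols, pitch = header$pitch,
    electrode_size = header$electrode_size,
    stim_sites = if (is.null(header$stim_sites)) NULL else header$stim_sites
  )
  traces <- if (n_samp > 0L) {
    lapply(seq_len(n_el), function(i) block[((i - 1L) * n_samp + 1L):(i * n_samp)])
  } else {
    rep(list(numeric(0)), n_el)
  }
  mea_recording(geom, as.numeric(header$sampling_rate),
                as.numeric(header$duration), traces, roi = header$roi)
}

#' Export a result table as CSV or JSON
#'
#' Loss-free text serialization of any tabular stage result. CSV output
#' carries an optional `# units:` comment line taken from the table's
#' `units` attribute (a named character vector) ahead of the column header;
#' numbers are written with full precision (15 significant digits).
#'
#' @param table a data frame.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    units <- attr(table, "units")
    if (!is.null(units))
      writeLines(paste0("# units: ",
                        paste(names(units), units, sep = "=", collapse = ",")),
                 con)
    utils::write.csv(table, con, row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back an exported result table
#'
#' @param path file written by [export_results()].
#' @param format `"csv"` or `"json"`.
#' @return a data frame; for CSV a `units` attribute is restored when present.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    units <- NULL
    skip <- 0L
    if (startsWith(first, "# units: ")) {
      skip <- 1L
      spec <- strsplit(sub("^# units: ", "", first), ",", fixed = TRUE)[[1L]]
      units <- sub("^[^=]*=", "", spec)
      names(units) <- sub("=.*$", "", spec)
    }
    out <- utils::read.csv(path, skip = skip)
    attr(out, "units") <- units
    out
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
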