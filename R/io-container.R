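#' Read a multichannel EEG recording from disk
#'
#' Supported formats: the package's own single-file container (binary, with a
#' JSON header, bit-exact round trip), its delimited-text fallback, EDF
#' (European Data Format), and BrainVision (`.vhdr` header plus binary
#' `.eeg`). Readers return the stored samples as-is: no resampling, filtering
#' or re-referencing is applied. Sample values are returned in microvolts;
#' when an EDF/BrainVision header declares a different physical unit the
#' exact declared scaling is applied.
#'
#' @param path file to read (`.vhdr` for BrainVision).
#' @param format one of `"auto"`, `"container"`, `"text"`, `"edf"`,
#'   `"brainvision"`. `"auto"` dispatches on the file extension and, for the
#'   container, its magic bytes.
#' @return an [recording()] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "container", "text",
                                            "edf", "brainvision")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     {
                       con <- file(path, "rb")
                       magic <- readBin(con, "raw", 8L)
                       close(con)
                       if (identical(rawToChar(magic), "EEGWAV01")) "container"
                       else "text"
                     })
  }
  switch(format,
         container = read_container(path),
         text = read_text_container(path),
         edf = read_edf(path),
         brainvision = read_brainvision(path),
         stop("unknown format: ", format))
}

#' Write a recording to the package container format
#'
#' The binary container stores a JSON header (labels, sampling rate, start
#' time, unit) followed by IEEE-754 doubles, and round-trips bit-exactly
#' through [read_recording()]. The text format writes the same header as
#' `#`-prefixed lines followed by a tab-separated samples-by-channels table
#' at 17 significant digits, which also round-trips exactly for doubles.
#'
#' @param rec an [recording()] object (validated before writing).
#' @param path output file.
#' @param format `"container"` (binary, default) or `"text"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("container", "text")) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "container") write_container(rec, path)
  else write_text_container(rec, path)
  invisible(path)
}

container_header <- function(rec) {
  jsonlite::toJSON(list(labels = rec$labels, fs = rec$fs, t0 = rec$t0,
                        unit = "uV", n_channels = nrow(rec$data),
                        n_samples = ncol(rec$data)),
                   auto_unbox = TRUE, digits = NA)
}

write_container <- function(rec, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(charToRaw("EEGWAV01"), con)
  hdr <- charToRaw(as.character(container_header(rec)))
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  writeBin(as.vector(rec$data), con, size = 8L, endian = "little")
}

read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "EEGWAV01")) stop("not a container file: ", path)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  dat <- readBin(con, "double", hdr$n_channels * hdr$n_samples,
                 size = 8L, endian = "little")
  if (length(dat) != hdr$n_channels * hdr$n_samples)
    stop("integrity error: truncated container data in ", path)
  recording(matrix(dat, nrow = hdr$n_channels), fs = hdr$fs,
            labels = hdr$labels, t0 = hdr$t0)
}

write_text_container <- function(rec, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c("#EEGWAVTXT", paste0("#META ", container_header(rec)),
               paste(rec$labels, collapse = "\t")), con)
  # samples as rows, channels as columns, full double precision
  txt <- matrix(sprintf("%.17g", t(rec$data)), nrow = ncol(rec$data))
  writeLines(do.call(paste, c(asplit(txt, 2), sep = "\t")), con)
}

read_text_container <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[[1]] != "#EEGWAVTXT")
    stop("not a text container file: ", path)
  meta_line <- grep("^#META ", lines, value = TRUE)
  if (!length(meta_line)) stop("missing #META header in ", path)
  hdr <- jsonlite::fromJSON(sub("^#META ", "", meta_line[[1]]))
  body <- lines[!startsWith(lines, "#")]
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           colClasses = "numeric")
  if (ncol(dat) != hdr$n_channels)
    stop("integrity error: ", ncol(dat), " columns for ",
         hdr$n_channels, " declared channels")
  recording(t(as.matrix(dat)), fs = hdr$fs, labels = hdr$labels, t0 = hdr$t0)
}

#' Write a results table as delimited text
#'
#' Writes a homogeneous data frame as tab-separated text with a header row;
#' numbers are serialized at full double precision (17 significant digits) so
#' that a round-trip parse reproduces the values exactly.
#'
#' @param rows a non-empty data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("schema error: `rows` must be a data frame")
  if (nrow(rows) == 0L || ncol(rows) == 0L)
    stop("schema error: empty results table")
  out <- rows
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path file to read.
#' @return a data frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}
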