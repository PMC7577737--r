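# Minimal BrainVision reader: INI-style .vhdr header plus binary .eeg data.
# Supports multiplexed IEEE_FLOAT_32 and INT_16 data (the common vendor
# export); vectorized orientation and ASCII data are rejected explicitly.

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]][[key]] <- val
    }
  }
  out
}

read_brainvision <- function(path) {
  hdr <- parse_vhdr(path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", path)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY")
    stop("only BINARY BrainVision data is supported")
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data is supported")
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # header stores microseconds
  bin_fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chans <- hdr[["Channel Infos"]]
  if (length(chans) < n_ch) stop("integrity error: channel list shorter than ",
                                 "NumberOfChannels")
  info <- lapply(chans[seq_len(n_ch)], function(v) strsplit(v, ",")[[1]])
  labels <- vapply(info, `[`, character(1), 1L)
  res <- vapply(info, function(v)
    if (length(v) >= 3 && nzchar(v[[3]])) as.numeric(v[[3]]) else 1,
    numeric(1))
  units <- vapply(info, function(v)
    if (length(v) >= 4 && nzchar(v[[4]])) v[[4]] else "µV", character(1))
  data_file <- file.path(dirname(path), ci$DataFile)
  if (!file.exists(data_file)) stop("data file not found: ", data_file)
  sz <- file.info(data_file)$size
  if (bin_fmt == "IEEE_FLOAT_32") {
    vals <- readBin(data_file, "double", n = sz / 4, size = 4L,
                    endian = "little")
  } else if (bin_fmt == "INT_16") {
    vals <- readBin(data_file, "integer", n = sz / 2, size = 2L,
                    signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", bin_fmt)
  n_samp <- length(vals) %/% n_ch
  data <- matrix(vals[seq_len(n_ch * n_samp)], nrow = n_ch)  # multiplexed
  data <- data * res  # resolution is exact per-channel scaling to the unit
  scale <- vapply(units, function(u)
    switch(tolower(u), "µv" = 1, uv = 1, mv = 1e3, v = 1e6, 1),
    numeric(1))
  if (any(scale != 1)) {
    message("converting BrainVision units to microvolts (exact scaling)")
    data <- data * scale
  }
  recording(data, fs = fs, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
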