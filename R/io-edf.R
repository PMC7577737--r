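# Minimal EDF (European Data Format) support. EDF stores 16-bit integers with
# a per-signal linear physical scaling; the reader applies exactly the scaling
# the header declares. Continuous recordings only; annotation signals are not
# supported.

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

read_edf <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256L) stop("not an EDF file (truncated header): ", path)
  n_rec <- as.integer(edf_field(raw, 237L, 8L))
  rec_dur <- as.numeric(edf_field(raw, 245L, 8L))
  ns <- as.integer(edf_field(raw, 253L, 4L))
  if (is.na(ns) || ns < 1L) stop("not an EDF file (bad signal count): ", path)
  sig_hdr <- function(offset, len) {
    vapply(seq_len(ns), function(i)
      edf_field(raw, 257L + offset * ns + (i - 1L) * len, len), character(1))
  }
  labels <- sig_hdr(0L, 16L)
  phys_dim <- sig_hdr(96L, 8L)  # after label(16) + transducer(80)
  phys_min <- as.numeric(sig_hdr(104L, 8L))
  phys_max <- as.numeric(sig_hdr(112L, 8L))
  dig_min <- as.numeric(sig_hdr(120L, 8L))
  dig_max <- as.numeric(sig_hdr(128L, 8L))
  spr <- as.integer(sig_hdr(216L, 8L))
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  header_bytes <- 256L * (ns + 1L)
  fs <- spr[[1]] / rec_dur
  vals <- readBin(raw[-seq_len(header_bytes)], "integer",
                  n = n_rec * ns * spr[[1]], size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) != n_rec * ns * spr[[1]])
    stop("integrity error: EDF data shorter than header declares")
  # record-major, signal blocks within each record
  arr <- array(vals, dim = c(spr[[1]], ns, n_rec))
  data <- matrix(0, ns, spr[[1]] * n_rec)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(ns)) {
    x <- as.vector(arr[, i, ])
    data[i, ] <- (x - dig_min[[i]]) * gain[[i]] + phys_min[[i]]
  }
  scale <- vapply(phys_dim, function(u)
    switch(tolower(u), uv = 1, "µv" = 1, mv = 1e3, v = 1e6, 1),
    numeric(1))
  if (any(scale != 1)) {
    message("converting EDF physical units to microvolts (exact scaling: ",
            paste(unique(paste0(phys_dim, " x", scale)), collapse = ", "), ")")
    data <- data * scale
  }
  recording(data, fs = fs, labels = labels)
}

edf_pad <- function(x, len) formatC(as.character(x), width = len, flag = "-")

# Internal EDF writer (16-bit quantization; used for fixtures and export).
write_edf <- function(rec, path, record_s = 1) {
  validate_recording(rec)
  spr <- rec$fs * record_s
  if (abs(spr - round(spr)) > 1e-8)
    stop("record duration must give an integer number of samples")
  spr <- as.integer(round(spr))
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec * spr != ncol(rec$data))
    stop("recording length must be a whole number of EDF records")
  ns <- nrow(rec$data)
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  pmax <- ifelse(pmax > pmin, pmax, pmin + 1)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X", 80L), edf_pad("X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(format(record_s), 8L), edf_pad(ns, 4L))
  sig <- paste0(
    paste(edf_pad(rec$labels, 16L), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8L), ns), collapse = ""),
    paste(edf_pad(formatC(pmin, format = "g", width = 8L), 8L), collapse = ""),
    paste(edf_pad(formatC(pmax, format = "g", width = 8L), 8L), collapse = ""),
    paste(rep(edf_pad(dmin, 8L), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 32L), ns), collapse = ""))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  # re-read the header fields actually written so the reader's scaling is exact
  pmin_w <- as.numeric(edf_pad(formatC(pmin, format = "g", width = 8L), 8L))
  pmax_w <- as.numeric(edf_pad(formatC(pmax, format = "g", width = 8L), 8L))
  dig <- matrix(0L, ns, ncol(rec$data))
  for (i in seq_len(ns)) {
    g <- (pmax_w[[i]] - pmin_w[[i]]) / (dmax - dmin)
    dig[i, ] <- as.integer(pmin(pmax(round((rec$data[i, ] - pmin_w[[i]]) / g) +
                                      dmin, dmin), dmax))
  }
  arr <- array(0L, dim = c(spr, ns, n_rec))
  for (i in seq_len(ns)) arr[, i, ] <- dig[i, ]
  writeBin(as.vector(arr), con, size = 2L, endian = "little")
  invisible(path)
}
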