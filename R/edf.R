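# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a 256-byte ASCII global header, one 256-byte ASCII header per
# signal, then data records of 16-bit little-endian integers mapped linearly
# from [digital_min, digital_max] to [physical_min, physical_max]. We write
# 1-second records (samples-per-record = fs), so recordings are truncated to
# a whole number of seconds on write. Round trips are exact up to the 16-bit
# quantization step.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

# physical min/max must survive an 8-char ASCII field; quantization is
# computed from the rounded values so reader and writer agree exactly
edf_num8 <- function(x) {
  s <- formatC(signif(x, 7), format = "g", width = 1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4)
  s
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-second EDF record")
  if (n_rec * fs != ncol(rec$data)) {
    warning("EDF writer truncating to ", n_rec, " whole seconds")
  }
  pmin <- numeric(ns); pmax <- numeric(ns)
  for (i in seq_len(ns)) {
    lo <- min(rec$data[i, ]); hi <- max(rec$data[i, ])
    if (hi <= lo) hi <- lo + 1  # constant channel: avoid zero scale
    # widen slightly so rounded-ASCII bounds still bracket the data
    span <- hi - lo
    pmin[i] <- as.numeric(edf_num8(lo - 0.01 * span))
    pmax[i] <- as.numeric(edf_num8(hi + 0.01 * span))
  }
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(vapply(rec$labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, function(v) edf_pad(edf_num8(v), 8), ""), collapse = ""),
    paste(vapply(pmax, function(v) edf_pad(edf_num8(v), 8), ""), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((rec$data[i, cols] - pmin[i]) / scale[i]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_field <- function(raw, at, width) {
  trimws(rawToChar(raw[(at + 1L):(at + width)]))
}

read_edf <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256) {
    stop("truncated EDF file: ", path, " (", length(raw),
         " bytes, header needs 256)")
  }
  ns <- as.integer(edf_field(raw, 252, 4))
  n_rec <- as.integer(edf_field(raw, 236, 8))
  hdr_bytes <- as.integer(edf_field(raw, 184, 8))
  dur <- as.numeric(edf_field(raw, 244, 8))
  if (length(raw) < hdr_bytes) {
    stop("truncated EDF file: ", path, " ends at byte ", length(raw),
         " inside the ", hdr_bytes, "-byte header")
  }
  off <- 256L
  fld <- function(width) {
    out <- vapply(seq_len(ns) - 1L,
                  function(i) edf_field(raw, off + i * width, width), "")
    off <<- off + ns * width
    out
  }
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  rec_len <- sum(spr) * 2L
  need <- hdr_bytes + n_rec * rec_len
  if (length(raw) < need) {
    stop("truncated EDF file: ", path, " ends at byte ", length(raw),
         ", expected ", need)
  }
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  vals <- readBin(raw[(hdr_bytes + 1L):need], "integer", n = n_rec * sum(spr),
                  size = 2L, signed = TRUE, endian = "little")
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- vals[(idx + 1L):(idx + spr[i])]
      idx <- idx + spr[i]
      phys <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  recording(data, fs = fs, labels = labels)
}
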