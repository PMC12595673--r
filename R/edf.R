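# Minimal European Data Format (EDF) reader/writer for continuous
# single- or multi-channel recordings. EDF stores 16-bit little-endian
# integers with per-channel linear physical scaling; only the fields needed
# for plain continuous recordings are handled (no EDF+ annotations).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF header field too long: '%s'", x))
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  .edf_pad(s, width)
}

#' Write a continuous recording to an EDF file
#'
#' @param x Numeric vector (one channel) or matrix with channels in rows, in
#'   physical units (uV by default).
#' @param fs_hz Sampling rate in Hz (integer-valued).
#' @param path Output file path.
#' @param labels Channel label(s); recycled to the number of channels.
#' @param phys_dim Physical dimension string stored per channel.
#' @return `path`, invisibly.
#' @details Data records are 1 s long when the signal length is a multiple of
#'   `fs_hz`; otherwise a single record holding the whole signal is written.
#'   Values are quantized to the 16-bit digital range over a symmetric
#'   physical range covering the data.
#' @export
write_edf <- function(x, fs_hz, path, labels = "A1", phys_dim = "uV") {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nchan <- nrow(x)
  ns <- ncol(x)
  labels <- rep_len(labels, nchan)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (fs_hz <= 0 || fs_hz != round(fs_hz)) stop("fs_hz must be a positive integer")
  if (ns %% fs_hz == 0) {
    n_rec <- ns %/% fs_hz
    rec_dur <- 1
    spr <- fs_hz
  } else {
    n_rec <- 1
    rec_dur <- ns / fs_hz
    spr <- ns
  }
  pmax_ <- vapply(seq_len(nchan), function(i) {
    m <- max(abs(x[i, ]), 1e-6)
    m * 1.000001
  }, 0)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X X X X", 80), .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 + 256 * nchan, 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_num(rec_dur, 8), .edf_pad(nchan, 4)
  )
  field <- function(f, width) paste0(vapply(seq_len(nchan), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) .edf_pad(labels[i], 16), 16),
    field(function(i) .edf_pad("", 80), 80),
    field(function(i) .edf_pad(phys_dim, 8), 8),
    field(function(i) .edf_num(-pmax_[i], 8), 8),
    field(function(i) .edf_num(pmax_[i], 8), 8),
    field(function(i) .edf_pad(dig_min, 8), 8),
    field(function(i) .edf_pad(dig_max, 8), 8),
    field(function(i) .edf_pad("", 80), 80),
    field(function(i) .edf_pad(spr, 8), 8),
    field(function(i) .edf_pad("", 32), 32)
  )
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nchan)) {
      seg <- x[i, ((r - 1) * spr + 1):(r * spr)]
      dig <- round((seg + pmax_[i]) / (2 * pmax_[i]) * (dig_max - dig_min) + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel Channel label to extract.
#' @return List with `signal` (numeric, physical units), `fs_hz`, and
#'   `label`.
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- rawToChar(readBin(con, "raw", 256))
  if (nchar(fixed) < 256) stop("corrupt EDF header: file too short")
  gets <- function(from, len) trimws(substr(fixed, from, from + len - 1))
  n_rec <- suppressWarnings(as.integer(gets(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(gets(245, 8)))
  nchan <- suppressWarnings(as.integer(gets(253, 4)))
  if (any(is.na(c(n_rec, rec_dur, nchan))) || nchan < 1 || n_rec < 1) {
    stop("corrupt EDF header: bad record counts")
  }
  sig_hdr <- rawToChar(readBin(con, "raw", 256 * nchan))
  if (nchar(sig_hdr) < 256 * nchan) stop("corrupt EDF header: truncated signal headers")
  # offsets in characters within the signal header block
  pos <- c(label = 0, transducer = 16 * nchan, dim = 96 * nchan,
           pmin = 104 * nchan, pmax = 112 * nchan, dmin = 120 * nchan,
           dmax = 128 * nchan, prefilter = 136 * nchan, spr = 216 * nchan)
  take <- function(start, width) {
    vapply(seq_len(nchan), function(i) {
      trimws(substr(sig_hdr, start + (i - 1) * width + 1, start + i * width))
    }, "")
  }
  labels <- take(pos["label"], 16)
  pmin_ <- as.numeric(take(pos["pmin"], 8))
  pmax_ <- as.numeric(take(pos["pmax"], 8))
  dmin_ <- as.numeric(take(pos["dmin"], 8))
  dmax_ <- as.numeric(take(pos["dmax"], 8))
  spr <- as.integer(take(pos["spr"], 8))
  if (is.null(channel)) channel <- labels[1]
  ci <- match(channel, labels)
  if (is.na(ci)) {
    stop(sprintf("channel '%s' not found (available: %s)",
                 channel, paste(labels, collapse = ", ")))
  }
  out <- numeric(n_rec * spr[ci])
  ptr <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nchan)) {
      vals <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      if (length(vals) < spr[i]) stop("corrupt EDF file: truncated data record")
      if (i == ci) {
        out[(ptr + 1):(ptr + spr[i])] <- vals
        ptr <- ptr + spr[i]
      }
    }
  }
  phys <- (out - dmin_[ci]) * (pmax_[ci] - pmin_[ci]) / (dmax_[ci] - dmin_[ci]) + pmin_[ci]
  list(signal = phys, fs_hz = spr[ci] / rec_dur, label = labels[ci])
}
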