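# Minimal EDF (European Data Format) reader/writer, sufficient for
# continuous equal-rate multichannel recordings: ASCII header, one-second
# data records, 16-bit little-endian samples with per-channel physical
# scaling. Round-trip error is bounded by the format's quantization step
# (physical range / 65535).

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)
}

fmt_num8 <- function(x) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 3, width = 1)
  if (nchar(s) > 8) stop("numeric EDF field does not fit: ", x)
  pad_ascii(s, 8)
}

#' Write a recording to an EDF file
#'
#' @param rec An `ewl_recording` (data in microvolts); `fs` must be a
#'   positive integer and the sample count a multiple of `fs` (one-second
#'   records).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$data
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  nrec <- ncol(x) / fs
  if (nrec != round(nrec)) {
    stop("sample count must be a whole number of 1 s records")
  }
  ns <- nrow(x)
  labels <- rownames(x)

  pmax_ <- apply(x, 1, function(ch) max(abs(ch), 1))
  pmax_ <- signif(pmax_ * 1.0001, 6)
  # affine map mirroring the reader: phys [-pm, pm] <-> dig [-32768, 32767]
  scale <- 2 * pmax_ / 65535
  dig <- round(sweep(sweep(x, 1, pmax_, "+"), 1, scale, "/")) - 32768
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_ascii("0", 8))
  wr(pad_ascii(rec$subject_id, 80))
  wr(pad_ascii("eegworkload synthetic recording", 80))
  wr(pad_ascii("01.01.26", 8))
  wr(pad_ascii("00.00.00", 8))
  wr(pad_ascii(256 * (ns + 1), 8))
  wr(pad_ascii("", 44))
  wr(pad_ascii(nrec, 8))
  wr(pad_ascii(1, 8))
  wr(pad_ascii(ns, 4))
  for (l in labels) wr(pad_ascii(l, 16))
  for (i in seq_len(ns)) wr(pad_ascii("synthetic", 80))
  for (i in seq_len(ns)) wr(pad_ascii("uV", 8))
  for (i in seq_len(ns)) wr(fmt_num8(-pmax_[i]))
  for (i in seq_len(ns)) wr(fmt_num8(pmax_[i]))
  for (i in seq_len(ns)) wr(pad_ascii(-32768, 8))
  for (i in seq_len(ns)) wr(pad_ascii(32767, 8))
  for (i in seq_len(ns)) wr(pad_ascii("BP 1-45Hz", 80))
  for (i in seq_len(ns)) wr(pad_ascii(fs, 8))
  for (i in seq_len(ns)) wr(pad_ascii("", 32))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      writeBin(as.integer(dig[ch, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples matrix, physical units),
#'   `fs` (samples per second, assuming one-second records), `labels`
#'   (channel labels) and `subject_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  subject <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)            # reserved
  if (length(unique(spr)) != 1) stop("mixed per-channel rates unsupported")

  data <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      scale <- (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      data[ch, idx] <- (raw - dmin[ch]) * scale + pmin_[ch]
    }
  }
  rownames(data) <- labels
  list(data = data, fs = spr[1] / dur, labels = labels,
       subject_id = subject)
}
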