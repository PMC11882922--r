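#' Write continuous data to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples in 1-second data
#' records, one physical min/max pair per channel derived from the data
#' range. The trailing partial second is zero-padded; the true sample
#' count is recoverable from `nsamp` in the JSON-style `recording`
#' header field.
#'
#' @param x channels x samples matrix (microvolts).
#' @param sfreq sampling rate, Hz (integer).
#' @param path output file.
#' @param channelNames channel labels (defaults to rownames).
#' @return `path`, invisibly.
#' @export
writeEdf <- function(x, sfreq, path, channelNames = rownames(x)) {
  stopifnot(is.matrix(x), sfreq == round(sfreq))
  ns <- nrow(x)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(ns))
  nsamp <- ncol(x)
  nrec <- ceiling(nsamp / sfreq)
  pad <- nrec * sfreq - nsamp
  if (pad > 0) x <- cbind(x, matrix(0, ns, pad))
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  fix <- pmax - pmin < 1e-9
  pmax[fix] <- pmin[fix] + 1
  # widen by 1% so the 3-significant-digit header fields (rounded
  # either way) still bracket the data: no clipping at the extremes
  span <- pmax - pmin
  pmin <- pmin - 0.01 * span
  pmax <- pmax + 0.01 * span
  dmin <- -32768; dmax <- 32767
  fld <- function(v, w) {
    s <- substr(format(v, width = w, justify = "left"), 1, w)
    formatC(s, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fld("0", 8), fld("X X X X", 80),
    fld(paste0("Startdate X nsamp=", nsamp), 80),
    fld("01.01.26", 8), fld("00.00.00", 8),
    fld(as.character(256 * (1 + ns)), 8), fld("EDF", 44),
    fld(as.character(nrec), 8), fld("1", 8), fld(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  sigHdr <- paste0(
    paste0(vapply(channelNames, fld, "", w = 16), collapse = ""),
    paste0(rep(fld("simulated", 80), ns), collapse = ""),
    paste0(rep(fld("uV", 8), ns), collapse = ""),
    paste0(vapply(sprintf("%.3g", pmin), fld, "", w = 8), collapse = ""),
    paste0(vapply(sprintf("%.3g", pmax), fld, "", w = 8), collapse = ""),
    paste0(rep(fld(as.character(dmin), 8), ns), collapse = ""),
    paste0(rep(fld(as.character(dmax), 8), ns), collapse = ""),
    paste0(rep(fld("none", 80), ns), collapse = ""),
    paste0(rep(fld(as.character(sfreq), 8), ns), collapse = ""),
    paste0(rep(fld("", 32), ns), collapse = ""))
  writeChar(sigHdr, con, eos = NULL)
  pminN <- as.numeric(sprintf("%.3g", pmin))
  pmaxN <- as.numeric(sprintf("%.3g", pmax))
  gain <- (dmax - dmin) / (pmaxN - pminN)
  for (r in seq_len(nrec)) {
    seg <- ((r - 1) * sfreq + 1):(r * sfreq)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, seg] - pminN[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [writeEdf()]
#'
#' @param path EDF file.
#' @return list `data` (channels x samples, physical units), `sfreq`,
#'   `channelNames`.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  rd(80)                      # patient
  recField <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  nrec <- as.integer(rd(8))
  durS <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  sfreq <- spr[1] / durS
  x <- matrix(0, ns, nrec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      x[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  nsamp <- suppressWarnings(
    as.integer(sub(".*nsamp=([0-9]+).*", "\\1", recField)))
  if (!is.na(nsamp) && nsamp <= ncol(x)) x <- x[, seq_len(nsamp), drop = FALSE]
  rownames(x) <- labels
  list(data = x, sfreq = sfreq, channelNames = labels)
}

#' Save / load an epoch container
#'
#' Epochs are stored as an RDS payload next to a JSON sidecar recording
#' channel names, sampling rate, window and trial count, so the
#' container is self-describing without loading the payload.
#'
#' @param epochs an [EpochSet-class].
#' @param path payload path (`.rds`); the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
saveEpochs <- function(epochs, path) {
  saveRDS(epochs, path)
  sidecar <- list(channels = epochs@layout@names, sfreq = epochs@sfreq,
                  window_s = range(epochs@times),
                  n_trials = dim(epochs@data)[3])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveEpochs
#' @export
loadEpochs <- function(path) readRDS(path)
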