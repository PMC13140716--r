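#' EDF input/output
#'
#' Minimal reader/writer for the European Data Format (EDF), the 16-bit
#' exchange format the recordings use. One file holds one
#' subject/stage/condition segment; channel labels, sampling rate and the
#' subject/stage/condition identifiers round-trip exactly, samples round-trip
#' within the 16-bit quantization step implied by the stored physical range.
#'
#' @name edf
NULL

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, digits = 6, format = "g", width = 1)
  if (nchar(s) > width) s <- formatC(x, digits = 4, format = "g", width = 1)
  edf_pad(s, width)
}

#' Write an EEG segment to an EDF file
#'
#' Samples are scaled to 16-bit integers over a symmetric physical range just
#' covering the data. The subject/stage/condition labels are stored in the
#' local patient identification field.
#'
#' @param segment an [eeg_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  stopifnot(inherits(segment, "eeg_segment"))
  x <- segment$samples
  ns <- nrow(x)
  fs <- segment$fs
  n <- ncol(x)
  # whole-second records when possible, else a single record
  if (fs == round(fs) && n %% fs == 0) {
    spr <- as.integer(fs); n_rec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; n_rec <- 1L; rec_dur <- n / fs
  }
  pm_raw <- max(abs(x), 1e-6) * 1.0001
  pm <- as.numeric(formatC(pm_raw, digits = 6, format = "g"))  # header-exact
  if (pm < pm_raw) pm <- pm_raw * 1.001  # never clip after rounding
  dmin <- -32768; dmax <- 32767
  dig <- round((x + pm) / (2 * pm) * (dmax - dmin) + dmin)
  dig[dig > dmax] <- dmax; dig[dig < dmin] <- dmin

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  pid <- paste("subject=", segment$subject, " stage=", segment$stage,
               " condition=", segment$condition, sep = "")
  wr(edf_pad("0", 8))
  wr(edf_pad(pid, 80))
  wr(edf_pad("thermoeeg synthetic segment", 80))
  wr(edf_pad("01.01.26", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 + 256 * ns, 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_num(rec_dur, 8)); wr(edf_pad(ns, 4))
  labels <- segment$channel_labels
  for (l in labels) wr(edf_pad(l, 16))
  for (l in labels) wr(edf_pad("AgCl electrode", 80))
  for (l in labels) wr(edf_pad("uV", 8))
  for (l in labels) wr(edf_num(-pm, 8))
  for (l in labels) wr(edf_num(pm, 8))
  for (l in labels) wr(edf_pad(dmin, 8))
  for (l in labels) wr(edf_pad(dmax, 8))
  for (l in labels) wr(edf_pad("", 80))
  for (l in labels) wr(edf_pad(spr, 8))
  for (l in labels) wr(edf_pad("", 32))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EEG segment from an EDF file
#'
#' @param path EDF file path.
#' @param montage optional [montage()]; if given, all its analysis labels
#'   must be present in the file, otherwise an error names the missing
#'   channels.
#' @return an [eeg_segment()].
#' @export
read_segment <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    raw <- readBin(con, "raw", nc)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  pid <- rd(80); rid <- rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stop("malformed EDF header: unparsable signal fields")
  n_total <- spr * n_rec
  samples <- matrix(0, nrow = ns, ncol = n_total[1L],
                    dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L,
                   endian = "little", signed = TRUE)
      if (length(d) < spr[i]) stop("malformed EDF file: truncated data record")
      phys <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      samples[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  meta <- c(subject = NA_character_, stage = NA_character_,
            condition = NA_character_)
  for (key in names(meta)) {
    m <- regmatches(pid, regexec(paste0(key, "=([^ ]+)"), pid))[[1L]]
    if (length(m) == 2L) meta[[key]] <- m[2L]
  }
  fs <- spr[1L] / rec_dur
  if (!is.null(montage)) {
    missing <- setdiff(montage$labels, labels)
    if (length(missing) > 0L)
      stop("EDF file is missing required channels: ",
           paste(missing, collapse = ", "))
    samples <- samples[montage$labels, , drop = FALSE]
  }
  eeg_segment(samples, fs, meta[["subject"]], meta[["stage"]],
              meta[["condition"]])
}

#' Quantization step of a written EDF file
#'
#' The physical value of one digital unit, computed from the stored header
#' scaling; the maximum round-trip error of [write_segment()] /
#' [read_segment()] is bounded by this step.
#'
#' @param path EDF file path.
#' @return numeric quantization step (physical units per digital unit).
#' @export
edf_quantization_step <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44); rd(8); rd(8)
  ns <- as.integer(rd(4))
  for (i in seq_len(ns)) rd(16)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(rd(8)); for (i in seq_len(ns - 1L)) rd(8)
  pmax <- as.numeric(rd(8)); for (i in seq_len(ns - 1L)) rd(8)
  dmin <- as.numeric(rd(8)); for (i in seq_len(ns - 1L)) rd(8)
  dmax <- as.numeric(rd(8)); for (i in seq_len(ns - 1L)) rd(8)
  (pmax - pmin) / (dmax - dmin)
}
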