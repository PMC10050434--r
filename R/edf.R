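# Minimal EDF / EDF+ input-output.
#
# Covers exactly what polysomnography ingest needs: 16-bit signal records
# with per-signal sampling rates, and EDF+ time-stamped annotation lists
# (TALs) for hypnograms. Physical values are mapped linearly onto the
# digital range -32768..32767, so a write/read round trip is exact up to
# half a quantization step, (phys_max - phys_min) / 65535 / 2.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1, nchar(s) - (nchar(s) - width) - 2), width = 1)
    if (nchar(s) <= width) break
    s <- substr(s, 1L, width)
  }
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' Writes one EDF file with 1-second data records. Each signal is quantized
#' to 16 bits over its own physical range.
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (one per channel).
#' @param sampling_rates Integer vector, samples per second for each signal
#'   (recycled if length 1). Every signal must span the same number of whole
#'   seconds.
#' @param physical_dims Character vector of unit strings (default `"uV"`).
#' @param patient,recording Free-text header fields.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(path, signals, sampling_rates = 100L,
                      physical_dims = "uV",
                      patient = "X", recording = "Startdate 01-JAN-2000") {
  ns <- length(signals)
  if (ns == 0L) abort("no signals to write")
  sampling_rates <- as.integer(rep_len(sampling_rates, ns))
  physical_dims <- rep_len(physical_dims, ns)
  secs <- vapply(seq_len(ns), function(i) length(signals[[i]]) / sampling_rates[i],
                 numeric(1))
  if (length(unique(secs)) != 1L || secs[1] != round(secs[1])) {
    abort("all signals must cover the same whole number of seconds")
  }
  n_rec <- as.integer(secs[1])

  pmin_ <- numeric(ns); pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    pmin_[i] <- lo; pmax_[i] <- hi
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (ns + 1L), 8), edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8), edf_pad(1L, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste(edf_pad(names(signals), 16), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad("", 80)[rep(1, ns)], collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(physical_dims, 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(pmin_, edf_num, ""), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(pmax_, edf_num, ""), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(-32768L, 8)[rep(1, ns)], collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(32767L, 8)[rep(1, ns)], collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad("", 80)[rep(1, ns)], collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad(sampling_rates, 8), collapse = ""), con, eos = NULL)
  writeChar(paste(edf_pad("", 32)[rep(1, ns)], collapse = ""), con, eos = NULL)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      sel <- ((r - 1L) * sampling_rates[i] + 1L):(r * sampling_rates[i])
      writeBin(dig[[i]][sel], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with `header` (patient, recording, n_records,
#'   record_duration) and `signals`, a list of per-channel lists each holding
#'   `label`, `sampling_rate` (samples per record / record duration), and
#'   `data` (numeric, physical units). Annotation channels are returned with
#'   raw bytes in `$bytes` instead of `$data`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(n) as.numeric(trimws(rd(n)))
  version <- trimws(rd(8))
  patient <- trimws(rd(80)); recording <- trimws(rd(80))
  rd(8); rd(8)                      # start date / time, unused
  header_bytes <- num(8)
  reserved <- trimws(rd(44))
  n_rec <- as.integer(num(8)); rec_dur <- num(8)
  ns <- as.integer(num(4))
  if (is.na(ns) || ns < 1L) abort(sprintf("not a parseable EDF header: %s", path))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")              # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) num(8), numeric(1))
  vapply(seq_len(ns), function(i) rd(80), "")              # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), integer(1))
  vapply(seq_len(ns), function(i) rd(32), "")              # reserved

  is_annot <- grepl("EDF Annotations", labels, fixed = TRUE)
  store <- lapply(seq_len(ns), function(i) {
    if (is_annot[i]) raw(0) else numeric(n_rec * spr[i])
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        store[[i]] <- c(store[[i]], readBin(con, "raw", 2L * spr[i]))
      } else {
        d <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
        sel <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
        store[[i]][sel] <- pmin_[i] +
          (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      }
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    out <- list(label = labels[i], sampling_rate = spr[i] / rec_dur,
                physical_dim = dims[i])
    if (is_annot[i]) out$bytes <- store[[i]] else out$data <- store[[i]]
    out
  })
  list(header = list(version = version, patient = patient,
                     recording = recording, reserved = reserved,
                     n_records = n_rec, record_duration = rec_dur),
       signals = signals)
}

#' Write an EDF+ annotation file
#'
#' Stores a list of `(onset, duration, text)` annotations as EDF+
#' time-stamped annotation lists in a single data record — the layout used
#' for hypnogram files.
#'
#' @param path Output file path.
#' @param onsets Numeric onsets in seconds from recording start.
#' @param durations Numeric durations in seconds.
#' @param texts Character annotation texts (e.g. `"Sleep stage W"`).
#' @return Invisibly, `path`.
#' @export
write_edf_annotations <- function(path, onsets, durations, texts) {
  stopifnot(length(onsets) == length(durations),
            length(onsets) == length(texts))
  tal <- function(on, du, tx) {
    paste0(ifelse(on >= 0, "+", ""), format(on, trim = TRUE, scientific = FALSE),
           "\x15", format(du, trim = TRUE, scientific = FALSE),
           "\x14", tx, "\x14")
  }
  body <- paste0("+0\x14\x14",
                 paste(tal(onsets, durations, texts), collapse = ""))
  bytes <- charToRaw(body)
  spr <- ceiling((length(bytes) + 2L) / 2L)   # samples (2 bytes each), with padding
  payload <- c(bytes, raw(2L * spr - length(bytes)))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("Startdate 01-JAN-2000", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(512L, 8), edf_pad("EDF+C", 44),
    edf_pad(1L, 8), edf_pad(1L, 8), edf_pad(1L, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(edf_pad("EDF Annotations", 16), con, eos = NULL)
  writeChar(edf_pad("", 80), con, eos = NULL)
  writeChar(edf_pad("", 8), con, eos = NULL)
  writeChar(edf_num(0), con, eos = NULL)
  writeChar(edf_num(1), con, eos = NULL)
  writeChar(edf_pad(-32768L, 8), con, eos = NULL)
  writeChar(edf_pad(32767L, 8), con, eos = NULL)
  writeChar(edf_pad("", 80), con, eos = NULL)
  writeChar(edf_pad(spr, 8), con, eos = NULL)
  writeChar(edf_pad("", 32), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}

# Parse raw TAL bytes into a tibble(onset, duration, annotation).
parse_tals <- function(bytes) {
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  out <- list()
  for (chunk in tals) {
    # each chunk may contain several "onset\x15dur\x14text\x14..." entries,
    # the first piece before any \x14 being a bare record timestamp
    entries <- strsplit(chunk, "\x14", fixed = TRUE)[[1]]
    entries <- entries[nzchar(entries)]
    i <- 1L
    while (i <= length(entries)) {
      head_ <- entries[i]
      if (grepl("\x15", head_, fixed = TRUE)) {
        parts <- strsplit(head_, "\x15", fixed = TRUE)[[1]]
        onset <- suppressWarnings(as.numeric(parts[1]))
        dur <- suppressWarnings(as.numeric(parts[2]))
        text <- if (i + 1L <= length(entries)) entries[i + 1L] else ""
        if (is.na(onset)) {
          abort(sprintf("unparseable annotation record %d: %s", i, head_))
        }
        out[[length(out) + 1L]] <-
          tibble(onset = onset, duration = dur %||% NA_real_, annotation = text)
        i <- i + 2L
      } else {
        i <- i + 1L                 # bare timestamp, skip
      }
    }
  }
  if (!length(out)) return(tibble(onset = numeric(), duration = numeric(),
                                  annotation = character()))
  bind_rows(out)
}

#' Read an EDF+ annotation file
#'
#' @param path EDF+ file containing an `EDF Annotations` channel.
#' @return A tibble with columns `onset`, `duration` (seconds) and
#'   `annotation` (text).
#' @export
read_edf_annotations <- function(path) {
  edf <- read_edf(path)
  ann <- Filter(function(s) grepl("EDF Annotations", s$label, fixed = TRUE),
                edf$signals)
  if (!length(ann)) abort(sprintf("no annotation channel in %s", path))
  parse_tals(do.call(c, lapply(ann, `[[`, "bytes")))
}
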