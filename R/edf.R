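# Minimal self-contained EDF (European Data Format) writer/reader for
# exporting simulated recordings: 16-bit samples, one-second data records,
# per-channel physical scaling, fixed (anonymized) start date so exports are
# byte-identical for identical inputs. Event markers go to a separate
# BIDS-style TSV, not into the EDF.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a recording to an EDF file
#'
#' @param raw A [raw_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  fs <- raw$fs
  if (fs != round(fs)) abort("EDF export requires an integer sampling rate.")
  n <- ncol(raw$data)
  n_rec <- ceiling(n / fs)
  ns <- nrow(raw$data)
  x <- cbind(raw$data, matrix(0, ns, n_rec * fs - n))

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  span <- pmax(pmax_ - pmin_, 1e-3)
  pmin_ <- pmin_ - 0.001 * span
  pmax_ <- pmax_ + 0.001 * span
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad_ascii(s, w)), con)
  wr("0", 8)
  wr(sprintf("X X X %s", raw$meta$participant %||% "X"), 80)
  wr(sprintf("Startdate 01-JAN-2000 run%s %s",
             raw$meta$run %||% "NA", raw$meta$task %||% "NA"), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  for (lab in raw$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.2f", v), 8)
  for (v in pmax_) wr(sprintf("%.2f", v), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  # re-read the rounded physical bounds so scaling matches the header exactly
  pmin_h <- as.numeric(sprintf("%.2f", pmin_))
  pmax_h <- as.numeric(sprintf("%.2f", pmax_))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    ix <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(ns)) {
      dig <- round((x[ci, ix] - pmin_h[ci]) * gain[ci] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param montage Montage to attach (default [standard_montage()]).
#' @return A [raw_recording()] with empty events (events live in the
#'   companion TSV; see [read_events_tsv()]).
#' @export
read_edf <- function(path, montage = standard_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  data <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ci], size = 2, endian = "little")
      phys <- (dig - dmin[ci]) * (pmax_[ci] - pmin_[ci]) /
        (dmax[ci] - dmin[ci]) + pmin_[ci]
      data[ci, ((r - 1) * spr[ci] + 1):(r * spr[ci])] <- phys
    }
  }
  fs <- spr[1] / rec_dur
  kinds <- ifelse(startsWith(labels, "EOG"), "EOG", "EEG")
  raw_recording(data, fs, kinds, montage,
                tibble::tibble(sample = integer(), task = character(),
                               condition = character()))
}

#' Write cue events to a BIDS-style TSV
#'
#' @param raw A [raw_recording()] with events.
#' @param path Output TSV path.
#' @param duration Cue duration in seconds written to every row (default 7).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(raw, path, duration = 7) {
  ev <- raw$events
  df <- data.frame(onset = (ev$sample - 1L) / raw$fs, duration = duration,
                   task = ev$task, condition = ev$condition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path TSV path.
#' @param fs Sampling rate used to convert onsets back to sample indices.
#' @return Tibble with columns `sample`, `task`, `condition`.
#' @export
read_events_tsv <- function(path, fs) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  tibble::tibble(sample = as.integer(round(df$onset * fs)) + 1L,
                 task = df$task, condition = df$condition)
}

#' Export a simulated participant to EDF + TSV files
#'
#' One EDF and one events TSV per run, plus deterministic file naming, so
#' identical seeds yield byte-identical exports.
#'
#' @param participant A `participant_recording`.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest of written files (`run`, `edf`, `events`).
#' @export
export_participant <- function(participant, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- participant$meta$participant %||% "P000"
  rows <- lapply(participant$runs, function(run) {
    r <- run$meta$run
    edf <- file.path(dir, sprintf("%s_run-%02d_eeg.edf", pid, r))
    ev <- file.path(dir, sprintf("%s_run-%02d_events.tsv", pid, r))
    write_edf(run, edf)
    write_events_tsv(run, ev)
    tibble::tibble(run = r, edf = edf, events = ev)
  })
  dplyr::bind_rows(rows)
}
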