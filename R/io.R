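# Recording I/O: minimal European Data Format (EDF) support and delimited
# text. The EDF subset written here uses 1-second data records, 16-bit
# samples, physical units "uV", and a per-channel symmetric physical range, so
# round-trip error is bounded by the 16-bit quantization step.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @param format `"edf"` or `"delimited"`. The delimited dialect is
#'   tab-separated with a header row of channel labels and one sample per row.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  format <- match.arg(format)
  if (format == "edf") write_recording_edf(rec, path) else write_recording_delim(rec, path)
  invisible(path)
}

write_recording_delim <- function(rec, path) {
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channel_labels)
  data.table::fwrite(dt, path, sep = "\t")
}

write_recording_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stopf("EDF writer requires a whole number of seconds (got %d samples at %d Hz)",
          ncol(rec$data), fs)
  }
  n_rec <- as.integer(round(n_rec))
  phys_max <- vapply(seq_len(ns), function(i) {
    m <- max(abs(rec$data[i, ]), 1e-6)
    as.numeric(formatC(m * 1.0001, digits = 6, format = "g", width = 8))
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field(sprintf("subject %s", rec$subject_id), 80L),
    pad_field(sprintf("condition %s", rec$condition), 80L),
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (ns + 1L), 8L),
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field("1", 8L),
    pad_field(ns, 4L)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels, pad_field, character(1), width = 16L), collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field("uV", 8L), ns), collapse = ""),
    paste(vapply(-phys_max, pad_field, character(1), width = 8L), collapse = ""),
    paste(vapply(phys_max, pad_field, character(1), width = 8L), collapse = ""),
    paste(rep(pad_field("-32767", 8L), ns), collapse = ""),
    paste(rep(pad_field("32767", 8L), ns), collapse = ""),
    paste(rep(pad_field("", 80L), ns), collapse = ""),
    paste(rep(pad_field(fs, 8L), ns), collapse = ""),
    paste(rep(pad_field("", 32L), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  dig <- round(sweep(rec$data, 1L, phys_max, "/") * 32767)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
}

#' Read a recording from EDF or delimited text
#'
#' @param path File path.
#' @param format `"edf"` or `"delimited"`.
#' @param fs Sampling rate in Hz; required for delimited files (the dialect
#'   stores no metadata), ignored for EDF.
#' @param subject_id,condition Optional provenance to attach.
#' @return A `recording`.
#' @export
read_recording <- function(path, format = c("edf", "delimited"), fs = NULL,
                           subject_id = NA_character_, condition = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "edf") {
    read_recording_edf(path, subject_id = subject_id, condition = condition)
  } else {
    if (is.null(fs)) stopf("`fs` is required when reading delimited recordings")
    read_recording_delim(path, fs, subject_id = subject_id, condition = condition)
  }
}

read_recording_delim <- function(path, fs, subject_id = NA_character_,
                                 condition = NA_character_) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  labels <- names(dt)
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1L]
      stopf("non-numeric value in '%s', column %d ('%s'), data row %s",
            basename(path), j, labels[j], ifelse(is.na(bad), "?", bad))
    }
    if (anyNA(col)) {
      stopf("missing value in '%s', column %d ('%s'), data row %d",
            basename(path), j, labels[j], which(is.na(col))[1L])
    }
  }
  recording(t(as.matrix(dt)), fs = fs, channel_labels = labels,
            subject_id = subject_id, condition = condition)
}

read_recording_edf <- function(path, subject_id = NA_character_,
                               condition = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                                   # header length (recomputed below)
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stopf("malformed EDF header in '%s'", basename(path))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  rd(80L * ns); rd(8L * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  rd(80L * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1)))
  rd(32L * ns)
  if (length(unique(spr)) != 1L) {
    stopf("EDF reader supports a single common sampling rate ('%s')", basename(path))
  }
  fs <- spr[1L] / rec_dur
  X <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1L], size = 2L,
                     endian = "little")
    if (length(block) < ns * spr[1L]) stopf("truncated EDF data in '%s'", basename(path))
    blk <- matrix(block, nrow = spr[1L], ncol = ns)
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    X[, idx] <- t(blk)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  X <- sweep(sweep(X, 1L, dmin, "-"), 1L, scale, "*")
  X <- sweep(X, 1L, pmin, "+")
  recording(X, fs = fs, channel_labels = labels,
            subject_id = subject_id, condition = condition)
}

#' Write a synthetic study to a directory
#'
#' One file per recording plus a JSON sidecar holding condition labels, seeds
#' and the ground-truth state specifications for recovery tests.
#'
#' @param study An `acu_study`.
#' @param dir Output directory (created if needed).
#' @param format `"edf"` or `"delimited"`.
#' @return The sidecar path, invisibly.
#' @export
write_study <- function(study, dir, format = c("edf", "delimited")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") "edf" else "tsv"
  files <- character(0)
  for (rec in study$recordings) {
    f <- file.path(dir, sprintf("%s_%s.%s", rec$subject_id, rec$condition, ext))
    write_recording(rec, f, format)
    files <- c(files, basename(f))
  }
  cfg <- study$config
  sidecar <- list(
    format = format, fs = cfg$fs, duration_s = cfg$duration_s,
    n_subjects = cfg$n_subjects, n_channels = cfg$n_channels,
    mixing_seed = cfg$mixing_seed, noise_seed = cfg$noise_seed,
    carrier_amp = cfg$carrier_amp,
    files = files,
    states = lapply(cfg$states, function(s) unclass(s))
  )
  sp <- file.path(dir, "study.json")
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA)
  invisible(sp)
}
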