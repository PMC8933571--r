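# Minimal WFDB reader/writer (header + format-16 signal file) and the alarm
# manifest / fixture-container interfaces. Only what the Challenge 2015
# record layout needs: single .dat, format 16, little-endian, interleaved.

parse_gain_spec <- function(s) {
  # "gain(baseline)/units", every part optional; defaults gain 200, base 0
  units <- NA_character_
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    units <- parts[2]
    s <- parts[1]
  }
  base <- 0
  if (grepl("\\(", s)) {
    base <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", s))
    s <- sub("\\(.*", "", s)
  }
  gain <- suppressWarnings(as.numeric(s))
  if (is.na(gain) || gain == 0) gain <- 200
  list(gain = gain, baseline = base, units = units)
}

#' Read a WFDB record (header + format-16 signal file)
#'
#' @param path base path of the record (with or without `.hea`).
#' @return list with `record_name`, `fs`, `n_samples`, `sig_names`,
#'   `signals` (n_samples x n_sig matrix, physical units) and `comments`.
#' @export
read_wfdb <- function(path) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- trimws(lines)
  comments <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rec <- strsplit(body[1], "\\s+")[[1]]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(strsplit(rec[3], "/")[[1]][1]) else 250
  n_samples <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- vector("list", n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(body[1 + i], "\\s+")[[1]]
    if (!grepl("^16", f[2]))
      stop("unsupported WFDB signal format '", f[2], "' (only 16)")
    g <- parse_gain_spec(if (length(f) >= 3) f[3] else "200")
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
      paste0("sig", i)
    sig[[i]] <- list(file = f[1], gain = g$gain, baseline = g$baseline,
                     name = desc)
  }
  dat <- file.path(dirname(hea), sig[[1]]$file)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  raw <- readBin(dat, "integer", n = file.size(dat) / 2L, size = 2L,
                 endian = "little", signed = TRUE)
  if (is.na(n_samples)) n_samples <- length(raw) %/% n_sig
  m <- matrix(raw[seq_len(n_samples * n_sig)], ncol = n_sig, byrow = TRUE)
  phys <- sapply(seq_len(n_sig), function(i)
    (m[, i] - sig[[i]]$baseline) / sig[[i]]$gain)
  colnames(phys) <- vapply(sig, `[[`, "", "name")
  list(record_name = rec[1], fs = fs, n_samples = n_samples,
       sig_names = colnames(phys), signals = phys, comments = comments)
}

#' Write a WFDB record (format 16)
#'
#' Physical values are quantized with the given per-signal gain
#' (`adc = round(x * gain + baseline)`, clamped to int16), so writing is
#' deterministic but lossy at 1/gain resolution.
#'
#' @param signals n_samples x n_sig numeric matrix (columns named).
#' @param path base path (no extension); writes `path.hea` and `path.dat`.
#' @param fs sampling rate in Hz.
#' @param gains per-signal gain (recycled); default 8192 for unit-scale data.
#' @param comments optional character vector written as `#` header lines.
#' @return invisibly, the header path.
#' @export
write_wfdb <- function(signals, path, fs, gains = 8192, comments = character()) {
  n_sig <- ncol(signals)
  n <- nrow(signals)
  gains <- rep_len(gains, n_sig)
  nm <- colnames(signals)
  if (is.null(nm)) nm <- paste0("sig", seq_len(n_sig))
  rec <- basename(path)
  hdr <- c(sprintf("%s %d %g %d", rec, n_sig, fs, n),
           sprintf("%s.dat 16 %g(0)/NU 16 0 0 0 0 %s", rec, gains, nm),
           if (length(comments)) paste0("#", comments))
  writeLines(hdr, paste0(path, ".hea"))
  adc <- sapply(seq_len(n_sig), function(i)
    pmax(pmin(round(signals[, i] * gains[i]), 32767), -32768))
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2L,
           endian = "little")
  invisible(paste0(path, ".hea"))
}

# Map raw monitor signal names onto canonical roles. The first two ECG-class
# leads become ECG1/ECG2 in file order.
classify_signal_names <- function(nms) {
  ecg_leads <- c("I", "II", "III", "AVR", "AVL", "AVF", "V", paste0("V", 1:6),
                 "MCL", "MCL1", "ECG", "ECG1", "ECG2")
  up <- toupper(trimws(nms))
  roles <- rep(NA_character_, length(nms))
  roles[up %in% c("PLETH", "PPG")] <- "PPG"
  roles[up %in% c("ABP", "ART", "AO", "P1")] <- "ABP"
  roles[up %in% c("RESP", "RR", "IMP")] <- "RESP"
  is_ecg <- which(up %in% ecg_leads & is.na(roles))
  if (length(is_ecg) >= 1) roles[is_ecg[1]] <- "ECG1"
  if (length(is_ecg) >= 2) roles[is_ecg[2]] <- "ECG2"
  roles
}

#' Read one record as a [waveform_record()]
#'
#' Channels are mapped to canonical roles by signal-name matching; roles
#' absent from the file are zero-filled and flagged unavailable. Alarm type
#' and label come from the manifest row when given, otherwise from the
#' header comment line (`#<Alarm_type> <True/False>` as written by
#' [write_dataset()]).
#'
#' @param path WFDB base path.
#' @param manifest_row optional list/1-row data.frame with `alarm_type` and
#'   optionally `label`.
#' @param onset_seconds alarm onset in seconds; `NULL` (default) places the
#'   onset at the record end; use 300 for Challenge Event-1 records.
#' @return a [waveform_record()].
#' @export
read_record <- function(path, manifest_row = NULL, onset_seconds = NULL) {
  w <- read_wfdb(path)
  if (is.null(manifest_row)) {
    if (!length(w$comments))
      abort_validation("no manifest row and no alarm comment in %s", path)
    parts <- strsplit(w$comments[1], "\\s+")[[1]]
    manifest_row <- list(alarm_type = parts[1],
                         label = if (length(parts) >= 2)
                           tolower(parts[2]) else "unknown")
  }
  roles <- classify_signal_names(w$sig_names)
  L <- nrow(w$signals)
  ch <- matrix(0, length(ALARM_ROLES), L, dimnames = list(ALARM_ROLES, NULL))
  avail <- setNames(rep(FALSE, length(ALARM_ROLES)), ALARM_ROLES)
  for (i in seq_along(roles)) {
    if (is.na(roles[i]) || avail[[roles[i]]]) next
    ch[roles[i], ] <- w$signals[, i]
    avail[[roles[i]]] <- TRUE
  }
  onset <- if (is.null(onset_seconds)) L else as.integer(round(w$fs * onset_seconds))
  if (onset > L)
    abort_validation("record %s shorter (%d) than onset %d", path, L, onset)
  lab <- manifest_row$label
  if (is.null(lab) || is.na(lab)) lab <- "unknown"
  waveform_record(record_id = w$record_name, channels = ch,
                  available = avail, fs = w$fs,
                  alarm_type = manifest_row$alarm_type, onset = onset,
                  label = lab)
}

#' Read an alarm manifest CSV
#'
#' Columns: `record_id`, `alarm_type` (long or short names), `label`
#' (`true`/`false`/`unknown`).
#' @param path CSV path.
#' @return data.frame with normalized `alarm_type` and `label`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "alarm_type", "label")
  if (!all(need %in% names(m)))
    abort_validation("manifest must have columns %s", paste(need, collapse = ", "))
  m$alarm_type <- vapply(m$alarm_type, normalize_alarm_type, "")
  m$label <- vapply(m$label, normalize_label, "")
  m
}

#' Read a directory of WFDB records listed in a manifest
#'
#' @param dir directory holding `manifest.csv` (or pass `manifest`) and the
#'   WFDB files.
#' @param manifest optional manifest data.frame (as from [read_manifest()]).
#' @param onset_seconds see [read_record()].
#' @return list of [waveform_record()]s.
#' @export
read_dataset <- function(dir, manifest = NULL, onset_seconds = NULL) {
  if (is.null(manifest)) manifest <- read_manifest(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i)
    read_record(file.path(dir, manifest$record_id[i]),
                manifest[i, ], onset_seconds = onset_seconds))
}

#' Write / read the internal fixture container
#'
#' A gzip CSV of the channel matrix at full double precision (`%.17g`, hence
#' bit-exact on round trip) plus a JSON sidecar with the record metadata.
#'
#' @param record a [waveform_record()].
#' @param path base path (writes `path.csv.gz` + `path.json`).
#' @return invisibly (write) / the record (read).
#' @export
write_fixture <- function(record, path) {
  con <- gzfile(paste0(path, ".csv.gz"), "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(record$channels)), function(i)
    paste(sprintf("%.17g", record$channels[i, ]), collapse = ","), ""), con)
  meta <- list(record_id = record$record_id,
               available = as.list(record$available), fs = record$fs,
               alarm_type = record$alarm_type, onset = record$onset,
               label = record$label, preprocessed = record$preprocessed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- readLines(gzfile(paste0(path, ".csv.gz")))
  ch <- do.call(rbind, lapply(rows, function(r)
    as.numeric(strsplit(r, ",", fixed = TRUE)[[1]])))
  rownames(ch) <- ALARM_ROLES
  rec <- waveform_record(meta$record_id, ch,
                         available = unlist(meta$available), fs = meta$fs,
                         alarm_type = meta$alarm_type, onset = meta$onset,
                         label = meta$label)
  rec$preprocessed <- isTRUE(meta$preprocessed)
  rec
}
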