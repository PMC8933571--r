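# WaveformRecord: one monitor record with canonical channels, alarm metadata
# and the pre-processing / segment-pair extraction used by the model.

#' Construct a waveform record
#'
#' A record holds the full multi-channel signal matrix in the fixed canonical
#' channel order (`ECG1`, `ECG2`, `PPG`, `ABP`, `RESP`), the sampling rate,
#' the alarm type, the 0-based alarm onset sample and the adjudicated label.
#' Channels absent from the source file are present but zero-filled and
#' flagged unavailable, mirroring the zero-imputation used before encoding.
#'
#' @param record_id character scalar.
#' @param channels numeric matrix, 5 x L, rows in [ALARM_ROLES] order (rows
#'   may be supplied named in any order and are re-ordered).
#' @param available named logical vector over roles; defaults to channels
#'   with non-zero range.
#' @param fs sampling rate in Hz.
#' @param alarm_type one of [ALARM_TYPES] (long manifest names accepted).
#' @param onset 0-based sample index of alarm onset; default `ncol(channels)`
#'   (alarm at record end, the Challenge Event-1 convention when the record
#'   is exactly 5 min).
#' @param label `"true_alarm"`, `"false_alarm"` or `"unknown"`.
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(record_id, channels, available = NULL, fs,
                            alarm_type, onset = ncol(channels),
                            label = "unknown") {
  alarm_type <- normalize_alarm_type(alarm_type)
  label <- normalize_label(label)
  if (!is.matrix(channels)) abort_validation("channels must be a matrix")
  if (!is.null(rownames(channels))) {
    if (!setequal(rownames(channels), ALARM_ROLES))
      abort_validation("channel rownames must be the 5 canonical roles")
    channels <- channels[ALARM_ROLES, , drop = FALSE]
  } else if (nrow(channels) != length(ALARM_ROLES)) {
    abort_validation("channels must have %d rows", length(ALARM_ROLES))
  }
  rownames(channels) <- ALARM_ROLES
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_validation("fs must be a positive scalar")
  if (!is_count(onset) || onset < 0)
    abort_validation("onset must be a nonnegative integer")
  if (ncol(channels) < onset)
    abort_validation("record %s has %d samples, shorter than onset %d",
                     record_id, ncol(channels), onset)
  if (is.null(available)) {
    rng <- apply(channels, 1, function(x) diff(range(x)))
    available <- rng > 0
  }
  available <- setNames(as.logical(available[ALARM_ROLES]), ALARM_ROLES)
  available[is.na(available)] <- FALSE
  channels[!available, ] <- 0
  structure(list(record_id = as.character(record_id), channels = channels,
                 available = available, fs = fs, alarm_type = alarm_type,
                 onset = as.integer(onset), label = label,
                 preprocessed = FALSE),
            class = "waveform_record")
}

normalize_alarm_type <- function(x) {
  x <- as.character(x)
  if (x %in% names(ALARM_TYPE_LONG)) x <- ALARM_TYPE_LONG[[x]]
  if (!x %in% ALARM_TYPES)
    abort_validation("unknown alarm type '%s'", x)
  x
}

normalize_label <- function(x) {
  x <- as.character(x)
  map <- c("true" = "true_alarm", "false" = "false_alarm",
           true_alarm = "true_alarm", false_alarm = "false_alarm",
           unknown = "unknown")
  if (!x %in% names(map)) abort_validation("unknown label '%s'", x)
  unname(map[x])
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record %s: %s/%s, fs=%g Hz, %d samples, onset=%d, channels: %s>\n",
              x$record_id, x$alarm_type, x$label, x$fs, ncol(x$channels),
              x$onset, paste(names(x$available)[x$available], collapse = "+")))
  invisible(x)
}

#' Pre-process a record: truncate to onset and min-max normalize
#'
#' Keeps only the real-time window `[0, onset)` and rescales each available
#' channel to `[0, 1]` (min to 0, max to 1) using statistics computed on that
#' window. Constant channels map to all zeros, the same value used to impute
#' missing channels. Idempotent.
#'
#' @param record a [waveform_record()].
#' @return the pre-processed record (`preprocessed = TRUE`).
#' @export
preprocess <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  if (record$onset <= 0) abort_validation("onset must be positive")
  ch <- record$channels[, seq_len(record$onset), drop = FALSE]
  for (r in ALARM_ROLES) {
    if (!record$available[[r]]) next
    x <- ch[r, ]
    rng <- range(x)
    ch[r, ] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
  }
  record$channels <- ch
  record$preprocessed <- TRUE
  record
}

#' Extract the Siamese alarm/baseline segment pair
#'
#' The alarm segment is the final 10 s before onset, `[onset - fs*10, onset)`.
#' The baseline segment is a same-length window starting uniformly at random
#' in `{0, ..., onset - 2*fs*10}` so it lies entirely before the alarm
#' segment (before time t - 10 s). Indices are 0-based, windows half-open.
#'
#' @param record a pre-processed [waveform_record()].
#' @param rng_seed integer; same seed gives the identical pair.
#' @param rule_score optional scalar in `[0, 1]` attached to the pair.
#' @param baseline_start optional explicit 0-based start (frozen mode).
#' @return a `segment_pair` list: `alarm_segment`, `baseline_segment`
#'   (both 5 x fs*10), `baseline_start`, `label`, `alarm_onehot`,
#'   `rule_score`.
#' @export
extract_pair <- function(record, rng_seed = 1L, rule_score = NULL,
                         baseline_start = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  Tlen <- as.integer(round(record$fs * 10))
  if (record$onset < 2L * Tlen)
    abort_validation("onset %d leaves no legal baseline window (need >= %d)",
                     record$onset, 2L * Tlen)
  if (is.null(baseline_start)) {
    hi <- record$onset - 2L * Tlen
    baseline_start <- with_seed(rng_seed,
      as.integer(floor(runif(1, 0, hi + 1))))
    baseline_start <- min(baseline_start, hi)
  }
  if (baseline_start < 0 || baseline_start + Tlen > record$onset - Tlen)
    abort_validation("baseline window [%d, %d) overlaps the alarm window",
                     baseline_start, baseline_start + Tlen)
  a0 <- record$onset - Tlen
  alarm_seg <- record$channels[, (a0 + 1):record$onset, drop = FALSE]
  base_seg <- record$channels[, (baseline_start + 1):(baseline_start + Tlen),
                              drop = FALSE]
  onehot <- as.numeric(ALARM_TYPES == record$alarm_type)
  structure(list(alarm_segment = alarm_seg, baseline_segment = base_seg,
                 baseline_start = as.integer(baseline_start),
                 label = record$label, alarm_onehot = onehot,
                 rule_score = rule_score),
            class = "segment_pair")
}

#' Stratified k-fold split of record ids
#'
#' Folds are stratified jointly on (alarm type, label): within every stratum
#' the shuffled members are dealt cyclically, continuing a global pointer so
#' that overall fold sizes differ by at most one.
#'
#' @param record_ids character vector.
#' @param labels,types vectors aligned with `record_ids`.
#' @param k number of folds (>= 2).
#' @param rng_seed integer seed.
#' @return list of `k` disjoint character vectors partitioning `record_ids`.
#' @export
make_folds <- function(record_ids, labels, types, k = 5L, rng_seed = 1L) {
  if (!is_count(k) || k < 2) abort_validation("k must be an integer >= 2")
  n <- length(record_ids)
  if (n < k) abort_validation("need at least k records")
  stopifnot(length(labels) == n, length(types) == n)
  strata <- paste(types, labels, sep = ":")
  fold_of <- integer(n)
  with_seed(rng_seed, {
    ptr <- 0L
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- (ptr + seq_along(idx) - 1L) %% k + 1L
      ptr <- (ptr + length(idx)) %% k
    }
  })
  lapply(seq_len(k), function(f) record_ids[fold_of == f])
}
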