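# Synthetic alarm-record simulator. Emulates the Challenge 2015 regime:
# 250 Hz, alarm onset at the record end, the triggering event inside the
# final 10 s, per-type rhythm signatures for true alarms and artifact
# corruption for false alarms. Morphology is deliberately schematic
# (Gaussian-bump QRS, smooth lagged pulses): the point is that the per-type
# beat-timing statistics are exactly realizable and recoverable.

#' Specification of a synthetic alarm dataset
#'
#' Defaults mirror the Challenge 2015 training set: the per-type mix and the
#' per-type true-alarm fractions are the published record counts
#' (ASY 122 with 22 true, EBR 89/43, ETC 140/131, VTA 341/89, VFB 58/6 of
#' 750 records).
#'
#' @param n_records number of records.
#' @param type_mix named proportions over [ALARM_TYPES] (sums to 1).
#' @param true_fraction per-type probability of a true alarm; scalar or
#'   named vector.
#' @param record_seconds record duration (alarm onset at the end); >= 20 s
#'   so a baseline window exists.
#' @param fs sampling rate in Hz.
#' @param noise_sd additive Gaussian noise amplitude (signal units; QRS has
#'   amplitude ~1).
#' @param artifact_menu artifact kinds used for false alarms.
#' @param rng_seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_records = 750,
                           type_mix = c(ASY = 122, EBR = 89, ETC = 140,
                                        VTA = 341, VFB = 58) / 750,
                           true_fraction = c(ASY = 22 / 122, EBR = 43 / 89,
                                             ETC = 131 / 140, VTA = 89 / 341,
                                             VFB = 6 / 58),
                           record_seconds = 300, fs = 250, noise_sd = 0.02,
                           artifact_menu = c("noise_burst", "lead_flat",
                                             "baseline_wander", "spike_train"),
                           rng_seed = 1L) {
  if (!is_count(n_records) || n_records < 1)
    abort_validation("n_records must be a positive integer")
  if (abs(sum(type_mix) - 1) > 1e-8)
    abort_validation("type_mix must sum to 1")
  if (is.null(names(type_mix))) names(type_mix) <- ALARM_TYPES
  if (length(true_fraction) == 1L)
    true_fraction <- setNames(rep(true_fraction, 5), ALARM_TYPES)
  if (any(true_fraction < 0 | true_fraction > 1))
    abort_validation("true_fraction must lie in [0, 1]")
  if (record_seconds < 20)
    abort_validation("record_seconds must be >= 20 (baseline window)")
  bad <- setdiff(artifact_menu,
                 c("noise_burst", "lead_flat", "baseline_wander", "spike_train"))
  if (length(bad)) abort_validation("unknown artifact kind '%s'", bad[1])
  structure(list(n_records = as.integer(n_records),
                 type_mix = type_mix[ALARM_TYPES],
                 true_fraction = true_fraction[ALARM_TYPES],
                 record_seconds = record_seconds, fs = fs,
                 noise_sd = noise_sd, artifact_menu = artifact_menu,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# render Gaussian bumps at given centers (seconds) onto a zero signal
add_bumps <- function(sig, centers, fs, amp, sigma) {
  n <- length(sig)
  half <- ceiling(4 * sigma * fs)
  for (ct in centers) {
    c0 <- round(ct * fs)
    if (c0 + half < 1 || c0 - half > n) next
    idx <- max(1, c0 - half):min(n, c0 + half)
    t <- (idx - 1) / fs - ct
    sig[idx] <- sig[idx] + amp * exp(-t^2 / (2 * sigma^2))
  }
  sig
}

# Beat schedule for one record: normal quasi-periodic rhythm, then (true
# alarms) the type's signature event ending at the record end. Returns beat
# times (s), per-beat "wide" flags (VTA), the event window (s) and the VFB
# oscillation window.
make_beat_schedule <- function(alarm_type, label, seconds) {
  hr0 <- runif(1, 60, 100)
  ev <- NULL; vfb_win <- NULL
  if (label == "true_alarm") {
    ev <- switch(alarm_type,
      ASY = list(kind = "pause", dur = runif(1, 4.5, 5.5)),
      EBR = list(kind = "run", n = 7L, hr = runif(1, 36, 39), wide = FALSE),
      ETC = list(kind = "run", n = 20L, hr = runif(1, 150, 180), wide = FALSE),
      VTA = list(kind = "run", n = 8L, hr = runif(1, 120, 160), wide = TRUE),
      VFB = list(kind = "vfb", dur = runif(1, 4.5, 5.5)))
    ev$dur <- switch(ev$kind, pause = ev$dur, vfb = ev$dur,
                     run = (ev$n - 1) * 60 / ev$hr)
    stopifnot(ev$dur <= 10)
  }
  ev_start <- if (is.null(ev)) seconds else seconds - ev$dur
  # normal rhythm up to the event (or the end)
  beats <- numeric(0); t <- runif(1, 0, 60 / hr0)
  while (t < ev_start - 0.2) {
    beats <- c(beats, t)
    t <- t + 60 / hr0 * (1 + rnorm(1, 0, 0.03))
  }
  wide <- rep(FALSE, length(beats))
  if (!is.null(ev)) {
    if (ev$kind == "run") {
      run <- ev_start + (0:(ev$n - 1)) * 60 / ev$hr
      beats <- c(beats, run)
      wide <- c(wide, rep(ev$wide, ev$n))
    } else if (ev$kind == "vfb") {
      vfb_win <- c(ev_start, seconds)
    } # pause: simply no beats
    ev_win <- c(ev_start, seconds)
  } else {
    ev_win <- NULL
  }
  list(beats = beats, wide = wide, hr0 = hr0, event = ev_win,
       vfb_win = vfb_win)
}

#' Generate one synthetic alarm record with ground truth
#'
#' Baseline rhythm is a quasi-periodic beat train (HR uniform in 60-100 bpm)
#' rendered as Gaussian-bump QRS complexes (with smaller P/T waves) on the
#' ECG channels and smooth pulses lagged 200 ms on PPG/ABP. True alarms end
#' with the type's signature: ASY a >= 4.5 s beat-free pause, EBR a 7-beat
#' run below 40 bpm, ETC a 20-beat run above 140 bpm, VTA an 8-beat run of
#' widened inverted beats above 100 bpm, VFB a 4-6 Hz oscillation replacing
#' beats for >= 4.5 s (pulsatile channels lose their pulse during VFB/VTA).
#' False alarms keep a normal rhythm and one artifact corrupts one channel
#' inside the final 10 s (`lead_flat` flattens the channel from ~12 s before
#' the end onward, emulating a fallen-off lead).
#'
#' @param alarm_type one of [ALARM_TYPES].
#' @param label `"true_alarm"` or `"false_alarm"`.
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer; same seed, bit-identical record.
#' @param record_id id string.
#' @return list with `record` ([waveform_record()]) and `truth` (list:
#'   `beat_times` per-channel 0-based sample indices, `event_window`
#'   0-based half-open sample interval or NULL, `label`, `alarm_type`,
#'   `artifact`, `baseline_hr`).
#' @export
generate_record <- function(alarm_type, label, spec = synthetic_spec(),
                            rng_seed = 1L, record_id = "synth") {
  alarm_type <- normalize_alarm_type(alarm_type)
  label <- normalize_label(label)
  if (label == "unknown") abort_validation("label must be true/false")
  fs <- spec$fs; seconds <- spec$record_seconds
  n <- as.integer(round(fs * seconds))
  if (seconds < 20) abort_validation("record too short for a baseline window")
  with_seed(rng_seed, {
    sch <- make_beat_schedule(alarm_type, label, seconds)
    lag <- 0.2                      # pulse transit delay, s
    pulse_beats <- sch$beats + lag
    pulse_amp <- rep(1, length(pulse_beats))
    if (any(sch$wide)) pulse_amp[sch$wide] <- 0.3   # impaired VT perfusion
    tgrid <- (seq_len(n) - 1) / fs
    ecg <- numeric(n)
    ecg <- add_bumps(ecg, sch$beats[!sch$wide], fs, 1.0, 0.017)       # QRS
    ecg <- add_bumps(ecg, sch$beats[!sch$wide] - 0.16, fs, 0.15, 0.025) # P
    ecg <- add_bumps(ecg, sch$beats[!sch$wide] + 0.28, fs, 0.25, 0.05)  # T
    if (any(sch$wide))
      ecg <- add_bumps(ecg, sch$beats[sch$wide], fs, -1.3, 0.035) # wide VT
    if (!is.null(sch$vfb_win)) {
      f <- runif(1, 4.2, 5.8); phi <- runif(1, 0, 2 * pi)
      in_win <- tgrid >= sch$vfb_win[1] & tgrid < sch$vfb_win[2]
      tau <- tgrid[in_win] - sch$vfb_win[1]
      ecg[in_win] <- ecg[in_win] +
        0.6 * (1 + 0.3 * sin(2 * pi * 0.7 * tau)) * sin(2 * pi * f * tau + phi)
    }
    pulse <- numeric(n)
    pulse <- add_bumps(pulse, pulse_beats, fs, 1, 0.12) * rep(1, 1)
    if (any(sch$wide)) {
      # re-render with attenuated event pulses
      pulse <- numeric(n)
      pulse <- add_bumps(pulse, pulse_beats[!sch$wide], fs, 1, 0.12)
      pulse <- add_bumps(pulse, pulse_beats[sch$wide], fs, 0.3, 0.12)
    }
    if (!is.null(sch$vfb_win)) {
      # circulatory collapse: no pulses after VFB onset (none scheduled)
    }
    resp <- 0.5 * sin(2 * pi * 0.25 * tgrid + runif(1, 0, 2 * pi))

    avail <- c(ECG1 = TRUE, ECG2 = TRUE,
               PPG = runif(1) < 0.7, ABP = runif(1) < 0.6,
               RESP = runif(1) < 0.3)
    if (!avail[["PPG"]] && !avail[["ABP"]])
      avail[[sample(c("PPG", "ABP"), 1)]] <- TRUE

    ch <- matrix(0, 5, n, dimnames = list(ALARM_ROLES, NULL))
    gain <- runif(5, 0.5, 2); offs <- runif(5, -1, 1)
    ch["ECG1", ] <- gain[1] * ecg + offs[1]
    ch["ECG2", ] <- gain[2] * (0.8 * ecg) + offs[2]
    if (avail[["PPG"]]) ch["PPG", ] <- gain[3] * pulse + offs[3]
    if (avail[["ABP"]]) ch["ABP", ] <- gain[4] * (0.6 * pulse + 0.4) + offs[4]
    if (avail[["RESP"]]) ch["RESP", ] <- gain[5] * resp + offs[5]
    if (spec$noise_sd > 0)
      for (r in ALARM_ROLES) if (avail[[r]])
        ch[r, ] <- ch[r, ] + rnorm(n, 0, spec$noise_sd * gain[match(r, ALARM_ROLES)])

    artifact <- NA_character_
    ev_win <- sch$event
    if (label == "false_alarm") {
      artifact <- sample(spec$artifact_menu, 1)
      target <- sample(names(avail)[avail], 1)
      amp <- gain[match(target, ALARM_ROLES)]
      if (artifact == "lead_flat") {
        a0 <- seconds - runif(1, 11, 12.5)
        idx <- which(tgrid >= a0)
        ch[target, idx] <- ch[target, idx[1]]
        win <- c(max(a0, seconds - 10), seconds)
      } else {
        dur <- runif(1, 2, 4)
        a0 <- runif(1, seconds - 10, seconds - dur)
        idx <- which(tgrid >= a0 & tgrid < a0 + dur)
        if (artifact == "noise_burst") {
          ch[target, idx] <- ch[target, idx] + rnorm(length(idx), 0, 2 * amp)
        } else if (artifact == "baseline_wander") {
          ch[target, idx] <- ch[target, idx] +
            3 * amp * sin(2 * pi * 0.3 * (tgrid[idx] - a0))
        } else { # spike_train at ~8 Hz, far above physiologic rates
          sp <- seq(a0, a0 + dur, by = 1 / 8)
          ch[target, ] <- add_bumps(ch[target, ], sp, fs, 2.5 * amp, 0.004)
        }
        win <- c(a0, a0 + dur)
      }
      ev_win <- win
    }

    beat_samples <- function(times) {
      s <- as.integer(round(times * fs))
      s[s >= 0 & s < n]
    }
    beat_times <- list(
      ECG1 = beat_samples(sch$beats), ECG2 = beat_samples(sch$beats),
      PPG = if (avail[["PPG"]]) beat_samples(pulse_beats) else integer(0),
      ABP = if (avail[["ABP"]]) beat_samples(pulse_beats) else integer(0),
      RESP = integer(0))
    truth <- list(
      beat_times = beat_times,
      event_window = if (!is.null(ev_win))
        c(max(0L, as.integer(round(ev_win[1] * fs))),
          min(n, as.integer(round(ev_win[2] * fs)))) else NULL,
      label = label, alarm_type = alarm_type, artifact = artifact,
      baseline_hr = sch$hr0, wide_beats = beat_samples(sch$beats[sch$wide]))
    rec <- waveform_record(record_id, ch, available = avail, fs = fs,
                           alarm_type = alarm_type, onset = n, label = label)
    list(record = rec, truth = truth)
  })
}

# largest-remainder apportionment of n into proportions p (ties: larger
# quota first, then earlier index)
apportion <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), -q, seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a labeled synthetic dataset
#'
#' Per-type counts follow the spec proportions by largest-remainder rounding;
#' within each type the number of true alarms is `round(count *
#' true_fraction)`. Fully seeded from `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (list of `(record, truth)` pairs) and
#'   `manifest` (data.frame `record_id`, `alarm_type`, `label`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  counts <- apportion(spec$n_records, spec$type_mix)
  if (spec$n_records < sum(counts > 0))
    abort_validation("n_records smaller than number of requested strata")
  rows <- list(); records <- list(); k <- 0L
  for (ti in seq_along(ALARM_TYPES)) {
    ty <- ALARM_TYPES[ti]
    n_ty <- counts[ti]
    if (n_ty == 0) next
    n_true <- round(n_ty * spec$true_fraction[[ty]])
    labels <- c(rep("true_alarm", n_true), rep("false_alarm", n_ty - n_true))
    for (j in seq_len(n_ty)) {
      k <- k + 1L
      id <- sprintf("s%04d%s", k, tolower(ty))
      seed <- substream_seed(spec$rng_seed, "record", id)
      records[[k]] <- generate_record(ty, labels[j], spec, rng_seed = seed,
                                      record_id = id)
      rows[[k]] <- data.frame(record_id = id, alarm_type = ty,
                              label = sub("_alarm", "", labels[j]))
    }
  }
  list(records = records, manifest = do.call(rbind, rows))
}

#' Write a generated dataset as WFDB records + manifest + ground truth
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rt in dataset$records) {
    rec <- rt$record
    sig <- t(rec$channels[rec$available, , drop = FALSE])
    colnames(sig) <- c(ECG1 = "II", ECG2 = "V", PPG = "PLETH", ABP = "ABP",
                       RESP = "RESP")[rownames(rec$channels)[rec$available]]
    long <- names(ALARM_TYPE_LONG)[match(rec$alarm_type, ALARM_TYPE_LONG)]
    write_wfdb(sig, file.path(dir, rec$record_id), fs = rec$fs,
               comments = paste(long, ifelse(rec$label == "true_alarm",
                                             "True", "False")))
    tr <- rt$truth
    tr$event_window <- if (is.null(tr$event_window)) NULL else tr$event_window
    jsonlite::write_json(tr, file.path(dir, paste0(rec$record_id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(dataset$manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
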