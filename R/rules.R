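# Reference rule-based alarm verifier: band-pass energy beat detection plus
# the per-type decision logic of the Challenge alarm definitions. Produces
# the scalar R in [0, 1] consumed by the rule-based embedding; any callable
# mapping a record to [0, 1] can be plugged in instead.

#' Detect beats in a single waveform channel
#'
#' FFT band-pass (default 5-25 Hz), squaring, moving-window integration
#' (150 ms) and adaptive-threshold peak picking with a 250 ms refractory
#' period. A channel is `flat` when its amplitude range is below `flat_eps`
#' and `noisy` when pre-refractory threshold crossings exceed a physiologic
#' ceiling (more than 10 candidates in any 2-s window, a 300 bpm
#' equivalent).
#'
#' @param signal numeric amplitude series (0-1 normalized scale assumed for
#'   the default `flat_eps`).
#' @param fs sampling rate in Hz (> 0).
#' @param band band-pass edges in Hz (upper edge clamped below Nyquist);
#'   the spectral mask has a raised-cosine rolloff to avoid ringing.
#' @param flat_eps flat-line range threshold.
#' @param refractory refractory period in seconds.
#' @param rectify use only the positive half-wave before squaring —
#'   appropriate for pulsatile channels, whose high-passed pulses are
#'   biphasic and would otherwise be double-counted.
#' @return list: `beats` (0-based sample indices, strictly increasing),
#'   `quality` (`"usable"`, `"flat"` or `"noisy"`), `widths` (per-beat
#'   half-max width of the squared band-passed energy, in samples), `energy`.
#' @export
detect_beats <- function(signal, fs, band = c(5, 25), flat_eps = 0.01,
                         refractory = 0.25, rectify = FALSE) {
  if (!is.numeric(fs) || fs <= 0) abort_validation("fs must be positive")
  n <- length(signal)
  if (n < 4 * fs) abort_validation("signal shorter than 4 s")
  if (diff(range(signal)) < flat_eps)
    return(list(beats = integer(0), quality = "flat",
                widths = numeric(0), energy = rep(0, n)))
  band[2] <- min(band[2], fs / 2 * 0.98)
  X <- fft(signal - mean(signal))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequencies
  roll <- min(max(band[1] / 2, 0.25), 1.5)   # raised-cosine rolloff width
  up <- pmin(pmax((f - (band[1] - roll)) / roll, 0), 1)
  dn <- pmin(pmax(((band[2] + roll) - f) / roll, 0), 1)
  mask <- 0.5 * (1 - cospi(up)) * 0.5 * (1 - cospi(dn))
  bp <- Re(fft(X * mask, inverse = TRUE)) / n
  # pulsatile mode: smooth unimodal pulses, use the rectified signal itself
  # (squaring + wide integration flattens broad pulses into double peaks)
  e <- if (rectify) pmax(bp, 0) else bp^2
  w <- max(3L, as.integer(round((if (rectify) 0.10 else 0.15) * fs)))
  mwi <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  thr <- (if (rectify) 0.3 else 0.2) * as.numeric(quantile(mwi, 0.98))
  if (thr <= 0)
    return(list(beats = integer(0), quality = "flat",
                widths = numeric(0), energy = e))
  interior <- 2:(n - 1)
  raw_max <- interior[mwi[interior] > thr &
                      mwi[interior] >= mwi[interior - 1] &
                      mwi[interior] > mwi[interior + 1]]
  # candidate peaks: largest-first suppression within 50 ms removes
  # threshold ripple so the candidate rate reflects real oscillations
  suppress <- function(peaks, min_gap) {
    keep <- integer(0)
    for (i in peaks[order(-mwi[peaks])])
      if (!length(keep) || all(abs(keep - i) >= min_gap))
        keep <- c(keep, i)
    sort(keep)
  }
  cand <- suppress(raw_max, 0.05 * fs)
  # physiologic ceiling: > 10 strong candidate peaks in any 2-s window
  # (300 bpm equivalent). Only peaks above half the reference amplitude
  # count (secondary P/T waves must not masquerade as noise), and peaks
  # within 120 ms merge (biphasic wide complexes count once)
  strong <- suppress(raw_max, 0.12 * fs)
  strong <- strong[mwi[strong] > 0.5 * as.numeric(quantile(mwi, 0.98))]
  noisy <- FALSE
  if (length(strong) > 10) {
    k <- length(strong)
    span <- strong[11:k] - strong[1:(k - 10)]
    noisy <- any(span < 2 * fs)
  }
  # broadband noise keeps the integrated energy above threshold almost
  # everywhere; physiologic rhythms are duty-cycled
  if (!rectify && mean(mwi > thr) > 0.8) noisy <- TRUE
  beats <- suppress(cand, refractory * fs)
  half_win <- as.integer(round(0.1 * fs))
  widths <- vapply(beats, function(b) {
    lo <- max(1, b - half_win); hi <- min(n, b + half_win)
    pk <- lo - 1 + which.max(e[lo:hi])     # refine to the energy peak
    h <- e[pk] / 2
    l <- pk; while (l > lo && e[l] > h) l <- l - 1
    r <- pk; while (r < hi && e[r] > h) r <- r + 1
    as.numeric(r - l)
  }, 0)
  list(beats = as.integer(beats - 1L),
       quality = if (noisy) "noisy" else "usable",
       widths = widths, energy = e)
}

# Morphological QRS width: half-max width of the squared, locally
# de-trended raw waveform around each beat. Measured on the un-filtered
# signal because band-pass filtering erodes the width excess of wide
# (ventricular) complexes.
beat_widths_raw <- function(x, fs, beats) {
  half <- as.integer(round(0.15 * fs))
  ctr <- as.integer(round(0.05 * fs))
  vapply(beats, function(b) {
    lo <- max(1, b - half); hi <- min(length(x), b + half)
    v <- (x[lo:hi] - median(x[lo:hi]))^2
    c0 <- b - lo + 1
    w <- max(1, c0 - ctr):min(length(v), c0 + ctr)
    pk <- w[which.max(v[w])]
    h <- v[pk] / 2
    l <- pk; while (l > 1 && v[l] > h) l <- l - 1
    r <- pk; while (r < length(v) && v[r] > h) r <- r + 1
    as.numeric(r - l)
  }, 0)
}

# maximal runs of consecutive beats whose internal RR intervals satisfy
# `cmp(hr)`; returns per-run beat index ranges
hr_runs <- function(beats, fs, cmp) {
  if (length(beats) < 2) return(list())
  hr <- 60 / (diff(beats) / fs)
  ok <- cmp(hr)
  runs <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j + 1)  # beat index range
      i <- j + 1
    }
    i <- i + 1
  }
  runs
}

#' Evaluate the per-type alarm rules on a record
#'
#' Beats are detected on every usable non-RESP channel over the trailing
#' 30 s (band 5-25 Hz on ECG, 0.5-8 Hz on pulsatile channels) and the final
#' 10 s are tested against the record's alarm-type definition: ASY, any 4-s
#' beat-free window; EBR, a run of >= 5 beats below 40 bpm; ETC, a run of
#' > 17 beats above 140 bpm; VTA, a run of > 5 widened beats (energy
#' half-width above 1.5x the channel median) above 100 bpm; VFB, dominant
#' 4-6 Hz spectral power in the trailing window. The score is 0.9 when any
#' usable channel satisfies the definition, 0.1 when at least one usable
#' channel exists but none does, and 0.5 (abstention) when no channel is
#' usable.
#'
#' @param record a [waveform_record()] (pre-processed; raw records are
#'   pre-processed on the fly).
#' @param scores the three output levels `c(negative, abstain, positive)`.
#' @return a `rule_result` list: `score`, `beats`, `hr_series`, `quality`,
#'   `decision_trace`.
#' @export
evaluate_rules <- function(record, scores = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(record, "waveform_record"))
  if (ncol(record$channels) == 0) abort_validation("record has no samples")
  if (!record$preprocessed) record <- preprocess(record)
  fs <- record$fs
  onset <- record$onset
  w30 <- min(as.integer(30 * fs), onset)
  s0 <- onset - w30                       # 0-based start of analysis window
  f10 <- onset - as.integer(10 * fs)      # 0-based start of decision window
  beats_all <- list(); quality <- c(); hr_first <- NULL
  fired <- FALSE; trace <- character(0)
  for (role in c("ECG1", "ECG2", "PPG", "ABP")) {
    if (!record$available[[role]]) { quality[role] <- "flat"; next }
    x <- record$channels[role, (s0 + 1):onset]
    x10 <- record$channels[role, (f10 + 1):onset]
    is_ecg <- role %in% c("ECG1", "ECG2")
    det <- detect_beats(x, fs, band = if (is_ecg) c(5, 25) else c(0.5, 8),
                        rectify = !is_ecg)
    q <- det$quality
    if (q == "usable" && diff(range(x10)) < 0.01) q <- "flat"
    quality[role] <- q
    beats_abs <- det$beats + s0
    beats_all[[role]] <- beats_abs
    if (record$alarm_type == "VFB") {
      # fibrillation looks "noisy" to an energy beat detector; use spectral
      # concentration on the trailing 4.5 s instead of beat statistics
      if (q != "flat" && vfb_band_fraction(x10, fs) >= 0.5) {
        fired <- TRUE
        trace <- c(trace, sprintf("%s: dominant 4-6 Hz oscillation", role))
      }
      next
    }
    if (q != "usable") next
    if (is.null(hr_first) && length(det$beats) >= 2)
      hr_first <- 60 / (diff(det$beats) / fs)
    hit <- switch(record$alarm_type,
      ASY = {
        pts <- sort(c(f10, beats_abs[beats_abs >= f10 & beats_abs < onset], onset))
        if (max(diff(pts)) >= 4 * fs) "asystole: 4 s beat-free window" else NULL
      },
      EBR = {
        runs <- hr_runs(beats_abs, fs, function(h) h < 40)
        ok <- any(vapply(runs, function(r)
          (r[2] - r[1] + 1) >= 5 && beats_abs[r[2]] >= f10, TRUE))
        if (ok) "bradycardia: >=5-beat run under 40 bpm" else NULL
      },
      ETC = {
        runs <- hr_runs(beats_abs, fs, function(h) h > 140)
        ok <- any(vapply(runs, function(r)
          (r[2] - r[1] + 1) > 17 && beats_abs[r[2]] >= f10, TRUE))
        if (ok) "tachycardia: >17-beat run over 140 bpm" else NULL
      },
      VTA = {
        hit <- NULL
        if (length(det$beats) >= 2 && role %in% c("ECG1", "ECG2")) {
          widths <- beat_widths_raw(x, fs, det$beats + 1L)
          wide <- widths > 1.5 * median(widths)
          runs <- hr_runs(beats_abs, fs, function(h) h > 100)
          ok <- any(vapply(runs, function(r) {
            idx <- r[1]:r[2]
            sum(wide[idx]) > 5 && beats_abs[r[2]] >= f10
          }, TRUE))
          if (ok) hit <- "vtach: >5 wide-complex beats over 100 bpm"
        }
        hit
      })
    if (!is.null(hit)) { fired <- TRUE; trace <- c(trace, paste0(role, ": ", hit)) }
  }
  usable <- if (record$alarm_type == "VFB") any(quality != "flat")
            else any(quality == "usable")
  score <- if (!usable) scores[2] else if (fired) scores[3] else scores[1]
  if (!usable) trace <- "abstain: no usable channel"
  if (!length(trace)) trace <- "no rule fired"
  structure(list(score = score, beats = beats_all, hr_series = hr_first,
                 quality = quality, decision_trace = paste(trace, collapse = "; ")),
            class = "rule_result")
}

# fraction of 0.5-25 Hz spectral power lying in the 3.5-6.5 Hz fibrillation
# band, over the trailing 4.5 s
vfb_band_fraction <- function(x, fs, tail_seconds = 4.5) {
  m <- min(length(x), as.integer(tail_seconds * fs))
  x <- x[(length(x) - m + 1):length(x)]
  x <- x - mean(x)
  P <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  f <- pmin(f, fs - f)
  tot <- sum(P[f >= 0.5 & f <= 25])
  if (tot <= 0) return(0)
  sum(P[f >= 3.5 & f <= 6.5]) / tot
}

#' Build a rule scorer from a specification
#'
#' @param spec `"reference"` (the [evaluate_rules()] implementation),
#'   `"constant:<v>"` for a fixed score, `"plugin:<path>"` to source an R
#'   file whose last value is a function, or directly a function taking a
#'   [waveform_record()] and returning a scalar in `[0, 1]`.
#' @return a function `record -> score`.
#' @export
rule_scorer <- function(spec = "reference") {
  fn <- if (is.function(spec)) {
    spec
  } else if (identical(spec, "reference")) {
    function(record) evaluate_rules(record)$score
  } else if (grepl("^constant:", spec)) {
    v <- as.numeric(sub("^constant:", "", spec))
    if (is.na(v)) abort_validation("bad constant rule score '%s'", spec)
    function(record) v
  } else if (grepl("^plugin:", spec)) {
    path <- sub("^plugin:", "", spec)
    if (!file.exists(path)) abort_validation("plugin file not found: %s", path)
    f <- source(path, local = new.env())$value
    if (!is.function(f)) abort_validation("plugin must evaluate to a function")
    f
  } else {
    abort_validation("unknown rule scorer '%s'", spec)
  }
  function(record) {
    s <- fn(record)
    if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1)
      abort_validation("rule scorer must return a scalar in [0, 1]")
    as.numeric(s)
  }
}
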