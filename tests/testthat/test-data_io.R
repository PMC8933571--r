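# Record construction, WFDB round trips, pre-processing, segment pairs and
# fold splitting.

make_rec <- function(n = 6000, fs = 250, onset = n, type = "VTA",
                     label = "true_alarm", seed = 1) {
  set.seed(seed)
  ch <- matrix(rnorm(5 * n), 5, n, dimnames = list(ALARM_ROLES, NULL))
  ch["RESP", ] <- 0
  waveform_record("r1", ch, fs = fs, alarm_type = type, onset = onset,
                  label = label)
}

test_that("read_record maps roles, zero-fills missing channels, validates", {
  dir <- withr::local_tempdir()
  n <- 75000
  set.seed(9)
  sig <- cbind(II = rnorm(n), PLETH = rnorm(n))
  write_wfdb(sig, file.path(dir, "rec1"), fs = 250)
  rec <- read_record(file.path(dir, "rec1"),
                     list(alarm_type = "Ventricular_Tachycardia",
                          label = "true"),
                     onset_seconds = 300)
  expect_s3_class(rec, "waveform_record")
  expect_equal(rec$onset, 75000)
  expect_equal(rec$alarm_type, "VTA")
  expect_equal(rec$label, "true_alarm")
  expect_true(rec$available[["ECG1"]])
  expect_true(rec$available[["PPG"]])
  expect_false(rec$available[["ECG2"]])
  expect_false(rec$available[["ABP"]])
  expect_false(rec$available[["RESP"]])
  # missing roles present and zero-filled
  expect_true(all(rec$channels["ABP", ] == 0))
  expect_true(all(rec$channels["RESP", ] == 0))
  # quantization at the declared gain
  expect_equal(rec$channels["ECG1", ], sig[, "II"], tolerance = 1e-3)

  # unknown alarm type rejected
  expect_error(read_record(file.path(dir, "rec1"),
                           list(alarm_type = "Flutter", label = "true")),
               class = "alarmsieve_validation_error")
  # record shorter than requested onset rejected
  write_wfdb(sig[1:1000, ], file.path(dir, "rec2"), fs = 250)
  expect_error(read_record(file.path(dir, "rec2"),
                           list(alarm_type = "VTA", label = "true"),
                           onset_seconds = 300),
               class = "alarmsieve_validation_error")
})

test_that("WFDB and fixture containers round-trip", {
  dir <- withr::local_tempdir()
  set.seed(4)
  sig <- cbind(II = round(rnorm(500), 3), V = round(rnorm(500), 3))
  write_wfdb(sig, file.path(dir, "rt"), fs = 250, gains = 1000)
  w <- read_wfdb(file.path(dir, "rt"))
  expect_equal(w$fs, 250)
  expect_equal(w$sig_names, c("II", "V"))
  expect_equal(unname(w$signals[, 1]), unname(sig[, 1]), tolerance = 1e-9)

  rec <- make_rec(n = 5000)
  write_fixture(rec, file.path(dir, "fx"))
  back <- read_fixture(file.path(dir, "fx"))
  expect_identical(back$channels, rec$channels)  # bit-exact
  expect_equal(back$alarm_type, rec$alarm_type)
  expect_equal(back$onset, rec$onset)
})

test_that("preprocess truncates, scales to [0,1] and is idempotent", {
  n <- 6000
  rec <- make_rec(n = n + 500, onset = n)
  # a channel with known range on [0, onset): min -2, max 6 -> (x+2)/8
  x <- c(seq(-2, 6, length.out = n), rep(0, 500))
  rec$channels["ECG1", ] <- x
  pp <- preprocess(rec)
  expect_equal(ncol(pp$channels), n)
  expect_equal(pp$channels["ECG1", ], (x[1:n] + 2) / 8, tolerance = 1e-12)
  # all channels in [0,1]; non-constant available channels attain both
  for (r in ALARM_ROLES) {
    v <- pp$channels[r, ]
    expect_true(all(v >= 0 & v <= 1))
    if (pp$available[[r]]) {
      expect_equal(min(v), 0)
      expect_equal(max(v), 1)
    }
  }
  # constant channel maps to zeros
  rec2 <- make_rec(n = 6000)
  rec2$channels["ECG2", ] <- 5.0
  rec2$available[["ECG2"]] <- TRUE
  pp2 <- preprocess(rec2)
  expect_true(all(pp2$channels["ECG2", ] == 0))
  # idempotence
  expect_equal(preprocess(pp)$channels, pp$channels, tolerance = 1e-12)
  # degenerate onset
  rec3 <- make_rec(); rec3$onset <- 0L
  expect_error(preprocess(rec3), class = "alarmsieve_validation_error")
})

test_that("extract_pair window arithmetic, determinism and bounds", {
  rec <- preprocess(make_rec(n = 75000, fs = 250))
  p <- extract_pair(rec, rng_seed = 7)
  expect_equal(dim(p$alarm_segment), c(5, 2500))
  expect_equal(dim(p$baseline_segment), c(5, 2500))
  # alarm window is exactly [onset - 2500, onset)
  expect_identical(p$alarm_segment,
                   rec$channels[, (75000 - 2500 + 1):75000])
  # baseline lies entirely before onset - fs*10
  expect_true(p$baseline_start >= 0)
  expect_true(p$baseline_start + 2500 <= 75000 - 2500)
  expect_identical(p$baseline_segment,
                   rec$channels[, (p$baseline_start + 1):(p$baseline_start + 2500)])
  expect_equal(sum(p$alarm_onehot), 1)
  expect_equal(which(p$alarm_onehot == 1), match("VTA", ALARM_TYPES))
  # same seed, same pair
  p2 <- extract_pair(rec, rng_seed = 7)
  expect_identical(p2$baseline_start, p$baseline_start)
  # different seeds explore the legal range
  starts <- vapply(1:50, function(s) extract_pair(rec, s)$baseline_start, 1L)
  expect_true(length(unique(starts)) > 10)
  expect_true(all(starts >= 0 & starts <= 70000))
  # boundary: onset exactly 2*T -> only legal start is 0
  recb <- preprocess(make_rec(n = 5000, fs = 250))
  for (s in 1:5) expect_equal(extract_pair(recb, s)$baseline_start, 0L)
  # onset below 2*T is rejected
  recc <- preprocess(make_rec(n = 4999, fs = 250))
  expect_error(extract_pair(recc, 1), class = "alarmsieve_validation_error")
})

test_that("make_folds partitions, balances and stratifies", {
  set.seed(8)
  n <- 750
  ids <- sprintf("r%03d", 1:n)
  types <- sample(ALARM_TYPES, n, replace = TRUE, prob = c(.17, .11, .19, .46, .07))
  labels <- sample(c("true_alarm", "false_alarm"), n, replace = TRUE)
  folds <- make_folds(ids, labels, types, k = 5, rng_seed = 1)
  expect_length(folds, 5)
  expect_equal(vapply(folds, length, 1L), rep(150L, 5))
  expect_setequal(unlist(folds), ids)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  # per-stratum counts differ by <= 1 across folds
  strata <- paste(types, labels)
  for (s in unique(strata)) {
    cnt <- vapply(folds, function(f) sum(strata[match(f, ids)] == s), 1L)
    expect_lte(max(cnt) - min(cnt), 1)
  }
  # exact stratification of a single homogeneous stratum
  f10 <- make_folds(sprintf("x%02d", 1:10), rep("true_alarm", 10),
                    rep("ASY", 10), k = 5, rng_seed = 2)
  expect_equal(vapply(f10, length, 1L), rep(2L, 5))
  # reproducible
  expect_identical(make_folds(ids, labels, types, 5, rng_seed = 9),
                   make_folds(ids, labels, types, 5, rng_seed = 9))
  expect_error(make_folds(ids, labels, types, k = 1),
               class = "alarmsieve_validation_error")
})
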