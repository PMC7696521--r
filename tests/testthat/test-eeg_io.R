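test_that("min-max normalization maps channels onto [0, 1]", {
  rec <- eeg_recording(
    matrix(c(2, 4, 6, 0, 1, 0.5), ncol = 2,
           dimnames = list(NULL, c("Fp1", "Fp2"))), rate = 1)
  out <- minmax_normalize(rec)
  expect_equal(out$samples[, "Fp1"], c(0, 0.5, 1))
  expect_equal(range(out$samples[, "Fp2"]), c(0, 1))
  # idempotent on already-normalized extremes
  expect_equal(minmax_normalize(out)$samples, out$samples)
  # constant channel is an error naming the channel
  bad <- eeg_recording(
    matrix(c(1, 1, 1, 0, 1, 2), ncol = 2,
           dimnames = list(NULL, c("Fp1", "Fp2"))), rate = 1)
  expect_error(minmax_normalize(bad), "Fp1")
})

test_that("normalization is invariant under positive affine transforms", {
  set.seed(3)
  x <- matrix(rnorm(512 * 3), ncol = 3,
              dimnames = list(NULL, c("F3", "F4", "Cz")))
  rec <- eeg_recording(x, rate = 128)
  rec2 <- rec
  rec2$samples <- 3.7 * rec2$samples + 11
  expect_equal(minmax_normalize(rec)$samples,
               minmax_normalize(rec2)$samples, tolerance = 1e-12)
})

test_that("segmentation yields non-overlapping epochs, drops remainder", {
  rec <- make_tone_recording(secs = 300 / 60)  # 5 s
  ep <- segment_epochs(rec, 4)
  expect_equal(n_epochs(ep), 1L)
  expect_equal(dim(ep$samples)[1L], 1024L)
  # 5-min recording at 256 Hz: exactly 75 epochs
  long <- eeg_recording(
    matrix(rnorm(300 * 256), ncol = 1, dimnames = list(NULL, "C3")),
    rate = 256, subject_id = "s", group_label = "control")
  eps <- segment_epochs(long, 4)
  expect_equal(n_epochs(eps), 75L)
  expect_equal(eps$manifest$epoch_index, 0:74)
  expect_true(all(eps$manifest$group_label == "control"))
  # segment-then-concatenate reproduces the first 4*floor(T/4) seconds
  rebuilt <- do.call(rbind, lapply(seq_len(75), function(i)
    epoch_matrix(eps, i)))
  expect_identical(as.vector(rebuilt), as.vector(long$samples[1:(75 * 1024), ,
                                                              drop = FALSE]))
  # too short: zero epochs with a warning, not an error
  short <- eeg_recording(
    matrix(rnorm(3 * 256), ncol = 1, dimnames = list(NULL, "C3")),
    rate = 256)
  expect_warning(ep0 <- segment_epochs(short, 4), "shorter")
  expect_equal(n_epochs(ep0), 0L)
})

test_that("band-pass/notch filtering attenuates out-of-band components", {
  rate <- 256
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  x <- cbind(mains = sin(2 * pi * 50 * t),
             alpha = sin(2 * pi * 10 * t),
             dc = rep(1, length(t)) + 0.01 * sin(2 * pi * 10 * t))
  rec <- eeg_recording(x, rate = rate)
  out <- bandpass_notch(rec, 0.5, 70, notch = 50)
  # 50 Hz tone: power at 50 Hz down by >= 20 dB
  pow50 <- function(v) {
    # fine grid (4 s windows) so the 50 Hz bin is resolved
    sp <- welch_psd(matrix(v, dimnames = list(NULL, list("a"))), rate,
                    band = eeg_band("wide", 0.5, 60), window_rule = "band")
    sp$S[which.min(abs(sp$freqs - 50)), 1]
  }
  expect_lt(pow50(out$samples[, "mains"]) / pow50(x[, "mains"]), 0.01)
  # passband tone: RMS preserved within 5 %
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(rms(out$samples[, "alpha"]) / rms(x[, "alpha"]), 1,
               tolerance = 0.05)
  # DC removed
  expect_lt(abs(mean(out$samples[, "dc"])), 0.05)
  expect_error(bandpass_notch(rec, 70, 0.5), "band edges")
})

test_that("ICA hook is identity by default and shape-checked", {
  rec <- make_tone_recording(secs = 2)
  expect_identical(apply_ica_hook(rec), rec)
  ident <- function(r) { r$samples <- r$samples * 1; r }
  expect_equal(apply_ica_hook(rec, ident)$samples, rec$samples)
  dropper <- function(r) { r$samples <- r$samples[, -1]; r }
  expect_error(apply_ica_hook(rec, dropper), "preserve")
})

test_that("EDF round trip preserves samples within 16-bit quantization", {
  spec <- synth_spec(n_subjects_per_group = 1, duration = 10, seed = 4)
  rec <- simulate_recording(spec, "mdd", "rt01")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path, group_label = "mdd")
  expect_identical(channel_labels(back), default_montage())
  expect_equal(back$rate, 256)
  # quantization step is range/65535 per channel
  for (ch in default_montage()) {
    step <- diff(range(rec$samples[, ch])) / 65535
    expect_lt(max(abs(back$samples[, ch] - rec$samples[, ch])), step)
  }
  expect_equal(back$subject_id, "rt01")
  unlink(path)
})

test_that("read_edf reorders channels to montage and tolerates decoration", {
  # write channels in scrambled order with vendor-style labels, plus midline
  spec <- synth_spec(n_subjects_per_group = 1, duration = 5, seed = 8)
  rec <- simulate_recording(spec, "control", "sc01")
  scramble <- c(sample(default_montage()), "Fz", "Cz", "Pz")
  set.seed(2)
  x <- cbind(rec$samples[, intersect(scramble, default_montage())],
             Fz = rnorm(nrow(rec$samples)), Cz = rnorm(nrow(rec$samples)),
             Pz = rnorm(nrow(rec$samples)))
  colnames(x) <- paste0("EEG ", colnames(x), "-LE")
  decorated <- eeg_recording(x, rate = 256, subject_id = "sc01")
  path <- tempfile(fileext = ".edf")
  write_edf(decorated, path)
  back <- read_edf(path)
  expect_identical(channel_labels(back), default_montage())
  for (ch in default_montage()) {
    step <- diff(range(rec$samples[, ch])) / 65535
    expect_lt(max(abs(back$samples[, ch] - rec$samples[, ch])), step)
  }
  unlink(path)
})

test_that("read_edf reports missing montage channels by name", {
  spec <- synth_spec(n_subjects_per_group = 1, duration = 5, seed = 8)
  rec <- simulate_recording(spec, "control", "sc02")
  rec$samples <- rec$samples[, setdiff(default_montage(), "T6")]
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_edf(path), "T6")
  unlink(path)
  expect_error(read_edf(tempfile(fileext = ".edf")), "cannot read")
})

test_that("an independent EDF reader recovers the written signal", {
  # cross-check the hand-written EDF writer against python-mne
  has_mne <- tryCatch({
    status <- suppressWarnings(system2("python", c("-c", "import mne"),
                                       stdout = FALSE, stderr = FALSE))
    identical(status, 0L)
  }, error = function(e) FALSE)
  if (!has_mne) {
    succeed("python/mne unavailable; round-trip oracle covered elsewhere")
    return(invisible(NULL))
  }
  spec <- synth_spec(n_subjects_per_group = 1, duration = 5, seed = 21)
  rec <- simulate_recording(spec, "mdd", "mne01")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  out_csv <- tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(%s, preload=True, verbose='ERROR')\n",
    "d = raw.get_data()\n",
    "np.savetxt(%s, d[:2, :1280].T, delimiter=',')\n"),
    deparse(path), deparse(out_csv))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  got <- as.matrix(utils::read.csv(out_csv, header = FALSE))
  # mne scales EDF 'uV' channels to volts
  for (j in 1:2) {
    step <- diff(range(rec$samples[, j])) / 65535
    expect_lt(max(abs(got[, j] * 1e6 - rec$samples[1:1280, j])), 2 * step)
  }
  unlink(c(path, out_csv, sf))
})
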