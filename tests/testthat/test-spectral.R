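test_that("Welch PSD peaks at the tone frequency and follows the window rule", {
  m <- make_tone_epoch(freq = 10)
  # per-band rule: alpha (f1 = 8) gives a 2/8 = 0.25 s (64-sample) window
  sp <- welch_psd(m, 256, band = "alpha", window_rule = "band")
  expect_equal(sp$window_sec, 0.25)
  expect_equal(sp$overlap, 0.5)
  # the peak sits at a grid frequency nearest to 10 Hz (4 Hz grid: a tie
  # between 8 and 12, both at distance 2)
  expect_equal(abs(sp$freqs[which.max(sp$S[, 1])] - 10),
               min(abs(sp$freqs - 10)))
  # delta rule caps at the epoch duration: single 4 s window
  spd <- welch_psd(m, 256, band = "delta", window_rule = "band")
  expect_equal(spd$window_sec, 4)
  # total rule uses the 0.5 Hz edge: also the whole 4 s epoch
  spt <- welch_psd(m, 256, band = "alpha", window_rule = "total")
  expect_equal(spt$window_sec, 4)
  expect_equal(spt$freqs[which.max(spt$S[, 1])], 10)
  # PSD is non-negative on a grid that starts at zero
  expect_true(all(sp$S >= 0))
  expect_equal(sp$freqs[1L], 0)
  expect_true(all(diff(sp$freqs) > 0))
})

test_that("white-noise PSD is approximately flat across bands", {
  set.seed(42)
  ratios <- replicate(100, {
    m <- matrix(rnorm(1024), dimnames = list(NULL, list("w")))
    sp <- welch_psd(m, 256, band = "alpha", window_rule = "band")
    in_alpha <- sp$freqs >= 8 & sp$freqs <= 13
    above <- sp$freqs >= 13 & sp$freqs <= 18
    mean(sp$S[in_alpha, 1]) / mean(sp$S[above, 1])
  })
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.25)
})

test_that("Simpson band power is exact on low-order polynomials", {
  # constant S = 1 over [8, 13]: integral 5
  sp <- structure(list(freqs = seq(8, 13, by = 0.25),
                       S = matrix(1, 21, 1)), class = "band_spectrum")
  expect_equal(unname(band_power(sp, eeg_band("alpha", 8, 13))), 5)
  # linear S = f on 5 points: Simpson exact
  sp2 <- structure(list(freqs = seq(0.5, 2.5, by = 0.5),
                        S = matrix(seq(0.5, 2.5, by = 0.5), 5, 1)),
                   class = "band_spectrum")
  expect_equal(unname(band_power(sp2, eeg_band("b", 0.5, 2.5))), 3)
  # quadratic is also integrated exactly on an odd grid
  f <- seq(0.5, 2.5, by = 0.25)
  sp3 <- structure(list(freqs = f, S = matrix(f^2)),
                   class = "band_spectrum")
  expect_equal(unname(band_power(sp3, eeg_band("b", 0.5, 2.5))),
               (2.5^3 - 0.5^3) / 3)
  # fewer than 3 points: trapezoid fallback with warning
  sp4 <- structure(list(freqs = c(8, 12), S = matrix(c(1, 1))),
                   class = "band_spectrum")
  expect_warning(bp <- band_power(sp4, eeg_band("alpha", 8, 13)),
                 "trapezoid")
  expect_equal(unname(bp), 4)
})

test_that("Simpson agrees with a 10x-refined trapezoid oracle on smooth spectra", {
  set.seed(7)
  for (rep in 1:5) {
    # smooth random spectrum: sum of broad gaussian bumps on a 0.25 Hz grid
    f <- seq(0, 30, by = 0.25)
    S <- rowSums(sapply(1:4, function(i) {
      a <- runif(1, 0.5, 2); mu <- runif(1, 2, 28); s <- runif(1, 2, 6)
      a * exp(-(f - mu)^2 / (2 * s^2))
    })) + 0.1
    spc <- structure(list(freqs = f, S = matrix(S)),
                     class = "band_spectrum")
    got <- unname(band_power(spc, eeg_band("alpha", 8, 13)))
    # oracle: dense trapezoid on a 10x-refined spline interpolation
    ff <- seq(8, 13, length.out = 10 * sum(f >= 8 & f <= 13))
    Sf <- stats::spline(f, S, xout = ff)$y
    oracle <- sum(diff(ff) * (head(Sf, -1) + Sf[-1]) / 2)
    expect_equal(got, oracle, tolerance = 0.01)
  }
})

test_that("relative power concentrates on a pure tone and is scale-free", {
  m <- make_tone_epoch(freq = 10)
  rp <- relative_power(m, 256, "alpha")
  expect_gte(unname(rp[1]), 0.95)
  # scaling the channel leaves the ratio unchanged to machine precision
  rp2 <- relative_power(m * 7.3, 256, "alpha")
  expect_equal(unname(rp), unname(rp2), tolerance = 1e-12)
})

test_that("white-noise relative power matches the flat-spectrum expectation", {
  set.seed(11)
  vals <- replicate(100, {
    m <- matrix(rnorm(1024), dimnames = list(NULL, list("w")))
    unname(relative_power(m, 256, "alpha"))
  })
  expect_lt(abs(mean(vals) - 5 / 29.5), 0.03)
})

test_that("band relative powers on a shared spectrum sum to ~1", {
  set.seed(13)
  spec <- synth_spec(n_subjects_per_group = 1, duration = 8, seed = 31)
  rec <- simulate_recording(spec, "control", "sum01")
  m <- epoch_matrix(segment_epochs(rec), 1)
  sp <- welch_psd(m, 256, band = total_band(), window_rule = "band")
  total <- band_power(sp, total_band())
  parts <- sapply(c("delta", "theta", "alpha", "beta"), function(b)
    band_power(sp, b))
  # closed intervals share edge frequencies, so the sum slightly exceeds 1;
  # Simpson edge weighting keeps the excess small on these spectra
  sums <- rowSums(parts) / total
  expect_true(all(sums > 0.9 & sums < 1.1))
})

test_that("degenerate spectra are rejected with channel names", {
  z <- matrix(0, 1024, 1, dimnames = list(NULL, "Cz"))
  expect_error(relative_power(z, 256, "alpha"), "Cz")
  expect_error(relative_power(make_tone_epoch(), 256,
                              eeg_band("x", 0.1, 31)), "within the total")
})
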