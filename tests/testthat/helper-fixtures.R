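# Fixtures built in code: small recordings and toy image sets.

# A deterministic multi-channel recording with known sinusoidal content.
make_tone_recording <- function(freqs = rep(10, 16), secs = 8, rate = 256,
                                labels = default_montage(),
                                noise_sd = 1e-4, seed = 99) {
  set.seed(seed)
  t <- seq(0, secs - 1 / rate, by = 1 / rate)
  x <- sapply(seq_along(labels), function(j) {
    sin(2 * pi * freqs[j] * t) + rnorm(length(t), sd = noise_sd)
  })
  colnames(x) <- labels
  eeg_recording(x, rate = rate, subject_id = "tone")
}

# A single-channel epoch of pure tone plus tiny dither.
make_tone_epoch <- function(freq = 10, secs = 4, rate = 256,
                            noise_sd = 1e-4, seed = 1) {
  set.seed(seed)
  t <- seq(0, secs - 1 / rate, by = 1 / rate)
  m <- matrix(sin(2 * pi * freq * t) + rnorm(length(t), sd = noise_sd),
              ncol = 1, dimnames = list(NULL, "Cz"))
  m
}

# Toy linearly separable image set: MDD-like images have elevated relative
# power on the left-hemisphere channels (red rows / blue columns).
make_separable_images <- function(n = 64, shift = 0.3, seed = 1) {
  set.seed(seed)
  x <- t(sapply(seq_len(n), function(i) {
    base <- runif(16, 0.2, 0.4)
    if (i <= n / 2) base[1:8] <- base[1:8] + shift
    m <- asymmetry_matrix(stats::setNames(base, default_montage()))
    as.vector(unclass(render_asym_image(m)))
  }))
  labels <- rep(c(1L, 0L), each = n / 2)
  image_set(x, data.frame(
    subject_id = sprintf("s%02d", rep(seq_len(n / 8), length.out = n)),
    group_label = ifelse(labels == 1L, "mdd", "control"),
    label = labels, stringsAsFactors = FALSE))
}

# Random images with random labels (null material for CV checks).
make_null_images <- function(n = 120, seed = 5) {
  set.seed(seed)
  x <- matrix(runif(n * 12288), n)
  labels <- rep(c(1L, 0L), length.out = n)
  image_set(x, data.frame(
    subject_id = sprintf("s%02d", rep(seq_len(n / 10), length.out = n)),
    group_label = ifelse(labels == 1L, "mdd", "control"),
    label = sample(labels), stringsAsFactors = FALSE))
}
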