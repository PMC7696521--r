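# Seeded synthetic EEG with controllable band structure and
# group-dependent hemispheric alpha asymmetry.

#' Specification for the synthetic EEG generator
#'
#' Each synthetic channel is a sum of band-limited Gaussian noise in the
#' four canonical bands (white noise spectrally confined to the band and
#' scaled to the requested RMS amplitude) plus a pink (1/f) broadband
#' floor.  For the MDD-like group, the alpha amplitude of the eight
#' left-hemisphere channels is multiplied by `asymmetry_effect`
#' (`effect = 1` means no group difference), emulating the hemispheric
#' alpha asymmetry reported as a depression biomarker.
#'
#' @param n_subjects_per_group Subjects per group (default 5).
#' @param duration Recording length in seconds (default 300, i.e. 75
#'   four-second epochs).
#' @param rate Sampling rate in Hz (default 256).
#' @param montage Channel order (default [default_montage()]).
#' @param band_amplitudes Named RMS amplitudes (arbitrary units, microvolt
#'   nominal) for delta/theta/alpha/beta oscillatory components.
#' @param noise_amplitude RMS of the pink-noise floor.
#' @param asymmetry_effect Multiplicative alpha-amplitude factor for
#'   left-hemisphere channels of the MDD-like group (> 0).
#' @param condition Condition tag carried on recordings (default `"EC"`).
#' @param seed Master integer seed; per-subject streams are derived
#'   deterministically from `(seed, subject_id, group)`.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects_per_group = 5L, duration = 300,
                       rate = 256, montage = default_montage(),
                       band_amplitudes = c(delta = 20, theta = 10,
                                           alpha = 20, beta = 8),
                       noise_amplitude = 10, asymmetry_effect = 1,
                       condition = "EC", seed = 1L) {
  validate_montage(montage, 16L)
  stopifnot(all(band_amplitudes >= 0), noise_amplitude >= 0,
            asymmetry_effect > 0, duration > 0, rate > 0,
            n_subjects_per_group >= 1)
  if (!all(c("delta", "theta", "alpha", "beta") %in%
           names(band_amplitudes))) {
    stop("band_amplitudes must name delta, theta, alpha and beta",
         call. = FALSE)
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         duration = duration, rate = rate, montage = montage,
         band_amplitudes = band_amplitudes,
         noise_amplitude = noise_amplitude,
         asymmetry_effect = asymmetry_effect,
         condition = condition, seed = as.integer(seed)),
    class = "synth_spec")
}

# Deterministic 31-bit sub-seed from (seed, subject_id, group).
sub_seed <- function(seed, subject_id, group) {
  h <- as.numeric(seed) %% 2147483629
  for (ch in utf8ToInt(paste(subject_id, group, sep = "/"))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

# Gaussian noise spectrally confined to [f1, f2] and scaled to unit RMS.
band_limited_noise <- function(n, rate, f1, f2) {
  x <- stats::rnorm(n)
  ft <- stats::fft(x)
  f <- seq(0L, n - 1L) * rate / n
  f <- pmin(f, rate - f)                 # two-sided frequency axis
  ft[f < f1 | f > f2] <- 0
  y <- Re(stats::fft(ft, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

# Pink (1/f) noise, unit RMS.
pink_noise <- function(n, rate) {
  x <- stats::rnorm(n)
  ft <- stats::fft(x)
  f <- seq(0L, n - 1L) * rate / n
  f <- pmin(f, rate - f)
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::fft(ft * scale, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' Simulate one synthetic EEG recording
#'
#' Fully determined by `(spec$seed, subject_id, group)`: the same triple
#' always reproduces the same samples, and adding subjects never changes
#' existing ones.
#'
#' @param spec A [synth_spec()].
#' @param group `"mdd"` or `"control"`.
#' @param subject_id Subject identifier string.
#' @return An [eeg_recording()] with `length(spec$montage)` channels.
#' @export
simulate_recording <- function(spec, group = c("control", "mdd"),
                               subject_id = "S01") {
  stopifnot(inherits(spec, "synth_spec"))
  group <- match.arg(group)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(sub_seed(spec$seed, subject_id, group))
  n <- as.integer(round(spec$duration * spec$rate))
  bands <- eeg_bands()
  lefts <- left_channels()
  x <- matrix(0, nrow = n, ncol = length(spec$montage))
  colnames(x) <- spec$montage
  for (j in seq_along(spec$montage)) {
    ch <- spec$montage[j]
    sig <- spec$noise_amplitude * pink_noise(n, spec$rate)
    for (bn in names(bands)) {
      amp <- spec$band_amplitudes[[bn]]
      if (bn == "alpha" && group == "mdd" && ch %in% lefts) {
        amp <- amp * spec$asymmetry_effect
      }
      if (amp > 0) {
        sig <- sig + amp *
          band_limited_noise(n, spec$rate, bands[[bn]]$f1, bands[[bn]]$f2)
      }
    }
    x[, j] <- sig
  }
  eeg_recording(x, rate = spec$rate, group_label = group,
                condition = spec$condition, subject_id = subject_id)
}

#' Simulate a full two-group dataset
#'
#' @param spec A [synth_spec()].
#' @return List of [eeg_recording()]s: `n_subjects_per_group` MDD-like
#'   (`mdd01`, `mdd02`, ...) and as many control-like (`ctl01`, ...).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ids <- sprintf("%02d", seq_len(spec$n_subjects_per_group))
  c(lapply(paste0("mdd", ids), function(id)
      simulate_recording(spec, "mdd", id)),
    lapply(paste0("ctl", ids), function(id)
      simulate_recording(spec, "control", id)))
}

#' Construct a labeled image set
#'
#' The container consumed by [train_cnn()] and [cross_validate()]:
#' flattened image rows plus a manifest with one row per image.
#'
#' @param images List of 64x64x3 arrays, an n x 64 x 64 x 3 array, or a
#'   pre-flattened n x 12288 matrix.
#' @param manifest Data frame with at least `group_label`; a numeric
#'   `label` column (MDD-like = 1, control = 0) is derived when absent.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, manifest) {
  x <- if (is.matrix(images) && ncol(images) == 64L * 64L * 3L) images
       else image_matrix(images)
  stopifnot(is.data.frame(manifest), nrow(manifest) == nrow(x))
  if (is.null(manifest$label)) {
    manifest$label <- as.integer(manifest$group_label == "mdd")
  }
  structure(list(x = x, manifest = manifest), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images (64x64x3), %d positive / %d negative\n",
              nrow(x$x), sum(x$manifest$label == 1L),
              sum(x$manifest$label == 0L)))
  invisible(x)
}

#' Recover one image of an image set as a 64x64x3 array
#' @param images An `image_set`.
#' @param i Image position.
#' @return An `asym_image` array.
#' @export
image_tensor <- function(images, i) {
  structure(array(images$x[i, ], dim = c(64L, 64L, 3L)),
            class = "asym_image")
}

#' Run the full synthetic benchmark pipeline
#'
#' simulate -> normalize -> (optional ICA hook) -> segment -> relative
#' power -> asymmetry matrix -> image, for every subject of both groups,
#' producing the labeled image set the classifier trains on.
#'
#' @param spec A [synth_spec()].
#' @param band Canonical band name or [eeg_band()] (default `"alpha"`).
#' @param epoch_duration Epoch length in seconds (default 4).
#' @param window_rule Passed to [relative_power()].
#' @param ica_hook Optional artifact-removal hook, see [apply_ica_hook()].
#' @return An `image_set` whose manifest records per-image provenance
#'   (subject, epoch index, band, group, label).
#' @export
make_benchmark <- function(spec, band = "alpha", epoch_duration = 4,
                           window_rule = "total", ica_hook = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  band <- as_band(band)
  recs <- simulate_dataset(spec)
  rows <- list()
  mats <- list()
  k <- 0L
  for (rec in recs) {
    rec <- minmax_normalize(rec)
    rec <- apply_ica_hook(rec, ica_hook)
    epochs <- segment_epochs(rec, epoch_duration)
    for (i in seq_len(n_epochs(epochs))) {
      rp <- relative_power(epoch_matrix(epochs, i), epochs$rate, band,
                           window_rule = window_rule)
      m <- asymmetry_matrix(rp, order = spec$montage, band = band$name,
                            subject_id = rec$subject_id,
                            epoch_index = i - 1L,
                            group_label = rec$group_label)
      k <- k + 1L
      mats[[k]] <- as.vector(unclass(render_asym_image(m)))
      rows[[k]] <- data.frame(
        subject_id = rec$subject_id, group_label = rec$group_label,
        condition = rec$condition, epoch_index = i - 1L,
        band = band$name,
        label = as.integer(rec$group_label == "mdd"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  image_set(do.call(rbind, mats), manifest)
}

#' Write every image of an image set as PNG files
#'
#' File names follow the `<subject>_<epoch>_<band>_<label>.png` convention.
#'
#' @param images An `image_set`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_image_set <- function(images, outdir) {
  stopifnot(inherits(images, "image_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mf <- images$manifest
  paths <- character(nrow(mf))
  for (i in seq_len(nrow(mf))) {
    paths[i] <- file.path(outdir, asym_png_name(
      mf$subject_id[i], mf$epoch_index[i], mf$band[i], mf$group_label[i]))
    write_asym_png(image_tensor(images, i), paths[i])
  }
  invisible(paths)
}
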