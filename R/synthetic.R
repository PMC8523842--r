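#' Default 15-electrode hybrid-BCI montage
#'
#' Eleven motor/central electrodes followed by four parieto-occipital ones,
#' in the order used throughout: the first block carries the motor-imagery
#' information, the last block the SSVEP response.
#'
#' @return Character vector of 15 electrode names.
#' @export
default_montage <- function() {
  c("FC3", "FC4", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP3", "CP4",
    "POz", "O1", "Oz", "O2")
}

#' Synthetic hybrid-EEG configuration
#'
#' Defaults emulate the recording conditions the package targets: 256 Hz
#' sampling, the 15-electrode montage of [default_montage()], 2 s trials,
#' 1/f background noise, a 10 Hz mu rhythm on C3/C4 whose amplitude is
#' attenuated (ERD) contralaterally to the imagined hand, and sinusoidal
#' SSVEP responses with harmonics on the occipital electrodes.
#'
#' @param fs Sampling rate (Hz).
#' @param montage Electrode names.
#' @param trial_sec Trial duration (s).
#' @param mi_trials_per_class MI trials per class ("left", "right").
#' @param ssvep_trials_per_class SSVEP trials per stimulus frequency.
#' @param mu_freq Mu-rhythm frequency (Hz).
#' @param mu_amp Mu amplitude relative to unit-variance noise.
#' @param erd_depth Fractional amplitude attenuation of the contralateral mu
#'   rhythm, in `[0, 1]`; 0 plants no class difference.
#' @param mi_channels Informative motor electrodes.
#' @param ssvep_freqs Stimulus frequencies (Hz), one class each.
#' @param n_harmonics Harmonics per stimulus (fundamental included).
#' @param ssvep_snr Fundamental amplitude relative to the noise standard
#'   deviation; harmonic h is scaled by `0.5^(h-1)`.
#' @param ssvep_channels Informative occipital electrodes.
#' @param noise_exponent Spectral exponent of the 1/f^a background noise.
#' @param noise_amp Noise standard deviation.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(fs = 256, montage = default_montage(),
                         trial_sec = 2, mi_trials_per_class = 20L,
                         ssvep_trials_per_class = 12L,
                         mu_freq = 10, mu_amp = 2, erd_depth = 0.8,
                         mi_channels = c("C3", "C4"),
                         ssvep_freqs = c(10, 12, 15), n_harmonics = 2L,
                         ssvep_snr = 1.5,
                         ssvep_channels = c("POz", "O1", "Oz", "O2"),
                         noise_exponent = 1, noise_amp = 1) {
  bad <- setdiff(c(mi_channels, ssvep_channels), montage)
  if (length(bad)) stop("informative channels not in montage: ",
                        paste(bad, collapse = ", "))
  if (ssvep_snr < 0) stop("ssvep_snr must be >= 0")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0,1]")
  if (max(ssvep_freqs) * n_harmonics >= fs / 2) {
    stop("a stimulus harmonic reaches Nyquist (", fs / 2, " Hz)")
  }
  structure(list(fs = fs, montage = montage, trial_sec = trial_sec,
                 mi_trials_per_class = as.integer(mi_trials_per_class),
                 ssvep_trials_per_class = as.integer(ssvep_trials_per_class),
                 mu_freq = mu_freq, mu_amp = mu_amp, erd_depth = erd_depth,
                 mi_channels = mi_channels, ssvep_freqs = ssvep_freqs,
                 n_harmonics = as.integer(n_harmonics), ssvep_snr = ssvep_snr,
                 ssvep_channels = ssvep_channels,
                 noise_exponent = noise_exponent, noise_amp = noise_amp),
            class = "synth_config")
}

# 1/f^a noise via spectral shaping of white Gaussian noise, rescaled to sd
one_over_f <- function(n, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  freqs <- pmin(freqs, n - freqs + 1)    # mirror for negative frequencies
  spec <- spec / freqs^(exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd_target / s)
  x
}

hemisphere_of <- function(name) {
  digit <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", name)))
  if (is.na(digit)) return("M")
  if (digit %% 2L == 1L) "L" else "R"
}

#' Generate synthetic motor-imagery epochs
#'
#' All channels carry 1/f background noise. Informative motor channels
#' additionally carry a mu-band oscillation (random phase per trial) whose
#' amplitude is attenuated by `erd_depth` contralaterally to the imagined
#' hand: left-hand imagery attenuates right-hemisphere channels and vice
#' versa (midline informative channels are never attenuated). Classes are
#' balanced and labelled "left"/"right".
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; generation is bit-reproducible per
#'   (config, seed).
#' @return An [epoch_set()] whose `extra` records the planted channels and
#'   the seed.
#' @export
generate_mi_epochs <- function(config, seed = 1L) {
  set.seed(seed)
  n_samples <- round(config$fs * config$trial_sec)
  n_ch <- length(config$montage)
  n_per <- config$mi_trials_per_class
  labels <- rep(c("left", "right"), each = n_per)
  n_tr <- length(labels)
  data <- array(0, dim = c(n_tr, n_ch, n_samples))
  t <- seq_len(n_samples) / config$fs
  mi_idx <- match(config$mi_channels, config$montage)
  hemis <- vapply(config$mi_channels, hemisphere_of, character(1))
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      data[tr, ch, ] <- one_over_f(n_samples, config$noise_exponent,
                                   config$noise_amp)
    }
    contralateral <- if (labels[tr] == "left") "R" else "L"
    for (k in seq_along(mi_idx)) {
      amp <- config$mu_amp *
        (if (hemis[k] == contralateral) 1 - config$erd_depth else 1)
      phase <- stats::runif(1, 0, 2 * pi)
      data[tr, mi_idx[k], ] <- data[tr, mi_idx[k], ] +
        amp * sin(2 * pi * config$mu_freq * t + phase)
    }
  }
  epoch_set(data, labels, config$fs, config$montage,
            extra = list(task = "MI", planted_channels = config$mi_channels,
                         erd_depth = config$erd_depth, seed = seed))
}

#' Generate synthetic SSVEP epochs
#'
#' All channels carry 1/f background noise; informative occipital channels
#' additionally carry sinusoids at the trial's stimulus frequency and its
#' harmonics (random phase per trial and harmonic, amplitude
#' `ssvep_snr * noise_amp * 0.5^(h-1)`). Labels are stimulus indices,
#' balanced across classes.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with the [epoch_set()] (`epochs`) and the matching
#'   [stimulus_spec()] (`stim`).
#' @export
generate_ssvep_epochs <- function(config, seed = 1L) {
  set.seed(seed)
  n_samples <- round(config$fs * config$trial_sec)
  n_ch <- length(config$montage)
  n_freq <- length(config$ssvep_freqs)
  labels <- rep(seq_len(n_freq), each = config$ssvep_trials_per_class)
  n_tr <- length(labels)
  data <- array(0, dim = c(n_tr, n_ch, n_samples))
  t <- seq_len(n_samples) / config$fs
  ss_idx <- match(config$ssvep_channels, config$montage)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      data[tr, ch, ] <- one_over_f(n_samples, config$noise_exponent,
                                   config$noise_amp)
    }
    f <- config$ssvep_freqs[labels[tr]]
    for (h in seq_len(config$n_harmonics)) {
      amp <- config$ssvep_snr * config$noise_amp * 0.5^(h - 1)
      phase <- stats::runif(1, 0, 2 * pi)
      wave <- amp * sin(2 * pi * h * f * t + phase)
      for (ch in ss_idx) data[tr, ch, ] <- data[tr, ch, ] + wave
    }
  }
  stim <- stimulus_spec(config$ssvep_freqs, config$n_harmonics, config$fs)
  epochs <- epoch_set(data, labels, config$fs, config$montage,
                      extra = list(task = "SSVEP",
                                   planted_channels = config$ssvep_channels,
                                   frequencies = config$ssvep_freqs,
                                   snr = config$ssvep_snr, seed = seed))
  list(epochs = epochs, stim = stim)
}

#' Write a canonical synthetic fixture suite
#'
#' Generates the default MI and SSVEP epoch sets, writes them in the package
#' container format (data CSV + JSON sidecar) together with a ground-truth
#' manifest, and returns the manifest. Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return The manifest, invisibly written to `manifest.json`.
#' @export
make_fixture_suite <- function(out_dir, config = synth_config(), seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mi <- generate_mi_epochs(config, seed)
  ss <- generate_ssvep_epochs(config, seed + 1L)
  write_epochs(mi, file.path(out_dir, "mi_epochs"))
  write_epochs(ss$epochs, file.path(out_dir, "ssvep_epochs"))
  manifest <- list(
    seed = seed, fs = config$fs, montage = config$montage,
    trial_sec = config$trial_sec,
    mi = list(file = "mi_epochs", trials = dim(mi$data)[1L],
              planted_channels = config$mi_channels,
              erd_depth = config$erd_depth),
    ssvep = list(file = "ssvep_epochs", trials = dim(ss$epochs$data)[1L],
                 planted_channels = config$ssvep_channels,
                 frequencies = config$ssvep_freqs,
                 n_harmonics = config$n_harmonics, snr = config$ssvep_snr)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
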