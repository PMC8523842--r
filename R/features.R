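#' Construct an epoch set
#'
#' The in-memory container for segmented multichannel EEG: a trials x
#' channels x samples array plus per-trial labels, sampling rate, and
#' montage names.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param labels Per-trial class labels (length = trials).
#' @param fs Sampling rate in Hz.
#' @param channel_names Ordered montage names (length = channels).
#' @param extra Optional named list of metadata (ground truth, seed, ...).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_names, extra = list()) {
  if (length(dim(data)) != 3L) stop("data must be a trials x channels x samples array")
  if (dim(data)[1L] != length(labels)) {
    stop("labels length (", length(labels), ") does not match trial count (",
         dim(data)[1L], ")")
  }
  if (dim(data)[2L] != length(channel_names)) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel dimension (", dim(data)[2L], ")")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz")
  structure(list(data = data, labels = labels, fs = fs,
                 channel_names = channel_names, extra = extra),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("epoch_set: ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("classes:", paste(names(table(x$labels)), table(x$labels),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Restrict an epoch set to a channel subset
#'
#' @param epochs An [epoch_set()].
#' @param channels Integer indices or channel names to keep.
#' @return A new `epoch_set` over the selected channels.
#' @export
select_channels <- function(epochs, channels) {
  if (is.character(channels)) {
    idx <- match(channels, epochs$channel_names)
    if (anyNA(idx)) stop("unknown channel names: ",
                         paste(channels[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(channels)
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
            epochs$channel_names[idx], epochs$extra)
}

#' Zero-phase band-pass filtering of MI epochs
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass, by default
#' 5-30 Hz, the band carrying the mu/beta rhythms used by CSP. Zero-phase
#' filtering avoids class-dependent phase distortion.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return Filtered `epoch_set` of identical shape.
#' @export
bandpass_mi <- function(epochs, low = 5, high = 30, order = 4L) {
  fs <- epochs$fs
  if (high >= fs / 2) {
    stop("band edge ", high, " Hz is not below Nyquist (", fs / 2, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- epochs$data
  for (tr in seq_len(dim(d)[1L])) {
    for (ch in seq_len(dim(d)[2L])) {
      d[tr, ch, ] <- signal::filtfilt(bf, d[tr, ch, ])
    }
  }
  epoch_set(d, epochs$labels, fs, epochs$channel_names, epochs$extra)
}

trial_matrix <- function(epochs, trial) {
  # samples x channels
  t(matrix(epochs$data[trial, , ], nrow = dim(epochs$data)[2L]))
}

# trace-normalized covariance of a samples x channels matrix
normalized_cov <- function(x) {
  v <- crossprod(x)
  v / sum(diag(v))
}

#' Fit common spatial patterns on a two-class epoch set
#'
#' Averages trace-normalized covariance matrices per class, whitens their
#' composite, and eigendecomposes the whitened class-1 covariance. Returned
#' filters correspond to the `m` largest and `m` smallest eigenvalues; in the
#' whitened metric the projected composite covariance is the identity, so the
#' class-1 eigenvalue of each filter is its class-1 variance share (0.5
#' everywhere when the class covariances coincide).
#'
#' @param epochs A band-passed two-class [epoch_set()].
#' @param m Filter pairs to keep; default `min(2, floor(C/2))` for C selected
#'   channels. With a single channel, CSP is skipped and the bank marks the
#'   log-variance fallback.
#' @return List of class `csp_bank`: `filters` (channels x 2m), `eigenvalues`
#'   (whitened class-1 eigenvalues, decreasing), `m`, `single_channel`.
#' @export
csp_fit <- function(epochs, m = NULL) {
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2L) stop("CSP requires exactly 2 classes, got ",
                                  length(classes))
  n_ch <- dim(epochs$data)[2L]
  if (n_ch == 1L) {
    return(structure(list(filters = matrix(1, 1L, 1L), eigenvalues = NA_real_,
                          m = 0L, single_channel = TRUE), class = "csp_bank"))
  }
  if (is.null(m)) m <- min(2L, n_ch %/% 2L)
  m <- as.integer(m)
  if (2L * m > n_ch) stop("2m filters exceed channel count")
  covs <- lapply(classes, function(cl) {
    trs <- which(epochs$labels == cl)
    if (length(trs) < 2L) stop("need >= 2 trials per class for CSP")
    cs <- lapply(trs, function(tr) normalized_cov(trial_matrix(epochs, tr)))
    Reduce(`+`, cs) / length(cs)
  })
  cc <- covs[[1L]] + covs[[2L]]
  ev <- eigen(cc, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values)) {
    eps <- 1e-8 * sum(diag(cc)) / n_ch
    warning("rank-deficient composite covariance; regularizing with ",
            format(eps), " * I")
    cc <- cc + diag(eps, n_ch)
    ev <- eigen(cc, symmetric = TRUE)
  }
  whiten <- diag(1 / sqrt(ev$values), n_ch) %*% t(ev$vectors)
  s1 <- whiten %*% covs[[1L]] %*% t(whiten)
  s1 <- (s1 + t(s1)) / 2
  es <- eigen(s1, symmetric = TRUE)     # values decreasing
  sel <- c(seq_len(m), seq.int(n_ch - m + 1L, n_ch))
  filters <- t(whiten) %*% es$vectors[, sel, drop = FALSE]
  structure(list(filters = filters, eigenvalues = es$values, m = m,
                 single_channel = FALSE), class = "csp_bank")
}

#' Normalized log-variance CSP features for one trial
#'
#' Projects the trial through the filter bank and returns, per filter, the
#' log of its variance share of the total projected variance. Features are
#' invariant to scaling the trial by a constant.
#'
#' @param trial Numeric samples x channels matrix.
#' @param bank A `csp_bank` from [csp_fit()].
#' @return Numeric feature vector of length `2m` (length 1 for the
#'   single-channel fallback).
#' @export
csp_features <- function(trial, bank) {
  if (bank$single_channel) {
    v <- stats::var(as.numeric(trial))
    if (v <= 0) stop("degenerate trial: zero variance")
    return(log(v))
  }
  if (ncol(trial) != nrow(bank$filters)) {
    stop("trial channel count does not match filter bank")
  }
  z <- trial %*% bank$filters
  v <- apply(z, 2L, stats::var)
  tot <- sum(v)
  if (tot <= 0) stop("degenerate trial: zero variance")
  log(v / tot)
}

#' SSVEP stimulus specification
#'
#' @param frequencies Distinct stimulus frequencies in Hz.
#' @param n_harmonics Harmonics per sinusoidal reference set (the fundamental
#'   counts as the first harmonic).
#' @param fs Sampling rate the references will be built at, used to check
#'   that every harmonic stays below Nyquist.
#' @return List of class `stimulus_spec`.
#' @export
stimulus_spec <- function(frequencies, n_harmonics = 2L, fs = 256) {
  frequencies <- as.numeric(frequencies)
  if (anyDuplicated(frequencies)) stop("stimulus frequencies must be distinct")
  if (any(frequencies * n_harmonics >= fs / 2)) {
    stop("a stimulus harmonic reaches Nyquist (", fs / 2, " Hz)")
  }
  structure(list(frequencies = frequencies,
                 n_harmonics = as.integer(n_harmonics), fs = fs),
            class = "stimulus_spec")
}

#' Sinusoidal reference matrix for one stimulus frequency
#'
#' Sine/cosine pairs at the frequency and its harmonics — the truncated
#' Fourier series the multichannel trial is correlated against.
#'
#' @param freq Stimulus frequency (Hz).
#' @param n_samples Number of samples.
#' @param fs Sampling rate (Hz).
#' @param n_harmonics Number of harmonics.
#' @return Matrix `n_samples x (2 * n_harmonics)`.
#' @export
cca_reference <- function(freq, n_samples, fs, n_harmonics = 2L) {
  t <- seq_len(n_samples) / fs
  cols <- lapply(seq_len(n_harmonics), function(h) {
    cbind(sin(2 * pi * h * freq * t), cos(2 * pi * h * freq * t))
  })
  do.call(cbind, cols)
}

# orthonormal basis of the column space of a centered matrix
orthobasis <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  qx <- qr(x)
  rank <- qx$rank
  if (rank == 0L) return(NULL)
  qr.Q(qx)[, seq_len(rank), drop = FALSE]
}

max_cancor <- function(qx, qy) {
  if (is.null(qx) || is.null(qy)) return(0)
  s <- svd(crossprod(qx, qy), nu = 0L, nv = 0L)$d[1L]
  min(max(s, 0), 1)
}

#' Maximal canonical correlation per stimulus frequency
#'
#' For each frequency in `stim`, builds the sinusoidal reference set and
#' returns the largest canonical correlation between the multichannel trial
#' and the references. Values lie in `[0, 1]` and are invariant to
#' channel-wise linear scaling of the trial.
#'
#' @param trial Numeric samples x channels matrix.
#' @param stim A [stimulus_spec()].
#' @param fs Sampling rate of the trial; defaults to `stim$fs`.
#' @return Numeric vector, one correlation per stimulus frequency.
#' @export
cca_score <- function(trial, stim, fs = stim$fs) {
  trial <- as.matrix(trial)
  if (nrow(trial) < 2L) stop("trial too short for canonical correlation")
  if (nrow(trial) < fs / min(stim$frequencies)) {
    stop("trial shorter than one period of the lowest stimulus frequency")
  }
  qx <- orthobasis(trial)
  vapply(stim$frequencies, function(f) {
    ref <- cca_reference(f, nrow(trial), fs, stim$n_harmonics)
    max_cancor(qx, orthobasis(ref))
  }, numeric(1))
}

#' Classify a trial by argmax canonical correlation
#'
#' @param trial Numeric samples x channels matrix.
#' @param stim A [stimulus_spec()] with at least two frequencies.
#' @param fs Sampling rate of the trial.
#' @return Index into `stim$frequencies` of the best-matching stimulus; ties
#'   within 1e-12 break toward the lowest index.
#' @export
cca_classify <- function(trial, stim, fs = stim$fs) {
  if (length(stim$frequencies) < 2L) stop("need >= 2 stimulus frequencies")
  scores <- cca_score(trial, stim, fs)
  which(scores >= max(scores) - 1e-12)[1L]
}
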