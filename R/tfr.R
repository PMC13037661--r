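#' Morlet time-frequency decomposition
#'
#' Convolves each trial of a single-channel signal with complex Morlet
#' wavelets (default four cycles: temporal SD `n_cycles / (2 pi f)`) and
#' returns magnitude-squared power per trial. Samples within one wavelet
#' half-width (`n_cycles / (2 f)`) of either epoch edge are flagged invalid
#' in the `edge_valid` mask.
#'
#' @param x trials x samples numeric matrix (one channel, vertex or
#'   component), or an `fm_epochs` container with a single channel.
#' @param sfreq sampling rate in Hz (ignored when `x` is a container).
#' @param freqs frequency grid in Hz; every frequency must be below Nyquist
#'   and resolvable within the epoch (f >= n_cycles / epoch length).
#' @param n_cycles wavelet cycles; default 4.
#' @param t0 time of the first sample (seconds); for containers taken from
#'   the object.
#' @return a `tfr` object: `power` (trials x freqs x samples), `freqs`,
#'   `times`, `n_cycles`, `kind = "total"`, `edge_valid` (freqs x samples
#'   logical).
#' @export
morlet_tfr <- function(x, sfreq = NULL, freqs, n_cycles = 4, t0 = 0) {
  if (inherits(x, "fm_epochs")) {
    stopifnot(dim(x$data)[2] == 1L)
    sfreq <- x$sfreq
    t0 <- x$t0
    x <- x$data[, 1L, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  n_tr <- nrow(x)
  n <- ncol(x)
  epoch_len <- n / sfreq
  if (any(freqs >= sfreq / 2)) {
    stop("frequencies must be below Nyquist", call. = FALSE)
  }
  if (any(freqs < n_cycles / epoch_len)) {
    stop("lowest frequency not resolvable: need f >= n_cycles / epoch length (",
         signif(n_cycles / epoch_len, 3), " Hz)", call. = FALSE)
  }
  power <- array(0, c(n_tr, length(freqs), n))
  # FFT-based convolution, all trials at once per frequency.
  for (fi in seq_along(freqs)) {
    k <- morlet_kernel(freqs[fi], sfreq, n_cycles)
    L <- length(k)
    nfft <- stats::nextn(n + L - 1L, 2)
    Kf <- fft(c(k, complex(real = rep(0, nfft - L))))
    Xf <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, n_tr)))
    conv <- stats::mvfft(Xf * Kf, inverse = TRUE) / nfft
    off <- (L - 1L) %/% 2L
    seg <- conv[off + seq_len(n), , drop = FALSE]
    power[, fi, ] <- t(Mod(seg)^2)
  }
  times <- t0 + (seq_len(n) - 1L) / sfreq
  half_width <- n_cycles / (2 * freqs)
  ev <- outer(half_width, times - times[1], function(h, dt) dt >= h) &
    outer(half_width, times[n] - times, function(h, dt) dt >= h)
  structure(list(power = power, freqs = freqs, times = times,
                 n_cycles = n_cycles, kind = "total", edge_valid = ev,
                 sfreq = sfreq),
            class = "tfr")
}

# Unit-energy complex Morlet wavelet sampled over +/- 5 temporal SDs.
morlet_kernel <- function(f, sfreq, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma_t * sfreq)
  t <- seq(-half, half) / sfreq
  env <- exp(-t^2 / (2 * sigma_t^2))
  k <- env * exp(2i * pi * f * t)
  k / sqrt(sum(Mod(k)^2))
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr:%s> %d trial(s) x %d freqs x %d samples (%g cycles)\n",
              x$kind, d[1], d[2], d[3], x$n_cycles))
  invisible(x)
}

#' Trial-averaged power of a TFR
#'
#' @param x a `tfr` object.
#' @return freqs x samples matrix.
#' @export
tfr_average <- function(x) {
  apply(x$power, c(2, 3), mean)
}

#' Evoked/induced decomposition of a time-frequency response
#'
#' The evoked response is the TFR of the trial-averaged signal (phase-locked
#' components survive averaging); the induced response is the remainder,
#' `total - evoked`, computed on the same grid so the identity
#' `evoked + induced = total` holds exactly. Induced power can be negative
#' pointwise where the evoked estimate exceeds the total.
#'
#' @inheritParams morlet_tfr
#' @return list with `total`, `evoked`, `induced` `tfr` objects (each with a
#'   single trial-averaged layer).
#' @export
evoked_induced <- function(x, sfreq = NULL, freqs, n_cycles = 4, t0 = 0) {
  if (inherits(x, "fm_epochs")) {
    stopifnot(dim(x$data)[2] == 1L)
    sfreq <- x$sfreq
    t0 <- x$t0
    x <- x$data[, 1L, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    warning("single trial: evoked equals total, induced is zero")
  }
  tot <- morlet_tfr(x, sfreq, freqs, n_cycles, t0)
  evo <- morlet_tfr(matrix(colMeans(x), 1L), sfreq, freqs, n_cycles, t0)
  tot_avg <- tot
  tot_avg$power <- array(tfr_average(tot), c(1L, length(freqs), ncol(x)))
  evo$kind <- "evoked"
  ind <- evo
  ind$power <- tot_avg$power - evo$power
  ind$kind <- "induced"
  list(total = tot_avg, evoked = evo, induced = ind)
}

#' Task-versus-baseline t-map of a per-trial TFR
#'
#' For every (frequency, time) cell, a paired t statistic of per-trial power
#' against the trial's mean baseline power at the same frequency.
#'
#' @param tfr_trials a `tfr` with per-trial power (see [morlet_tfr()]).
#' @param baseline_window two-element `[from, to)` interval in seconds.
#' @return list with `t` (freqs x samples matrix), `freqs`, `times`, `n`.
#' @export
baseline_tmap <- function(tfr_trials, baseline_window) {
  bi <- which(tfr_trials$times >= baseline_window[1] &
                tfr_trials$times < baseline_window[2])
  if (length(bi) == 0L) stop("baseline window outside epoch", call. = FALSE)
  P <- tfr_trials$power
  d <- dim(P)
  tmap <- matrix(NA_real_, d[2], d[3])
  warned <- FALSE
  for (fi in seq_len(d[2])) {
    base <- apply(P[, fi, bi, drop = FALSE], 1, mean)
    for (ti in seq_len(d[3])) {
      diffs <- P[, fi, ti] - base
      s <- sd(diffs)
      if (!is.finite(s) || s == 0) {
        if (!warned) {
          warning("zero-variance cell(s); t set to NaN")
          warned <- TRUE
        }
        tmap[fi, ti] <- NaN
      } else {
        tmap[fi, ti] <- mean(diffs) / (s / sqrt(d[1]))
      }
    }
  }
  list(t = tmap, freqs = tfr_trials$freqs, times = tfr_trials$times, n = d[1])
}
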