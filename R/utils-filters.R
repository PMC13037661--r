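# Zero-phase IIR filtering helpers shared by the EMG and MEG preprocessing
# stages. All filters are 4th-order Butterworth applied forward-backward so
# onset timing is not biased by group delay. Narrow bands (e.g. 0.5-4 Hz at
# 300 Hz) are realised as a high-pass/low-pass cascade, which is numerically
# far better conditioned than a single 8th-order transfer function.

# Odd (antisymmetric) edge extension, as is standard for forward-backward
# filtering: x is reflected about its end points so the filter sees no step.
pad_odd <- function(x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen < 1L) {
    return(list(x = x, padlen = 0L))
  }
  left <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  list(x = c(left, x, right), padlen = padlen)
}

# Forward-backward application of one Arma filter with odd padding.
filtfilt_pad <- function(filt, x, padlen = 3L * 15L) {
  p <- pad_odd(x, padlen)
  y <- signal::filter(filt, p$x)
  y <- rev(signal::filter(filt, rev(y)))
  if (p$padlen > 0L) y <- y[seq(p$padlen + 1L, p$padlen + length(x))]
  as.numeric(y)
}

# Design the per-stage filters for a (possibly one-sided) band.
design_band <- function(lo, hi, sfreq, order = 4L) {
  nyq <- sfreq / 2
  if (!is.null(hi) && hi >= nyq) {
    stop("upper band edge (", hi, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  if (!is.null(lo) && !is.null(hi) && lo >= hi) {
    stop("band edges must satisfy lo < hi", call. = FALSE)
  }
  filts <- list()
  if (!is.null(lo) && lo > 0) {
    filts$hp <- signal::butter(order, lo / nyq, type = "high")
  }
  if (!is.null(hi)) {
    filts$lp <- signal::butter(order, hi / nyq, type = "low")
  }
  filts
}

# Apply a designed band (zero-phase) to one numeric vector.
apply_band <- function(filts, x) {
  if (!is.null(filts$hp)) x <- filtfilt_pad(filts$hp, x)
  if (!is.null(filts$lp)) x <- filtfilt_pad(filts$lp, x)
  x
}

# Zero-phase band-pass over the samples dimension of a trials x channels x
# samples array.
filter_epoch_array <- function(arr, lo, hi, sfreq, order = 4L) {
  filts <- design_band(lo, hi, sfreq, order)
  d <- dim(arr)
  out <- arr
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[tr, ch, ] <- apply_band(filts, arr[tr, ch, ])
    }
  }
  out
}

# Integer-factor decimation with zero-phase anti-alias low-pass at 0.8 of the
# output Nyquist.
decimate_vec <- function(x, factor, sfreq) {
  if (factor == 1L) {
    return(x)
  }
  lp <- signal::butter(4L, 0.8 / factor, type = "low")
  y <- filtfilt_pad(lp, x)
  y[seq(1L, length(x), by = factor)]
}
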