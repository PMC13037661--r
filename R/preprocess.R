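#' Canonical movement-analysis frequency bands
#'
#' The six bands used throughout the pipeline: delta (0.5-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz), gamma (30-60 Hz) and
#' high-gamma (60-90 Hz).
#'
#' @return tibble with columns `name`, `lo`, `hi` (Hz).
#' @export
band_specs <- function() {
  tibble::tibble(
    name = c("delta", "theta", "alpha", "beta", "gamma", "hgamma"),
    lo = c(0.5, 4, 8, 13, 30, 60),
    hi = c(4, 8, 13, 30, 60, 90)
  )
}

#' Zero-phase band-pass filtering of an epoch container
#'
#' Applies a zero-phase Butterworth band-pass (4th-order high-pass and
#' low-pass stages run forward-backward) to every trial and channel. Trial
#' order, labels and the time axis are preserved; the band tag is updated.
#'
#' @param epochs an `fm_epochs` container.
#' @param lo,hi band edges in Hz; `hi` must be below Nyquist.
#' @param name optional band tag; default `"lo-hi"`.
#' @return a container of the same class, filtered.
#' @export
bandpass <- function(epochs, lo, hi, name = NULL) {
  stopifnot(inherits(epochs, "fm_epochs"))
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi <= lo) {
    stop("invalid band: need 0 <= lo < hi", call. = FALSE)
  }
  out <- epochs
  out$data <- filter_epoch_array(epochs$data, lo, hi, epochs$sfreq)
  out$band <- if (is.null(name)) sprintf("%g-%g", lo, hi) else name
  out
}

#' Decompose epochs into the six canonical bands
#'
#' @param epochs an `fm_epochs` container (broadband).
#' @param bands a band table as from [band_specs()]; rows may be subset.
#' @return named list of filtered containers, one per band.
#' @export
make_bands <- function(epochs, bands = band_specs()) {
  out <- lapply(seq_len(nrow(bands)), function(i) {
    bandpass(epochs, bands$lo[i], bands$hi[i], name = bands$name[i])
  })
  names(out) <- bands$name
  out
}

#' Align epochs to per-trial movement onset and resample
#'
#' Re-epochs each trial so that time 0 is the trial's EMG-detected movement
#' onset, then decimates to `sfreq_out` with a zero-phase anti-alias
#' low-pass. The output grid is half-open `[tmin, tmax)`.
#'
#' @param epochs an `fm_epochs` container whose time axis is cue-aligned.
#' @param onsets per-trial onset times in seconds on the current time axis.
#' @param tmin,tmax output window in seconds relative to onset.
#' @param sfreq_out output rate; `epochs$sfreq` must be an integer multiple.
#' @return a container of the same class on the new grid.
#' @export
align_and_resample <- function(epochs, onsets, tmin = -2, tmax = 2,
                               sfreq_out = 300) {
  stopifnot(inherits(epochs, "fm_epochs"),
            length(onsets) == n_trials(epochs))
  factor <- epochs$sfreq / sfreq_out
  if (abs(factor - round(factor)) > 1e-9) {
    stop("sfreq (", epochs$sfreq, ") must be an integer multiple of ",
         sfreq_out, call. = FALSE)
  }
  factor <- as.integer(round(factor))
  d <- dim(epochs$data)
  i0 <- round((onsets - epochs$t0 + tmin) * epochs$sfreq) + 1L
  i1 <- i0 + round((tmax - tmin) * epochs$sfreq) - 1L
  bad <- which(i0 < 1L | i1 > d[3])
  if (length(bad) > 0L) {
    stop("requested window exceeds available data for trial(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_out <- round((tmax - tmin) * sfreq_out)
  out <- array(0, c(d[1], d[2], n_out))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      seg <- epochs$data[tr, ch, seq(i0[tr], i1[tr])]
      out[tr, ch, ] <- decimate_vec(seg, factor, epochs$sfreq)[seq_len(n_out)]
    }
  }
  res <- epochs
  res$data <- out
  res$sfreq <- sfreq_out
  res$t0 <- tmin
  res$cue_sample <- NULL
  res
}
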