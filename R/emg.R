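#' EMG envelope extraction
#'
#' Band-pass filters the raw EMG (default 20-450 Hz), full-wave rectifies,
#' and smooths with a low-pass filter (default 50 Hz). All filters are
#' 4th-order Butterworth applied forward-backward, so the envelope has no
#' group delay and onset timing is unbiased.
#'
#' @param raw an [emg_epochs()] object; `sfreq` must exceed twice the upper
#'   band edge.
#' @param lo,hi band-pass edges in Hz.
#' @param smooth low-pass smoothing cutoff in Hz.
#' @return an [emg_epochs()] object holding the per-trial envelopes.
#' @export
emg_envelope <- function(raw, lo = 20, hi = 450, smooth = 50) {
  stopifnot(inherits(raw, "emg_epochs"))
  nyq <- raw$sfreq / 2
  if (hi >= nyq) {
    stop("band edge ", hi, " Hz is at or above Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  bp <- design_band(lo, hi, raw$sfreq)
  lp <- design_band(NULL, smooth, raw$sfreq)
  d <- dim(raw$data)
  out <- raw$data
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- apply_band(bp, raw$data[tr, ch, ])
      out[tr, ch, ] <- apply_band(lp, abs(x))
    }
  }
  env <- raw
  env$data <- out
  env$band <- "emg-envelope"
  env
}

#' Threshold-based movement onset and offset for one envelope trace
#'
#' The movement-initiation threshold is `T = mu + k * sigma`, where `mu` and
#' `sigma` are the mean and (n-1) standard deviation of the envelope over the
#' epoch (or over `stat_window` sample indices if given). The first sample
#' strictly exceeding `T` is the movement onset; the last sample of the last
#' above-threshold run is the movement offset. If no sample exceeds `T` the
#' trial is flagged as "no movement detected" rather than raising an error.
#'
#' @param envelope numeric vector, one trial's EMG envelope.
#' @param sfreq sampling rate in Hz.
#' @param cue_sample 1-based sample index of the visual cue (for reaction
#'   time). Default 1.
#' @param k threshold multiplier (>= 0); default 2.
#' @param stat_window optional integer sample indices over which `mu` and
#'   `sigma` are computed (e.g. a pre-cue baseline); default the full epoch.
#' @return one-row tibble: `onset_sample`, `offset_sample`, `reaction_time`,
#'   `movement_time`, `threshold`, `mu`, `sigma`, `k`, `valid`.
#' @examples
#' env <- c(rep(0, 20), 10, 10)
#' detect_onset_offset(env, sfreq = 1000)
#' @export
detect_onset_offset <- function(envelope, sfreq, cue_sample = 1L, k = 2,
                                stat_window = NULL) {
  stopifnot(all(is.finite(envelope)), k >= 0)
  stat <- if (is.null(stat_window)) envelope else envelope[stat_window]
  mu <- mean(stat)
  sigma <- sd(stat)
  if (!is.finite(sigma)) sigma <- 0
  thr <- mu + k * sigma
  above <- which(envelope > thr)
  if (length(above) == 0L) {
    return(tibble::tibble(
      onset_sample = NA_integer_, offset_sample = NA_integer_,
      reaction_time = NA_real_, movement_time = NA_real_,
      threshold = thr, mu = mu, sigma = sigma, k = k, valid = FALSE
    ))
  }
  onset <- above[1L]
  offset <- above[length(above)]
  tibble::tibble(
    onset_sample = onset, offset_sample = offset,
    reaction_time = (onset - cue_sample) / sfreq,
    movement_time = (offset - onset) / sfreq,
    threshold = thr, mu = mu, sigma = sigma, k = k,
    valid = onset >= cue_sample
  )
}

#' Movement timing for every trial of an EMG envelope container
#'
#' Applies [detect_onset_offset()] per trial (first channel) and binds the
#' results into one tibble, adding trial index and task label.
#'
#' @param envelopes an [emg_epochs()] envelope container (see
#'   [emg_envelope()]).
#' @inheritParams detect_onset_offset
#' @return tibble with one row per trial: `trial`, `label`, plus the
#'   [detect_onset_offset()] columns.
#' @export
movement_timing <- function(envelopes, k = 2, stat_window = NULL) {
  stopifnot(inherits(envelopes, "emg_epochs"))
  rows <- lapply(seq_len(n_trials(envelopes)), function(tr) {
    detect_onset_offset(envelopes$data[tr, 1L, ], envelopes$sfreq,
                        cue_sample = envelopes$cue_sample, k = k,
                        stat_window = stat_window)
  })
  dplyr::bind_cols(
    tibble::tibble(trial = seq_len(n_trials(envelopes)),
                   label = envelopes$labels),
    dplyr::bind_rows(rows)
  )
}

#' Export movement timings as TSV
#'
#' Writes `trial, label, onset_s, offset_s, rt_s, mt_s, valid_flag`.
#'
#' @param timings a [movement_timing()] tibble.
#' @param sfreq sampling rate used to convert sample indices to seconds.
#' @param path output path.
#' @param t0 epoch start time in seconds (default 0).
#' @return `path`, invisibly.
#' @export
write_timings <- function(timings, sfreq, path, t0 = 0) {
  out <- data.frame(
    trial = timings$trial, label = as.character(timings$label),
    onset_s = t0 + (timings$onset_sample - 1L) / sfreq,
    offset_s = t0 + (timings$offset_sample - 1L) / sfreq,
    rt_s = timings$reaction_time, mt_s = timings$movement_time,
    valid_flag = timings$valid
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Four-class EMG decoding
#'
#' Segments each trial's envelope from `tmin` to `tmax` seconds around its
#' detected movement onset and feeds the segments to the 5-fold
#' cross-validated one-versus-rest linear classifier. Trials flagged invalid,
#' or whose segment falls outside the epoch, are dropped with a warning.
#'
#' @param envelopes an [emg_envelope()] container.
#' @param timings a [movement_timing()] tibble for the same trials.
#' @param tmin,tmax segment bounds in seconds relative to onset.
#' @param decim integer decimation factor applied to the segment (features
#'   per trial = segment length / decim).
#' @param folds,seed cross-validation settings (see [cv_ovr_linear()]).
#' @return a `decoding_result` (see [cv_ovr_linear()]).
#' @export
emg_decode <- function(envelopes, timings, tmin = -1, tmax = 2, decim = 10L,
                       folds = 5L, seed = 1) {
  stopifnot(inherits(envelopes, "emg_epochs"))
  n_samp <- dim(envelopes$data)[3]
  i0 <- round(tmin * envelopes$sfreq)
  i1 <- round(tmax * envelopes$sfreq) - 1L
  ok <- timings$valid & !is.na(timings$onset_sample) &
    (timings$onset_sample + i0 >= 1L) & (timings$onset_sample + i1 <= n_samp)
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) dropped (invalid or segment outside epoch)")
  }
  idx <- which(ok)
  if (length(idx) < 2L) stop("too few valid trials for decoding", call. = FALSE)
  sel <- seq(i0, i1, by = decim)
  feats <- t(vapply(idx, function(tr) {
    envelopes$data[tr, 1L, timings$onset_sample[tr] + sel]
  }, numeric(length(sel))))
  cv_ovr_linear(feats, droplevels(envelopes$labels[idx]), folds = folds,
                seed = seed)
}
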