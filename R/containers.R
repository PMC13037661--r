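#' Epoch containers
#'
#' Light-weight containers for epoched multichannel recordings. `data` is a
#' trials x channels x samples numeric array; sample 0 of the time axis is at
#' `t0` seconds relative to movement onset. Sensor, source (vertex) and EMG
#' epochs share the same layout and differ only in what the second dimension
#' indexes.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sfreq sampling frequency in Hz.
#' @param t0 time of the first sample in seconds relative to movement onset.
#' @param band frequency-band tag, e.g. `"broadband"`, `"delta"`.
#' @param labels per-trial task labels (factor or coercible); length must
#'   equal the number of trials.
#' @param channel_names optional channel names.
#' @return An object of class `sensor_epochs` (also `fm_epochs`).
#' @examples
#' ep <- sensor_epochs(array(rnorm(2 * 3 * 10), c(2, 3, 10)),
#'                     sfreq = 10, t0 = -0.5, labels = c("thumb", "index"))
#' ep
#' @export
sensor_epochs <- function(data, sfreq, t0, band = "broadband", labels,
                          channel_names = NULL) {
  new_epochs(data, sfreq, t0, band, labels, channel_names,
             class = "sensor_epochs", space = "sensor")
}

#' @rdname sensor_epochs
#' @export
source_epochs <- function(data, sfreq, t0, band = "broadband", labels,
                          channel_names = NULL) {
  new_epochs(data, sfreq, t0, band, labels, channel_names,
             class = "source_epochs", space = "source")
}

#' EMG epoch container
#'
#' Like [sensor_epochs()] but carries the sample index of the visual cue,
#' which anchors reaction-time computation.
#'
#' @inheritParams sensor_epochs
#' @param cue_sample 1-based sample index of the visual-cue onset.
#' @return An object of class `emg_epochs` (also `fm_epochs`).
#' @export
emg_epochs <- function(data, sfreq, t0 = 0, labels, cue_sample,
                       channel_names = NULL) {
  stopifnot(cue_sample >= 1, cue_sample <= dim(data)[3])
  ep <- new_epochs(data, sfreq, t0, band = "emg", labels, channel_names,
                   class = "emg_epochs", space = "emg")
  ep$cue_sample <- as.integer(cue_sample)
  ep
}

new_epochs <- function(data, sfreq, t0, band, labels, channel_names,
                       class, space) {
  if (length(dim(data)) == 2L) {
    data <- array(data, c(dim(data)[1], 1L, dim(data)[2]))
  }
  stopifnot(length(dim(data)) == 3L, sfreq > 0)
  labels <- as.factor(labels)
  if (length(labels) != dim(data)[1]) {
    stop("labels length (", length(labels), ") must equal trial count (",
         dim(data)[1], ")", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("%s%03d", substr(space, 1, 3), seq_len(dim(data)[2]))
  }
  structure(
    list(data = data, sfreq = sfreq, t0 = t0, band = band, labels = labels,
         channel_names = channel_names, space = space),
    class = c(class, "fm_epochs")
  )
}

#' @export
print.fm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d trials x %d %s x %d samples @ %g Hz\n",
              class(x)[1], d[1], d[2],
              if (x$space == "source") "vertices" else "channels",
              d[3], x$sfreq))
  cat(sprintf("  band: %s   time: [%.3f, %.3f) s   classes: %s\n",
              x$band, x$t0, x$t0 + d[3] / x$sfreq,
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Time axis of an epoch container
#'
#' @param epochs an `fm_epochs` object.
#' @return numeric vector of sample times in seconds relative to onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$sfreq
}

n_trials <- function(epochs) dim(epochs$data)[1]

# Index of the sample closest to time t (seconds); half-open convention:
# time_to_sample(epochs, t0) == 1.
time_to_sample <- function(epochs, t) {
  as.integer(round((t - epochs$t0) * epochs$sfreq)) + 1L
}

# Sample indices covering [from, to) on the epoch grid.
window_samples <- function(epochs, from, to) {
  i0 <- time_to_sample(epochs, from)
  i1 <- time_to_sample(epochs, to) - 1L
  n <- dim(epochs$data)[3]
  if (i0 < 1L || i1 > n || i1 < i0) {
    stop(sprintf("window [%g, %g) falls outside the epoch [%g, %g)",
                 from, to, epochs$t0, epochs$t0 + n / epochs$sfreq),
         call. = FALSE)
  }
  seq(i0, i1)
}

#' Convert epochs to a long tibble
#'
#' One row per (trial, channel, sample); useful for ggplot2 displays and
#' dplyr summaries of small containers.
#'
#' @param x an `fm_epochs` object.
#' @param ... unused.
#' @return a tibble with columns `trial`, `label`, `channel`, `time`, `value`.
#' @export
as_tibble.fm_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    label = rep(x$labels, times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    time = rep(epoch_times(x), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Write / read an epoch container
#'
#' Persists an epoch container as a directory holding a JSON metadata file
#' (`meta.json`), the raw sample array (`data.bin`, IEEE doubles in
#' trial-fastest order), and an `events.tsv` table (trial, label, onset_s).
#' The round trip is bit-exact for both data and time-axis metadata.
#'
#' @param epochs an `fm_epochs` object.
#' @param path directory to create/overwrite.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   restored container.
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    class = class(epochs)[1], dims = dim(epochs$data),
    sfreq = epochs$sfreq, t0 = epochs$t0, band = epochs$band,
    space = epochs$space, labels = as.character(epochs$labels),
    label_levels = levels(epochs$labels),
    channel_names = epochs$channel_names,
    cue_sample = epochs$cue_sample
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  ev <- data.frame(trial = seq_len(n_trials(epochs)),
                   label = as.character(epochs$labels),
                   onset_s = 0)
  write.table(ev, file.path(path, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n, size = 8L, endian = "little")
  data <- array(vals, meta$dims)
  labels <- factor(meta$labels, levels = meta$label_levels)
  ep <- switch(meta$class,
    emg_epochs = emg_epochs(data, meta$sfreq, meta$t0, labels,
                            cue_sample = meta$cue_sample,
                            channel_names = meta$channel_names),
    source_epochs = source_epochs(data, meta$sfreq, meta$t0, meta$band,
                                  labels, meta$channel_names),
    sensor_epochs(data, meta$sfreq, meta$t0, meta$band, labels,
                  meta$channel_names)
  )
  ep
}
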