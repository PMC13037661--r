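#' Cross-validated one-versus-rest linear classification
#'
#' Stratified k-fold cross-validation of a four-class (or any multi-class)
#' one-versus-rest linear SVM. Standardization is fitted on the training
#' fold only; feature extraction can likewise be made fold-aware by passing
#' a `feature_fun` instead of a matrix, which receives the training and test
#' trial indices and must return features fitted on the training trials only
#' (used for PCA loadings and activation-map extrema selection).
#'
#' @param features trials x features numeric matrix, or a
#'   `function(train_idx, test_idx)` returning `list(train =, test =)`
#'   matrices.
#' @param labels per-trial class labels (factor or coercible).
#' @param folds number of folds; default 5 (train on 80%, test on 20%).
#' @param seed RNG seed controlling fold assignment.
#' @param cost SVM regularization constant C; default 1.
#' @return a `decoding_result`: `fold_accuracies`, `mean_accuracy`, `sd`,
#'   `per_class_accuracy` (class-conditional recall), `confusion` (counts,
#'   rows = true class, aggregated over folds), `folds` (per-trial fold id),
#'   `predictions`.
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("a", "b"), each = 20)
#' cv_ovr_linear(X, y, seed = 1)$mean_accuracy
#' @export
cv_ovr_linear <- function(features, labels, folds = 5L, seed = 1, cost = 1) {
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  n <- length(labels)
  if (length(classes) < 2L) {
    stop("need at least two classes", call. = FALSE)
  }
  if (any(table(labels) < folds)) {
    stop("every class needs at least `folds` trials", call. = FALSE)
  }
  fold_id <- stratified_folds(labels, folds, seed)
  fn <- if (is.function(features)) {
    features
  } else {
    features <- as.matrix(features)
    stopifnot(nrow(features) == n)
    if (all(apply(features, 2, sd) == 0)) {
      warning("all features have zero variance")
    }
    function(train, test) list(train = features[train, , drop = FALSE],
                               test = features[test, , drop = FALSE])
  }
  preds <- factor(rep(NA_character_, n), levels = classes)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    if (any(table(labels[train]) == 0) || any(table(labels[test]) == 0)) {
      stop("a class is absent from a fold; reduce `folds`", call. = FALSE)
    }
    ft <- fn(train, test)
    sc <- fit_scaler(ft$train)
    Xtr <- apply_scaler(ft$train, sc)
    Xte <- apply_scaler(ft$test, sc)
    dv <- matrix(0, length(test), length(classes))
    for (k in seq_along(classes)) {
      ybin <- factor(ifelse(labels[train] == classes[k], "pos", "neg"),
                     levels = c("pos", "neg"))
      fitk <- e1071::svm(Xtr, ybin, kernel = "linear", cost = cost,
                         scale = FALSE)
      d <- attr(stats::predict(fitk, Xte, decision.values = TRUE),
                "decision.values")
      # orient decision values so larger means "pos"
      sgn <- if (grepl("^pos", colnames(d)[1])) 1 else -1
      dv[, k] <- sgn * d[, 1]
    }
    preds[test] <- classes[max.col(dv, ties.method = "first")]
    fold_acc[f] <- mean(preds[test] == labels[test])
  }
  confusion <- table(true = labels, predicted = preds)
  new_decoding_result(fold_acc, confusion, fold_id, preds, labels)
}

new_decoding_result <- function(fold_acc, confusion, fold_id, preds, labels) {
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(
    fold_accuracies = fold_acc,
    mean_accuracy = mean(fold_acc),
    sd = sd(fold_acc),
    per_class_accuracy = per_class,
    confusion = unclass(confusion),
    folds = fold_id, predictions = preds, labels = labels
  ), class = "decoding_result")
}

stratified_folds <- function(labels, folds, seed) {
  local_seed(seed)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

fit_scaler <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(m = m, s = s)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$m), 2, sc$s, "/")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f +/- %.3f over %d folds (chance %.3f)\n",
              x$mean_accuracy, x$sd, length(x$fold_accuracies),
              1 / nrow(x$confusion)))
  invisible(x)
}

#' Tidy methods for decoding results
#'
#' `tidy()` returns per-fold accuracies; `glance()` a one-row summary with
#' the mean, SD and chance level.
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracies),
                 accuracy = x$fold_accuracies)
}

#' @rdname tidy.decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, sd = x$sd,
                 folds = length(x$fold_accuracies),
                 n_trials = length(x$labels),
                 chance = 1 / nrow(x$confusion))
}

#' Point-wise time-resolved decoding
#'
#' One cross-validation run per time sample, with the reconstructed
#' amplitudes of all vertices at that sample as features, yielding an
#' accuracy-versus-time series.
#'
#' @param source_epochs a band-limited [source_epochs()] container.
#' @param folds,seed,cost see [cv_ovr_linear()].
#' @param decim run the analysis every `decim`-th sample (default 1).
#' @param span optional `[from, to)` restriction in seconds.
#' @return a `decoding_series`: tibble `series` (`time`, `accuracy`), plus
#'   the per-point `decoding_result` summaries.
#' @export
pointwise_decode <- function(source_epochs, folds = 5L, seed = 1, cost = 1,
                             decim = 1L, span = NULL) {
  idx <- if (is.null(span)) {
    seq_len(dim(source_epochs$data)[3])
  } else {
    window_samples(source_epochs, span[1], span[2])
  }
  idx <- idx[seq(1L, length(idx), by = decim)]
  times <- epoch_times(source_epochs)[idx]
  acc <- vapply(idx, function(s) {
    cv_ovr_linear(source_epochs$data[, , s], source_epochs$labels,
                  folds = folds, seed = seed, cost = cost)$mean_accuracy
  }, numeric(1))
  new_decoding_series(tibble::tibble(time = times, accuracy = acc),
                      kind = "pointwise",
                      n_classes = nlevels(source_epochs$labels))
}

#' Window-wise decoding of trial-resolved activation maps
#'
#' One cross-validation run per 50-ms window, with each trial's per-vertex
#' activation indices for that window as features. Vertices with NaN values
#' in a window are dropped listwise for that window.
#'
#' @param awmap a trial-resolved windowed `activation_map`
#'   (see [a_window_maps()]).
#' @param folds,seed,cost see [cv_ovr_linear()].
#' @return a `decoding_series` with one row per window (`window`, `time`,
#'   `accuracy`).
#' @export
windowwise_decode <- function(awmap, folds = 5L, seed = 1, cost = 1) {
  stopifnot(!is.null(awmap$window_length))
  n_win <- dim(awmap$A_trial)[3]
  acc <- vapply(seq_len(n_win), function(w) {
    F <- awmap$A_trial[, , w]
    bad <- apply(F, 2, function(col) any(!is.finite(col)))
    if (any(bad)) {
      warning(sum(bad), " NaN vertex(es) dropped in window ", w)
      F <- F[, !bad, drop = FALSE]
    }
    cv_ovr_linear(F, awmap$labels, folds = folds, seed = seed,
                  cost = cost)$mean_accuracy
  }, numeric(1))
  new_decoding_series(
    tibble::tibble(window = seq_len(n_win),
                   time = awmap$window_starts + awmap$window_length / 2,
                   accuracy = acc),
    kind = "windowwise", n_classes = length(awmap$tasks)
  )
}

new_decoding_series <- function(series, kind, n_classes) {
  structure(list(series = series, kind = kind, n_classes = n_classes,
                 chance = 1 / n_classes),
            class = "decoding_series")
}

#' @export
print.decoding_series <- function(x, ...) {
  cat(sprintf("<decoding_series:%s> %d points, peak %.3f (chance %.3f)\n",
              x$kind, nrow(x$series), max(x$series$accuracy), x$chance))
  invisible(x)
}

#' @export
tidy.decoding_series <- function(x, ...) {
  x$series
}

# ---- feature extraction schemes ------------------------------------------

task_window_samples <- function(source_epochs, task_window, decim) {
  idx <- window_samples(source_epochs, task_window[1], task_window[2])
  idx[seq(1L, length(idx), by = decim)]
}

#' PCA-based features
#'
#' Concatenated retained-component time courses over the task period. The
#' plain function fits the PCA on all trials (the published leakage
#' profile); [pca_feature_fun()] returns a fold-aware extractor that fits
#' loadings on the training trials only.
#'
#' @param source_epochs a [source_epochs()] container.
#' @param task_window `[from, to)` task period in seconds; default -1 to 2.
#' @param var_frac retained cumulative variance fraction; default 0.70.
#' @param decim temporal decimation of the feature time courses.
#' @return trials x (components * samples) matrix.
#' @export
features_pca <- function(source_epochs, task_window = c(-1, 2),
                         var_frac = 0.70, decim = 1L) {
  pca <- roi_pca(source_epochs, var_frac)
  idx <- task_window_samples(source_epochs, task_window, decim)
  sc <- pca$scores[, , idx, drop = FALSE]
  matrix(sc, dim(sc)[1])
}

#' @rdname features_pca
#' @export
pca_feature_fun <- function(source_epochs, task_window = c(-1, 2),
                            var_frac = 0.70, decim = 1L) {
  idx <- task_window_samples(source_epochs, task_window, decim)
  d <- dim(source_epochs$data)
  extract <- function(rot, trials) {
    out <- matrix(0, length(trials), ncol(rot) * length(idx))
    for (i in seq_along(trials)) {
      out[i, ] <- as.vector(t(rot) %*% source_epochs$data[trials[i], , idx])
    }
    out
  }
  function(train, test) {
    sub <- source_epochs
    sub$data <- source_epochs$data[train, , , drop = FALSE]
    sub$labels <- droplevels(source_epochs$labels[train])
    pca <- roi_pca(sub, var_frac)
    list(train = extract(pca$rotation, train),
         test = extract(pca$rotation, test))
  }
}

extract_vertex_series <- function(source_epochs, vertices, idx) {
  arr <- source_epochs$data[, vertices, idx, drop = FALSE]
  # vertex-major concatenation per trial: v1 samples, v2 samples, ...
  matrix(aperm(arr, c(1, 3, 2)), dim(arr)[1])
}

# Trial-averaged extrema per task from a trial-resolved map restricted to
# `trials`. Returns the 2 x n_tasks vertex vector (max then min per task).
extrema_from_trials <- function(A_trial, labels, tasks, trials, window = NULL) {
  sel <- function(a) c(which.max(ifelse(is.na(a), -Inf, a)),
                       which.min(ifelse(is.na(a), Inf, a)))
  out <- integer(0)
  for (tk in tasks) {
    tr <- intersect(trials, which(labels == tk))
    a <- if (is.null(window)) {
      colMeans(A_trial[tr, , drop = FALSE])
    } else {
      colMeans(matrix(A_trial[tr, , window], nrow = length(tr)))
    }
    out <- c(out, sel(a))
  }
  out
}

#' Activation-epoch (A-epoch) features
#'
#' The source-reconstructed time series over the task period at the eight
#' extrema vertices of the full-epoch activation map (max and min per task;
#' duplicates across tasks retained).
#'
#' @param source_epochs a [source_epochs()] container.
#' @param extrema an [extrema_vertices()] tibble for the full-epoch map.
#' @param task_window,decim see [features_pca()].
#' @return trials x (8 * samples) matrix.
#' @export
features_a_epoch <- function(source_epochs, extrema, task_window = c(-1, 2),
                             decim = 1L) {
  idx <- task_window_samples(source_epochs, task_window, decim)
  verts <- as.vector(rbind(extrema$max_vertex, extrema$min_vertex))
  extract_vertex_series(source_epochs, verts, idx)
}

#' @rdname features_a_epoch
#' @param amap a trial-resolved full-epoch `activation_map`; extrema are
#'   recomputed from the training trials of each fold.
#' @export
a_epoch_feature_fun <- function(source_epochs, amap, task_window = c(-1, 2),
                                decim = 1L) {
  idx <- task_window_samples(source_epochs, task_window, decim)
  function(train, test) {
    verts <- extrema_from_trials(amap$A_trial, amap$labels, amap$tasks, train)
    F <- extract_vertex_series(source_epochs, verts, idx)
    list(train = F[train, , drop = FALSE], test = F[test, , drop = FALSE])
  }
}

#' Activation-window (A-window) features
#'
#' For every 50-ms window, the source-reconstructed segments at that
#' window's eight extrema vertices; segments from all windows are
#' concatenated in temporal order. When the task window and window tiling
#' match, the dimensionality equals that of [features_a_epoch()].
#'
#' @param source_epochs a [source_epochs()] container.
#' @param windowed_extrema an [extrema_vertices()] tibble for a windowed map.
#' @param awmap a trial-resolved windowed `activation_map` (fold-aware
#'   variant).
#' @param span `[from, to)` interval covered by the windows.
#' @param window window length in seconds.
#' @param decim temporal decimation within each segment.
#' @return trials x (windows * 8 * samples_per_window) matrix.
#' @export
features_a_window <- function(source_epochs, windowed_extrema,
                              span = c(-1, 2), window = 0.050, decim = 1L) {
  spw <- as.integer(round(window * source_epochs$sfreq))
  all_idx <- window_samples(source_epochs, span[1], span[2])
  n_win <- length(all_idx) %/% spw
  n_tr <- dim(source_epochs$data)[1]
  blocks <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    ex <- windowed_extrema[windowed_extrema$window == w, ]
    verts <- as.vector(rbind(ex$max_vertex, ex$min_vertex))
    idx <- all_idx[seq((w - 1L) * spw + 1L, w * spw)]
    idx <- idx[seq(1L, length(idx), by = decim)]
    blocks[[w]] <- extract_vertex_series(source_epochs, verts, idx)
  }
  do.call(cbind, blocks)
}

#' @rdname features_a_window
#' @export
a_window_feature_fun <- function(source_epochs, awmap, span = c(-1, 2),
                                 window = 0.050, decim = 1L) {
  spw <- as.integer(round(window * source_epochs$sfreq))
  all_idx <- window_samples(source_epochs, span[1], span[2])
  n_win <- dim(awmap$A_trial)[3]
  function(train, test) {
    blocks <- vector("list", n_win)
    for (w in seq_len(n_win)) {
      verts <- extrema_from_trials(awmap$A_trial, awmap$labels, awmap$tasks,
                                   train, window = w)
      idx <- all_idx[seq((w - 1L) * spw + 1L, w * spw)]
      idx <- idx[seq(1L, length(idx), by = decim)]
      blocks[[w]] <- extract_vertex_series(source_epochs, verts, idx)
    }
    F <- do.call(cbind, blocks)
    list(train = F[train, , drop = FALSE], test = F[test, , drop = FALSE])
  }
}

#' Time-frequency power features
#'
#' Morlet power of component or extrema-vertex time courses as classifier
#' inputs (amplitude-based alternative to raw time series).
#'
#' @param x trials x channels x samples array (e.g. `roi_pca()$scores` or a
#'   vertex subset of a [source_epochs()] container's data).
#' @param sfreq sampling rate in Hz.
#' @param freqs wavelet frequency grid in Hz.
#' @param n_cycles wavelet cycles; default 4.
#' @param decim temporal decimation of the power time courses.
#' @return trials x (channels * freqs * samples) matrix.
#' @export
features_power <- function(x, sfreq, freqs, n_cycles = 4, decim = 1L) {
  d <- dim(x)
  tsel <- seq(1L, d[3], by = decim)
  blocks <- vector("list", d[2])
  for (ch in seq_len(d[2])) {
    tf <- morlet_tfr(x[, ch, , drop = FALSE][, 1, , drop = TRUE],
                     sfreq, freqs, n_cycles)
    P <- tf$power[, , tsel, drop = FALSE]
    blocks[[ch]] <- matrix(P, d[1])
  }
  do.call(cbind, blocks)
}

# ---- virtual channels -----------------------------------------------------

#' Build virtual channels from decodable windows
#'
#' Collects, for every time window whose window-wise decoding accuracy is
#' significantly above chance, the eight extrema vertices of that window's
#' activation map (4 tasks x max/min), forming a set of source-space virtual
#' channels. The decodable time spans from the point-wise analysis restrict
#' which segments of the virtual-channel series are later used as classifier
#' input.
#'
#' @param windowed_extrema an [extrema_vertices()] tibble for the windowed
#'   map.
#' @param decodable_windows integer indices of significantly decodable
#'   windows (e.g. from [cluster_permutation()] on window-wise accuracy
#'   series across subjects).
#' @param decodable_timespans two-column matrix or data frame of `[from, to)`
#'   second intervals from the point-wise analysis; defaults to the union of
#'   the decodable windows.
#' @param window window length in seconds; default 0.05.
#' @param span_start start of the windowed span in seconds; default -1.
#' @return a `virtual_channel_set`: `entries` tibble (`window`, `task`,
#'   `polarity`, `vertex`), `decodable_windows`, `decodable_timespans`,
#'   `empty` flag.
#' @export
build_virtual_channels <- function(windowed_extrema, decodable_windows,
                                   decodable_timespans = NULL,
                                   window = 0.050, span_start = -1) {
  if (length(decodable_windows) == 0L) {
    warning("no significantly decodable window: empty virtual-channel set")
    return(structure(list(entries = tibble::tibble(
      window = integer(), task = character(), polarity = character(),
      vertex = integer()), decodable_windows = integer(),
      decodable_timespans = NULL, empty = TRUE, window = window,
      span_start = span_start), class = "virtual_channel_set"))
  }
  ex <- windowed_extrema[windowed_extrema$window %in% decodable_windows, ]
  entries <- dplyr::bind_rows(
    dplyr::transmute(ex, window = .data$window, task = .data$task,
                     polarity = "max", vertex = .data$max_vertex),
    dplyr::transmute(ex, window = .data$window, task = .data$task,
                     polarity = "min", vertex = .data$min_vertex)
  )
  entries <- dplyr::arrange(entries, .data$window, .data$task, .data$polarity)
  if (is.null(decodable_timespans)) {
    starts <- span_start + (decodable_windows - 1L) * window
    decodable_timespans <- cbind(from = starts, to = starts + window)
  }
  structure(list(entries = entries,
                 decodable_windows = sort(unique(decodable_windows)),
                 decodable_timespans = decodable_timespans, empty = FALSE,
                 window = window, span_start = span_start),
            class = "virtual_channel_set")
}

#' @export
print.virtual_channel_set <- function(x, ...) {
  cat(sprintf("<virtual_channel_set> %d entries over %d decodable window(s)%s\n",
              nrow(x$entries), length(x$decodable_windows),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

# Downsample the full virtual-channel series once per distinct vertex
# (30 Hz by default, before segmentation), then cut the decodable-span
# segments. Returns a lookup keyed by vertex.
vc_decimated_series <- function(source_epochs, vertices, sfreq_out) {
  factor <- source_epochs$sfreq / sfreq_out
  stopifnot(abs(factor - round(factor)) < 1e-9)
  factor <- as.integer(round(factor))
  uniq <- unique(vertices)
  n_tr <- dim(source_epochs$data)[1]
  out <- lapply(uniq, function(v) {
    X <- matrix(source_epochs$data[, v, , drop = FALSE], n_tr)
    t(apply(X, 1, function(row) decimate_vec(row, factor, source_epochs$sfreq)))
  })
  names(out) <- as.character(uniq)
  list(series = out, sfreq = sfreq_out, t0 = source_epochs$t0,
       factor = factor)
}

# Segment one window's 8 virtual channels over the decodable time spans on
# the downsampled grid.
vc_window_features <- function(source_epochs, vcs, w, sfreq_out = 30,
                               cache = NULL) {
  ent <- vcs$entries[vcs$entries$window == w, ]
  if (is.null(cache)) {
    cache <- vc_decimated_series(source_epochs, ent$vertex, sfreq_out)
  }
  n_dec <- ncol(cache$series[[1]])
  segs <- list()
  for (r in seq_len(nrow(vcs$decodable_timespans))) {
    i0 <- floor((vcs$decodable_timespans[r, 1] - cache$t0) * cache$sfreq) + 1L
    i1 <- ceiling((vcs$decodable_timespans[r, 2] - cache$t0) * cache$sfreq)
    idx <- seq(max(1L, i0), min(n_dec, i1))
    block <- lapply(as.character(ent$vertex), function(v) {
      cache$series[[v]][, idx, drop = FALSE]
    })
    segs[[r]] <- do.call(cbind, block)
  }
  do.call(cbind, segs)
}

#' Single-window versus window-combined virtual-channel decoding
#'
#' Decodes the four tasks from (1) each decodable window's eight virtual
#' channels alone and (2) all virtual channels of all decodable windows
#' combined, under identical cross-validation folds. Virtual-channel series
#' are downsampled (default to 30 Hz) before segment extraction.
#'
#' @param source_epochs a band-limited [source_epochs()] container.
#' @param vcs a [build_virtual_channels()] set.
#' @param sfreq_out downsampling target in Hz; default 30.
#' @param folds,seed,cost see [cv_ovr_linear()].
#' @return list with `single` (tibble: `window`, `mean_accuracy`, `sd`),
#'   `single_results` (per-window `decoding_result`s), `combined`
#'   (`decoding_result`), `comparison` tibble.
#' @export
single_vs_combined <- function(source_epochs, vcs, sfreq_out = 30,
                               folds = 5L, seed = 1, cost = 1) {
  if (vcs$empty) stop("virtual-channel set is empty", call. = FALSE)
  wins <- vcs$decodable_windows
  cache <- vc_decimated_series(source_epochs, vcs$entries$vertex, sfreq_out)
  feats <- lapply(wins, function(w) {
    vc_window_features(source_epochs, vcs, w, sfreq_out, cache = cache)
  })
  single_results <- lapply(feats, function(F) {
    cv_ovr_linear(F, source_epochs$labels, folds = folds, seed = seed,
                  cost = cost)
  })
  combined_feats <- do.call(cbind, feats)
  combined <- cv_ovr_linear(combined_feats, source_epochs$labels,
                            folds = folds, seed = seed, cost = cost)
  single <- tibble::tibble(
    window = wins,
    mean_accuracy = vapply(single_results, function(r) r$mean_accuracy,
                           numeric(1)),
    sd = vapply(single_results, function(r) r$sd, numeric(1))
  )
  comparison <- dplyr::bind_rows(
    dplyr::mutate(single, scheme = sprintf("single_w%02d", .data$window)),
    tibble::tibble(window = NA_integer_,
                   mean_accuracy = combined$mean_accuracy,
                   sd = combined$sd, scheme = "combined")
  )
  list(single = single, single_results = single_results,
       combined = combined, comparison = comparison)
}
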