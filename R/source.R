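#' Pooled sensor covariance of an epoch container
#'
#' Channel covariance computed over all trials and samples (the whole
#' experimental period), after removing each channel's grand mean.
#'
#' @param epochs an `fm_epochs` container.
#' @return symmetric positive semi-definite channels x channels matrix.
#' @export
data_covariance <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] * d[3] < d[2] + 1L) {
    stop("need at least channels + 1 total samples", call. = FALSE)
  }
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), d[1] * d[3], d[2])
  if (anyNA(X)) stop("data contain NaN/NA", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  # 1/N normalizer: pooling is then invariant under trial duplication
  C <- crossprod(Xc) / nrow(Xc)
  (C + t(C)) / 2
}

#' Fit an LCMV beamformer with max-variance orientation
#'
#' For each vertex the regularized inverse covariance is applied to the
#' vertex's orientation lead fields; the source orientation is chosen as the
#' direction of maximal reconstructed variance, obtained by eigendecomposition
#' of the projected power matrix restricted to the non-silent (tangential)
#' subspace. Weights satisfy the unit-gain constraint `w %*% l = 1` along the
#' chosen orientation.
#'
#' Regularization is Tikhonov: `reg * mean(diag(C))` added to the diagonal.
#'
#' @param source_model a [make_source_model()] object (or any list with a
#'   `leadfield` matrix; orientation is then taken as fixed).
#' @param covariance channels x channels data covariance
#'   (see [data_covariance()]).
#' @param reg regularization fraction (>= 0); default 0.05.
#' @return a `beamformer_fit`: `weights` (vertices x channels), `orientation`
#'   (vertices x 3 or `NULL` for fixed models), `reg`, `data_cov`.
#' @export
fit_lcmv <- function(source_model, covariance, reg = 0.05) {
  stopifnot(reg >= 0)
  C <- (covariance + t(covariance)) / 2
  n_ch <- nrow(C)
  Cr <- C + diag(reg * mean(diag(C)), n_ch)
  Cinv <- tryCatch(solve(Cr), error = function(e) {
    stop("covariance is singular; use reg > 0", call. = FALSE)
  })
  if (reg == 0 && rcond(Cr) < 1e-12) {
    stop("covariance is numerically singular; use reg > 0", call. = FALSE)
  }
  lf <- source_model$leadfield
  n_vert <- ncol(lf)
  free_ori <- !is.null(source_model$leadfield3) &&
    !is.null(source_model$tangential_basis)
  W <- matrix(0, n_vert, n_ch)
  ori <- if (free_ori) matrix(0, n_vert, 3) else NULL
  for (v in seq_len(n_vert)) {
    if (free_ori) {
      Lt <- source_model$leadfield3[, v, ] %*% source_model$tangential_basis[v, , ]
      S2 <- t(Lt) %*% Cinv %*% Lt
      S2 <- (S2 + t(S2)) / 2
      eg <- eigen(S2, symmetric = TRUE)
      # unit-gain output variance along u is 1 / (u' S2 u): the max-variance
      # orientation is the eigenvector with the smallest eigenvalue.
      u <- eg$vectors[, which.min(eg$values)]
      o3 <- as.vector(source_model$tangential_basis[v, , ] %*% u)
      if (o3[which.max(abs(o3))] < 0) o3 <- -o3
      ori[v, ] <- o3
      l <- as.vector(source_model$leadfield3[, v, ] %*% o3)
    } else {
      l <- lf[, v]
    }
    Cl <- Cinv %*% l
    W[v, ] <- Cl / as.numeric(crossprod(l, Cl))
  }
  structure(list(weights = W, orientation = ori, reg = reg, data_cov = C),
            class = "beamformer_fit")
}

#' @export
print.beamformer_fit <- function(x, ...) {
  cat(sprintf("<beamformer_fit> %d vertices x %d channels (reg = %g)\n",
              nrow(x$weights), ncol(x$weights), x$reg))
  invisible(x)
}

# Effective lead field of each vertex under the fit's chosen orientation.
effective_leadfield <- function(source_model, fit) {
  if (is.null(fit$orientation)) {
    return(source_model$leadfield)
  }
  n_vert <- nrow(fit$weights)
  sapply(seq_len(n_vert), function(v) {
    as.vector(source_model$leadfield3[, v, ] %*% fit$orientation[v, ])
  })
}

#' Project sensor epochs into source space
#'
#' Applies the beamformer weights to every trial.
#'
#' @param epochs a [sensor_epochs()] container.
#' @param fit a [fit_lcmv()] object.
#' @return a [source_epochs()] container, trials x vertices x samples.
#' @export
reconstruct <- function(epochs, fit) {
  d <- dim(epochs$data)
  if (d[2] != ncol(fit$weights)) {
    stop("channel count mismatch: epochs have ", d[2], ", fit expects ",
         ncol(fit$weights), call. = FALSE)
  }
  n_vert <- nrow(fit$weights)
  out <- array(0, c(d[1], n_vert, d[3]))
  for (tr in seq_len(d[1])) {
    out[tr, , ] <- fit$weights %*% epochs$data[tr, , ]
  }
  source_epochs(out, epochs$sfreq, epochs$t0, epochs$band, epochs$labels,
                channel_names = sprintf("v%04d", seq_len(n_vert)))
}

# Biased (1/n) per-vertex variance of reconstructed series over a sample
# window, optionally without mean removal.
window_power <- function(y, idx, demean = TRUE) {
  seg <- y[, idx, drop = FALSE]
  if (demean) {
    m <- rowMeans(seg)
    rowMeans(seg * seg) - m * m
  } else {
    rowMeans(seg * seg)
  }
}

#' Activation-index map (full epoch)
#'
#' For each trial and vertex, the activation index contrasts beamformed
#' source power in the task window against the baseline window:
#' `A = (w Cs w' - w Cb w') / (w Cs w' + w Cb w')`, where `Cs` and `Cb` are
#' the trial's channel covariances over the two windows and `w` the vertex's
#' beamformer weights. Per-trial maps are averaged within task. Quadratic
#' forms use the biased (1/n) normalizer; window means are removed by default.
#'
#' @param fit a [fit_lcmv()] object.
#' @param epochs the [sensor_epochs()] the index is computed from.
#' @param task_window,baseline_window two-element numeric `[from, to)`
#'   intervals in seconds. Defaults: task -1 to 2 s, baseline -2 to -1.5 s.
#' @param demean remove window means before computing power (default TRUE);
#'   FALSE uses raw second moments.
#' @return an `activation_map`: `A` (tasks x vertices, trial-averaged),
#'   `A_trial` (trials x vertices), `labels`, window metadata.
#' @export
activation_index <- function(fit, epochs, task_window = c(-1, 2),
                             baseline_window = c(-2, -1.5), demean = TRUE) {
  ti <- window_samples(epochs, task_window[1], task_window[2])
  bi <- window_samples(epochs, baseline_window[1], baseline_window[2])
  if (length(bi) == 0L) stop("baseline window is empty", call. = FALSE)
  d <- dim(epochs$data)
  n_vert <- nrow(fit$weights)
  A_trial <- matrix(NA_real_, d[1], n_vert)
  warned <- FALSE
  for (tr in seq_len(d[1])) {
    y <- fit$weights %*% epochs$data[tr, , ]
    qs <- window_power(y, ti, demean)
    qb <- window_power(y, bi, demean)
    den <- qs + qb
    zero <- den == 0
    if (any(zero) && !warned) {
      warning("zero task+baseline power at some vertices; A set to NaN")
      warned <- TRUE
    }
    A_trial[tr, ] <- ifelse(zero, NaN, (qs - qb) / den)
  }
  new_activation_map(A_trial, epochs$labels, task_window, baseline_window,
                     window_length = NULL)
}

#' Windowed activation-index maps (50-ms windows)
#'
#' Tiles `span` with non-overlapping windows of `window` seconds (the default
#' 50 ms over `[-1, 2)` gives exactly 60 windows of 15 samples at 300 Hz) and
#' computes the activation index of each window against the fixed baseline.
#'
#' @inheritParams activation_index
#' @param window window length in seconds.
#' @param span two-element `[from, to)` interval tiled by the windows.
#' @return an `activation_map` with `A` (tasks x vertices x windows),
#'   `A_trial` (trials x vertices x windows), and `window_starts`.
#' @export
a_window_maps <- function(fit, epochs, window = 0.050, span = c(-1, 2),
                          baseline_window = c(-2, -1.5), demean = TRUE) {
  spw <- window * epochs$sfreq
  if (abs(spw - round(spw)) > 1e-9) {
    stop("window length is not an integer number of samples", call. = FALSE)
  }
  spw <- as.integer(round(spw))
  n_win <- (span[2] - span[1]) / window
  if (abs(n_win - round(n_win)) > 1e-9) {
    stop("span is not divisible by the window length", call. = FALSE)
  }
  n_win <- as.integer(round(n_win))
  all_idx <- window_samples(epochs, span[1], span[2])
  bi <- window_samples(epochs, baseline_window[1], baseline_window[2])
  d <- dim(epochs$data)
  n_vert <- nrow(fit$weights)
  A_trial <- array(NA_real_, c(d[1], n_vert, n_win))
  warned <- FALSE
  for (tr in seq_len(d[1])) {
    y <- fit$weights %*% epochs$data[tr, , ]
    qb <- window_power(y, bi, demean)
    for (w in seq_len(n_win)) {
      idx <- all_idx[seq((w - 1L) * spw + 1L, w * spw)]
      qs <- window_power(y, idx, demean)
      den <- qs + qb
      zero <- den == 0
      if (any(zero) && !warned) {
        warning("zero task+baseline power at some vertices; A set to NaN")
        warned <- TRUE
      }
      A_trial[tr, , w] <- ifelse(zero, NaN, (qs - qb) / den)
    }
  }
  m <- new_activation_map(A_trial, epochs$labels, span, baseline_window,
                          window_length = window)
  m$window_starts <- span[1] + (seq_len(n_win) - 1L) * window
  m
}

new_activation_map <- function(A_trial, labels, task_window, baseline_window,
                               window_length) {
  tasks <- levels(labels)
  if (length(dim(A_trial)) == 2L) {
    A <- t(sapply(tasks, function(tk) {
      colMeans(A_trial[labels == tk, , drop = FALSE])
    }))
  } else {
    A <- array(NA_real_, c(length(tasks), dim(A_trial)[2], dim(A_trial)[3]),
               dimnames = list(tasks, NULL, NULL))
    for (k in seq_along(tasks)) {
      A[k, , ] <- apply(A_trial[labels == tasks[k], , , drop = FALSE],
                        c(2, 3), mean)
    }
  }
  structure(list(A = A, A_trial = A_trial, labels = labels, tasks = tasks,
                 task_window = task_window, baseline_window = baseline_window,
                 window_length = window_length),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  if (is.null(x$window_length)) {
    cat(sprintf("<activation_map> full-epoch: %d tasks x %d vertices\n",
                nrow(x$A), ncol(x$A)))
  } else {
    cat(sprintf("<activation_map> windowed: %d tasks x %d vertices x %d windows (%g ms)\n",
                dim(x$A)[1], dim(x$A)[2], dim(x$A)[3], 1000 * x$window_length))
  }
  invisible(x)
}

#' Tidy an activation map
#'
#' @param x an `activation_map`.
#' @param ... unused.
#' @return tibble with columns `task`, `window` (NA for full-epoch maps),
#'   `vertex`, `A`.
#' @export
tidy.activation_map <- function(x, ...) {
  if (is.null(x$window_length)) {
    tibble::tibble(
      task = rep(x$tasks, times = ncol(x$A)),
      window = NA_integer_,
      vertex = rep(seq_len(ncol(x$A)), each = length(x$tasks)),
      A = as.vector(x$A)
    )
  } else {
    d <- dim(x$A)
    tibble::tibble(
      task = rep(x$tasks, times = d[2] * d[3]),
      window = rep(seq_len(d[3]), each = d[1] * d[2]),
      vertex = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      A = as.vector(x$A)
    )
  }
}

#' Extrema vertices of an activation map
#'
#' For each task (and each window, for windowed maps) returns the vertices
#' attaining the maximum and minimum trial-averaged activation index — the
#' most task-related activation locations. Four tasks yield eight vertices
#' per map (or per window). Ties are broken toward the lowest vertex index;
#' NaN vertices are excluded.
#'
#' @param map an `activation_map`.
#' @return tibble with columns `window` (NA for full-epoch), `task`,
#'   `max_vertex`, `min_vertex`.
#' @export
extrema_vertices <- function(map) {
  pick <- function(a) {
    if (all(is.na(a))) stop("activation map is all-NaN", call. = FALSE)
    c(max = which.max(ifelse(is.na(a), -Inf, a)),
      min = which.min(ifelse(is.na(a), Inf, a)))
  }
  if (is.null(map$window_length)) {
    rows <- lapply(seq_along(map$tasks), function(k) {
      p <- pick(map$A[k, ])
      tibble::tibble(window = NA_integer_, task = map$tasks[k],
                     max_vertex = p[["max"]], min_vertex = p[["min"]])
    })
  } else {
    n_win <- dim(map$A)[3]
    rows <- lapply(seq_len(n_win), function(w) {
      dplyr::bind_rows(lapply(seq_along(map$tasks), function(k) {
        p <- pick(map$A[k, , w])
        tibble::tibble(window = w, task = map$tasks[k],
                       max_vertex = p[["max"]], min_vertex = p[["min"]])
      }))
    })
  }
  dplyr::bind_rows(rows)
}

#' Spatial PCA over the ROI vertex dimension
#'
#' Principal components of the source signals over vertices, computed on
#' trial-concatenated, time-demeaned data. The smallest leading set of
#' components whose cumulative explained variance exceeds `var_frac` is
#' retained, and per-trial component time courses are returned.
#'
#' @param source_epochs a [source_epochs()] container.
#' @param var_frac fraction of total variance to exceed, in (0, 1];
#'   default 0.70.
#' @return a `roi_pca` object: `rotation` (vertices x n_components),
#'   `explained` (per-component variance fractions), `n_components`,
#'   `scores` (trials x n_components x samples).
#' @export
roi_pca <- function(source_epochs, var_frac = 0.70) {
  if (var_frac <= 0 || var_frac > 1) {
    stop("var_frac must be in (0, 1]", call. = FALSE)
  }
  d <- dim(source_epochs$data)
  stopifnot(d[2] >= 2)
  X <- matrix(aperm(source_epochs$data, c(3, 1, 2)), d[1] * d[3], d[2])
  X <- sweep(X, 2, colMeans(X))
  # eigendecomposition in vertex space (rows >> columns)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  varexp <- ev / sum(ev)
  ncomp <- which(cumsum(varexp) > var_frac)[1]
  if (is.na(ncomp)) ncomp <- length(varexp)
  rot <- eg$vectors[, seq_len(ncomp), drop = FALSE]
  scores <- array(0, c(d[1], ncomp, d[3]))
  for (tr in seq_len(d[1])) {
    scores[tr, , ] <- t(rot) %*% source_epochs$data[tr, , ]
  }
  structure(list(rotation = rot, explained = varexp, n_components = ncomp,
                 var_frac = var_frac, scores = scores,
                 labels = source_epochs$labels, sfreq = source_epochs$sfreq,
                 t0 = source_epochs$t0),
            class = "roi_pca")
}

#' @export
print.roi_pca <- function(x, ...) {
  cat(sprintf("<roi_pca> %d component(s) explaining %.1f%% of variance\n",
              x$n_components, 100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}
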