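#' Vertex-wise windowed decoding
#'
#' Classifies the four tasks at every vertex from its 50-ms source
#' segments, one cross-validation run per (window, vertex), recording both
#' the four-class accuracy and the per-class accuracies (class-conditional
#' recall).
#'
#' @param source_epochs a band-limited [source_epochs()] container.
#' @param window window length in seconds; default 0.05.
#' @param span `[from, to)` interval tiled by windows; default -1 to 2.
#' @param windows optional integer subset of window indices to compute.
#' @param vertices optional integer subset of vertices.
#' @param folds,seed,cost see [cv_ovr_linear()].
#' @return a `vertex_accuracy` object: `accuracy` (windows x vertices,
#'   non-computed entries NA), `per_class` (windows x vertices x tasks),
#'   `window_starts`, `tasks`.
#' @export
vertexwise_decode <- function(source_epochs, window = 0.050, span = c(-1, 2),
                              windows = NULL, vertices = NULL,
                              folds = 5L, seed = 1, cost = 1) {
  spw <- as.integer(round(window * source_epochs$sfreq))
  all_idx <- window_samples(source_epochs, span[1], span[2])
  n_win <- length(all_idx) %/% spw
  n_vert <- dim(source_epochs$data)[2]
  tasks <- levels(source_epochs$labels)
  if (is.null(windows)) windows <- seq_len(n_win)
  if (is.null(vertices)) vertices <- seq_len(n_vert)
  acc <- matrix(NA_real_, n_win, n_vert)
  per_class <- array(NA_real_, c(n_win, n_vert, length(tasks)),
                     dimnames = list(NULL, NULL, tasks))
  for (w in windows) {
    idx <- all_idx[seq((w - 1L) * spw + 1L, w * spw)]
    for (v in vertices) {
      F <- matrix(source_epochs$data[, v, idx], dim(source_epochs$data)[1])
      res <- cv_ovr_linear(F, source_epochs$labels, folds = folds,
                           seed = seed, cost = cost)
      acc[w, v] <- res$mean_accuracy
      per_class[w, v, ] <- res$per_class_accuracy[tasks]
    }
  }
  structure(list(accuracy = acc, per_class = per_class,
                 window_starts = source_epochs$t0 +
                   (all_idx[seq(1L, length(all_idx), by = spw)] - 1L) /
                   source_epochs$sfreq,
                 window = window, tasks = tasks,
                 windows = windows, vertices = vertices),
            class = "vertex_accuracy")
}

#' @export
print.vertex_accuracy <- function(x, ...) {
  cat(sprintf("<vertex_accuracy> %d windows x %d vertices (%d computed)\n",
              nrow(x$accuracy), ncol(x$accuracy), sum(!is.na(x$accuracy))))
  invisible(x)
}

#' Individual finger-preference labels
#'
#' Labels each (window, vertex) with the task attaining the highest
#' per-class accuracy. Exact ties leave the vertex unassigned (NA), which
#' keeps the downstream group vote robust to arbitrary ordering.
#'
#' @param x a [vertexwise_decode()] result, or a windows x vertices x tasks
#'   per-class accuracy array with task dimnames.
#' @return windows x vertices character matrix of task labels (NA where
#'   unassigned or not computed).
#' @export
label_individual <- function(x) {
  pc <- if (inherits(x, "vertex_accuracy")) x$per_class else x
  tasks <- dimnames(pc)[[3]]
  d <- dim(pc)
  labels <- matrix(NA_character_, d[1], d[2])
  for (w in seq_len(d[1])) {
    for (v in seq_len(d[2])) {
      a <- pc[w, v, ]
      if (all(is.na(a))) next
      mx <- max(a)
      winners <- which(a == mx)
      if (length(winners) == 1L) labels[w, v] <- tasks[winners]
    }
  }
  labels
}

#' Group digit map by voting
#'
#' Identifies (window, vertex) cells whose mean four-class accuracy across
#' subjects is significantly above chance (one-sided sign-flip permutation
#' test with Benjamini-Hochberg correction per window), then assigns each
#' significant cell the task label held by the largest number of subjects'
#' individual maps. Voting ties leave the cell unassigned.
#'
#' @param individual_labels list (one per subject) of windows x vertices
#'   label matrices from [label_individual()].
#' @param accuracies list (one per subject) of windows x vertices accuracy
#'   matrices from [vertexwise_decode()].
#' @param tasks character vector of task names.
#' @param chance chance level; default 0.25.
#' @param alpha significance level on adjusted p-values; default 0.05.
#' @param n_perm permutations; default 1000.
#' @param seed RNG seed.
#' @return a `digit_map`: `labels` (windows x vertices, NA outside the
#'   significant mask), `significant` mask, `mean_accuracy`, `p_adj`,
#'   `counts` tibble, `threshold` (see [finger_counts()]).
#' @export
group_digit_map <- function(individual_labels, accuracies, tasks,
                            chance = 0.25, alpha = 0.05, n_perm = 1000,
                            seed = 1) {
  n_sub <- length(individual_labels)
  stopifnot(n_sub >= 2, length(accuracies) == n_sub)
  d <- dim(accuracies[[1]])
  # subjects x vertices x windows stack for the permutation test
  accs <- array(NA_real_, c(n_sub, d[2], d[1]))
  for (s in seq_len(n_sub)) accs[s, , ] <- t(accuracies[[s]])
  computed <- !is.na(accuracies[[1]])
  accs[is.na(accs)] <- chance # non-computed cells can never be significant
  vp <- vertex_permutation_bh(accs, chance = chance, n_perm = n_perm,
                              alpha = alpha, seed = seed)
  significant <- t(vp$mask) & computed
  labels <- matrix(NA_character_, d[1], d[2])
  n_ties <- 0L
  for (w in seq_len(d[1])) {
    for (v in seq_len(d[2])) {
      if (!significant[w, v]) next
      votes <- table(factor(
        vapply(individual_labels, function(m) m[w, v], character(1)),
        levels = tasks))
      if (sum(votes) == 0L) next
      mx <- max(votes)
      winners <- names(votes)[votes == mx]
      if (length(winners) == 1L) {
        labels[w, v] <- winners
      } else {
        n_ties <- n_ties + 1L
      }
    }
  }
  if (n_ties > 0L) message(n_ties, " voting tie(s) left unassigned")
  mean_acc <- Reduce(`+`, accuracies) / n_sub
  dm <- structure(list(labels = labels, significant = significant,
                       mean_accuracy = mean_acc, p_adj = t(vp$p_adj),
                       tasks = tasks, alpha = alpha),
                  class = "digit_map")
  fc <- finger_counts(dm)
  dm$counts <- fc$counts
  dm$threshold <- fc$threshold
  dm
}

#' @export
print.digit_map <- function(x, ...) {
  cat(sprintf("<digit_map> %d windows x %d vertices, %d assigned (threshold %g)\n",
              nrow(x$labels), ncol(x$labels), sum(!is.na(x$labels)),
              x$threshold))
  invisible(x)
}

#' Per-finger vertex counts and activation threshold
#'
#' Counts, per window, the vertices assigned to each finger in a group digit
#' map. The activation threshold is 25% of one-fourth of the maximum total
#' assigned count over windows; windows whose per-finger count exceeds the
#' threshold are flagged.
#'
#' @param digitmap a [group_digit_map()] result (or any object with a
#'   `labels` matrix and `tasks`).
#' @return list with `counts` tibble (`window`, `task`, `count`,
#'   `above_threshold`) and `threshold`.
#' @export
finger_counts <- function(digitmap) {
  labels <- digitmap$labels
  tasks <- digitmap$tasks
  n_win <- nrow(labels)
  counts <- tidyr::expand_grid(window = seq_len(n_win), task = tasks)
  counts$count <- mapply(function(w, tk) sum(labels[w, ] == tk, na.rm = TRUE),
                         counts$window, counts$task)
  totals <- vapply(seq_len(n_win), function(w) sum(!is.na(labels[w, ])),
                   numeric(1))
  threshold <- 0.25 * max(totals, 0) / 4
  counts$above_threshold <- counts$count > threshold
  list(counts = counts, threshold = threshold)
}

#' Tidy a digit map
#'
#' @param x a `digit_map`.
#' @param ... unused.
#' @return tibble with `window`, `vertex`, `label`, `accuracy`,
#'   `significant`.
#' @export
tidy.digit_map <- function(x, ...) {
  d <- dim(x$labels)
  tibble::tibble(
    window = rep(seq_len(d[1]), times = d[2]),
    vertex = rep(seq_len(d[2]), each = d[1]),
    label = as.vector(x$labels),
    accuracy = as.vector(x$mean_accuracy),
    significant = as.vector(x$significant)
  )
}
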