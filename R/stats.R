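#' Friedman rank test for repeated measures
#'
#' Rank-based comparison of paired conditions across subjects (midrank ties),
#' with the chi-square reference distribution. A thin wrapper around
#' [stats::friedman.test()] returning a tidy one-row tibble.
#'
#' @param block_matrix subjects x conditions numeric matrix.
#' @return tibble with `chi2`, `df`, `p`.
#' @export
friedman_rank_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (any(apply(m, 1, function(r) all(r == r[1])))) {
    warning("constant row(s): these subjects contribute no rank information")
  }
  ft <- stats::friedman.test(m)
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(chi2) && all(apply(m, 1, function(r) all(r == r[1])))) {
    chi2 <- 0 # all-constant rows carry no rank information at all
    p <- 1
  }
  tibble::tibble(chi2 = chi2, df = unname(ft$parameter), p = p)
}

#' Wilcoxon signed-rank test
#'
#' Paired (or one-sample against `mu`) signed-rank test with midranks and
#' zero-differences dropped. Small samples without rank ties use the exact
#' sign-flip distribution; otherwise a normal approximation with continuity
#' correction and tie-corrected variance is used. The signed `z` statistic is
#' reported in both cases (negative when the rank sum falls below its null
#' expectation), matching common reporting practice.
#'
#' @param x numeric vector.
#' @param y optional paired vector; the test is on `x - y`.
#' @param mu null value for the one-sample case (default 0).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (directions refer to `x - y` or `x - mu`).
#' @param method `"auto"` (exact when n <= 25 and no ties), `"exact"`, or
#'   `"normal"`.
#' @return tibble with `z`, `p`, `w_plus` (positive-rank sum), `n`
#'   (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 alternative = c("two.sided", "greater", "less"),
                                 method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  d <- if (is.null(y)) x - mu else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; test undefined")
    return(tibble::tibble(z = NA_real_, p = NA_real_, w_plus = NA_real_,
                          n = 0L, method = "undefined"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  use_exact <- switch(method,
    exact = TRUE,
    normal = FALSE,
    auto = !ties && n <= 25L
  )
  ew <- n * (n + 1) / 4
  if (use_exact && !ties) {
    p_le <- stats::psignrank(w_plus, n)
    p_ge <- stats::psignrank(w_plus - 1, n, lower.tail = FALSE)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le
    )
    meth <- "exact"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5 * sign(w_plus - ew)
    zc <- (w_plus - ew - cc) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(zc)),
      greater = pnorm(zc, lower.tail = FALSE),
      less = pnorm(zc)
    )
    meth <- "normal"
  }
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w_plus - ew - 0.5 * sign(w_plus - ew)) / sqrt(sigma2)
  tibble::tibble(z = z, p = min(1, p), w_plus = w_plus, n = n, method = meth)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, clipped at 1).
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Cluster-based permutation test over time (or time-frequency)
#'
#' One-sample (against `null_value`) or paired test on a subjects x points
#' series. A per-point t statistic is thresholded at the cluster-forming
#' level; contiguous supra-threshold points (4-connected cells for
#' two-dimensional maps) form clusters scored by their summed t (cluster
#' mass). The null distribution of the maximum cluster mass is built by
#' random sign flips of the subject-level effects, and each observed cluster
#' receives the permutation p-value `(1 + #{null >= mass}) / (n_perm + 1)`.
#'
#' @param data subjects x points matrix, or a subjects x freqs x times array.
#' @param y optional matching array for a paired comparison (`data - y`).
#' @param null_value value subtracted under the one-sample null; default 0.
#' @param n_perm number of permutations; default 5000.
#' @param alpha cluster significance level; default 0.05.
#' @param tail `"two"`, `"pos"` (right) or `"neg"` (left).
#' @param cluster_threshold cluster-forming t threshold; default the
#'   two-sided (or one-sided) p < 0.05 t quantile at subjects - 1 df.
#' @param seed RNG seed for the permutations.
#' @return a `cluster_result`: `clusters` tibble (`id`, `start`, `end`,
#'   `size`, `mass`, `p`), `mask` (significant points at `alpha`), `tmap`,
#'   `n_perm`, `alpha`.
#' @export
cluster_permutation <- function(data, y = NULL, null_value = 0,
                                n_perm = 5000, alpha = 0.05,
                                tail = c("two", "pos", "neg"),
                                cluster_threshold = NULL, seed = 1) {
  tail <- match.arg(tail)
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  x <- if (is.null(y)) data else data - y
  dims <- dim(x)
  is2d <- length(dims) == 3L
  n <- dims[1]
  stopifnot(n >= 2)
  shape <- if (is2d) dims[2:3] else dims[2]
  X <- if (is2d) matrix(x, n) else as.matrix(x)
  X <- X - null_value
  df <- n - 1
  if (is.null(cluster_threshold)) {
    cluster_threshold <- if (tail == "two") qt(0.975, df) else qt(0.95, df)
  }

  t_of <- function(M, ss) {
    # M: n_perm x points matrix of means; ss: fixed colSums of squares
    v <- (matrix(ss, nrow(M), length(ss), byrow = TRUE) - n * M^2) / df
    v[v < .Machine$double.eps] <- NA
    M / sqrt(v / n)
  }
  ss <- colSums(X^2)
  tobs <- t_of(matrix(colMeans(X), 1), ss)[1, ]

  clus <- find_clusters(tobs, cluster_threshold, tail, shape)

  local_seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Mp <- (S %*% X) / n
  Tp <- t_of(Mp, ss)
  null_max <- if (!is2d) {
    max_run_mass(Tp, cluster_threshold, tail)
  } else {
    vapply(seq_len(n_perm), function(i) {
      cl <- find_clusters(Tp[i, ], cluster_threshold, tail, shape)
      if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
    }, numeric(1))
  }

  if (nrow(clus) > 0L) {
    clus$p <- vapply(clus$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
  } else {
    clus$p <- numeric(0)
  }
  mask <- if (is2d) array(FALSE, shape) else rep(FALSE, shape)
  for (i in seq_len(nrow(clus))) {
    if (clus$p[i] <= alpha) mask[clus$members[[i]]] <- TRUE
  }
  structure(list(clusters = clus[, c("id", "start", "end", "size", "mass", "p")],
                 members = clus$members, mask = mask, tmap = tobs,
                 shape = shape, n_perm = n_perm, alpha = alpha,
                 cluster_threshold = cluster_threshold, tail = tail),
            class = "cluster_result")
}

# Maximum cluster mass per row of a permutation t matrix (1D contiguity),
# vectorized across permutations: running supra-threshold run sums column by
# column.
max_run_mass <- function(Tp, thr, tail) {
  Tp[is.na(Tp)] <- 0
  best <- rep(0, nrow(Tp))
  if (tail %in% c("two", "pos")) {
    run <- rep(0, nrow(Tp))
    for (j in seq_len(ncol(Tp))) {
      above <- Tp[, j] > thr
      run <- ifelse(above, run + Tp[, j], 0)
      best <- pmax(best, run)
    }
  }
  if (tail %in% c("two", "neg")) {
    run <- rep(0, nrow(Tp))
    for (j in seq_len(ncol(Tp))) {
      below <- Tp[, j] < -thr
      run <- ifelse(below, run - Tp[, j], 0)
      best <- pmax(best, run)
    }
  }
  best
}

# Supra-threshold clusters of a t map. For 1D shapes uses run-length
# encoding; for 2D shapes (freq x time) 4-connected components.
find_clusters <- function(tv, thr, tail, shape) {
  tv_na <- ifelse(is.na(tv), 0, tv)
  sets <- list()
  if (tail %in% c("two", "pos")) sets$pos <- tv_na > thr
  if (tail %in% c("two", "neg")) sets$neg <- tv_na < -thr
  out <- list()
  for (s in names(sets)) {
    act <- sets[[s]]
    if (!any(act)) next
    comp <- if (length(shape) == 2L) {
      label_components_2d(matrix(act, shape[1], shape[2]))
    } else {
      label_runs_1d(act)
    }
    for (id in seq_len(max(comp))) {
      members <- which(comp == id)
      if (length(members) == 0L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        start = min(members), end = max(members),
        size = length(members), mass = sum(tv_na[members]),
        members = list(members)
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(id = integer(), start = integer(), end = integer(),
                          size = integer(), mass = numeric(),
                          members = list()))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$start), ]
  res$id <- seq_len(nrow(res))
  res[, c("id", "start", "end", "size", "mass", "members")]
}

label_runs_1d <- function(act) {
  r <- rle(act)
  lab <- integer(length(act))
  id <- 0L
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      id <- id + 1L
      lab[seq(pos, pos + r$lengths[i] - 1L)] <- id
    }
    pos <- pos + r$lengths[i]
  }
  lab
}

label_components_2d <- function(act) {
  lab <- matrix(0L, nrow(act), ncol(act))
  id <- 0L
  for (j in seq_len(ncol(act))) {
    for (i in seq_len(nrow(act))) {
      if (act[i, j] && lab[i, j] == 0L) {
        id <- id + 1L
        stack <- list(c(i, j))
        while (length(stack) > 0L) {
          cur <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          ci <- cur[1]; cj <- cur[2]
          if (ci < 1 || cj < 1 || ci > nrow(act) || cj > ncol(act)) next
          if (!act[ci, cj] || lab[ci, cj] != 0L) next
          lab[ci, cj] <- id
          stack <- c(stack, list(c(ci - 1L, cj), c(ci + 1L, cj),
                                 c(ci, cj - 1L), c(ci, cj + 1L)))
        }
      }
    }
  }
  lab
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, alpha = %g\n",
              nrow(x$clusters), x$n_perm, x$alpha))
  if (nrow(x$clusters) > 0L) print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' Significant spans of a cluster result
#'
#' @param x a `cluster_result`.
#' @param alpha significance level; defaults to the result's alpha.
#' @return tibble of clusters with `p <= alpha` (columns `start`, `end`, `p`).
#' @export
significant_spans <- function(x, alpha = x$alpha) {
  dplyr::filter(x$clusters, .data$p <= alpha)
}

#' One-sided vertex-wise permutation test with BH correction
#'
#' Tests per-vertex mean classification accuracy across subjects against
#' chance by sign-flipping subject deviations, then adjusts the per-vertex
#' permutation p-values with Benjamini-Hochberg within each window.
#'
#' @param accuracy subjects x vertices matrix, or subjects x vertices x
#'   windows array.
#' @param chance chance level subtracted from every accuracy; default 0.25.
#' @param n_perm permutations; default 1000.
#' @param alpha significance level applied to adjusted p-values.
#' @param seed RNG seed.
#' @return list with `p_raw`, `p_adj`, `mask` (same vertex/window shape).
#' @export
vertex_permutation_bh <- function(accuracy, chance = 0.25, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  x <- accuracy
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  n <- d[1]
  local_seed(seed)
  p_raw <- p_adj <- array(NA_real_, d[2:3])
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  for (w in seq_len(d[3])) {
    Xw <- x[, , w, drop = FALSE][, , 1] - chance
    if (is.null(dim(Xw))) Xw <- matrix(Xw, nrow = n)
    obs <- colMeans(Xw)
    nullm <- (S %*% Xw) / n
    p_raw[, w] <- vapply(seq_len(d[2]), function(v) {
      (1 + sum(nullm[, v] >= obs[v])) / (n_perm + 1)
    }, numeric(1))
    p_adj[, w] <- bh_adjust(p_raw[, w])
  }
  mask <- p_adj <= alpha
  if (length(dim(accuracy)) == 2L) {
    p_raw <- p_raw[, 1]; p_adj <- p_adj[, 1]; mask <- mask[, 1]
  }
  list(p_raw = p_raw, p_adj = p_adj, mask = mask, alpha = alpha,
       n_perm = n_perm, chance = chance)
}
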