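test_that("Friedman test matches the hand-ranked oracle", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, byrow = TRUE)
  res <- friedman_rank_test(m)
  expect_equal(res$chi2, 6)
  expect_equal(res$df, 2)

  # identical conditions: zero statistic, p = 1
  expect_warning(res0 <- friedman_rank_test(matrix(2, 3, 3)), "constant")
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)

  # column permutation leaves the statistic unchanged
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(friedman_rank_test(x)$chi2,
               friedman_rank_test(x[, c(3, 1, 2)])$chi2)
})

test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration", {
  set.seed(3)
  x <- rnorm(8) + 0.5
  res <- wilcoxon_signed_rank(x, method = "exact")

  # independent oracle: enumerate all 2^8 sign assignments
  rk <- rank(abs(x))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  W <- as.vector(signs %*% rk)
  w_obs <- sum(rk[x > 0])
  p_two <- min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
  expect_equal(res$p, p_two, tolerance = 1e-9)
  expect_equal(res$w_plus, w_obs)

  # one-sided enumerations
  expect_equal(wilcoxon_signed_rank(x, method = "exact",
                                    alternative = "greater")$p,
               mean(W >= w_obs), tolerance = 1e-9)
  expect_equal(wilcoxon_signed_rank(x, method = "exact",
                                    alternative = "less")$p,
               mean(W <= w_obs), tolerance = 1e-9)
})

test_that("Wilcoxon z is antisymmetric and degenerate input is flagged", {
  set.seed(4)
  x <- rnorm(12)
  y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$z, -wilcoxon_signed_rank(y, x)$z)
  expect_warning(res <- wilcoxon_signed_rank(x, x), "zero")
  expect_true(is.na(res$p))
  expect_equal(res$n, 0L)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ps <- sort(runif(10))
  expect_true(!is.unsorted(bh_adjust(ps)))
})

test_that("cluster permutation detects contiguous effects with the right tail", {
  set.seed(6)
  X <- matrix(rnorm(10 * 60), 10)
  X[, 21:35] <- X[, 21:35] + 1.5
  cr <- cluster_permutation(X, n_perm = 500, seed = 1)
  sp <- significant_spans(cr)
  expect_gte(nrow(sp), 1)
  overlap <- max(0, min(35, sp$end[1]) - max(21, sp$start[1]) + 1) / 15
  expect_gte(overlap, 0.8)

  # tail reversal flips the detected sign
  crn <- cluster_permutation(-X, n_perm = 500, seed = 1, tail = "neg")
  spn <- significant_spans(crn)
  expect_gte(nrow(spn), 1)
  expect_lt(spn$mass[1], 0)

  # p-values honor the permutation lower bound
  expect_true(all(cr$clusters$p >= 1 / 501))

  # extreme cluster-forming threshold: only single-point clusters remain
  crh <- cluster_permutation(X, n_perm = 200, seed = 2,
                             cluster_threshold = max(abs(cr$tmap)) - 1e-9)
  if (nrow(crh$clusters) > 0) expect_true(all(crh$clusters$size == 1))

  expect_warning(cluster_permutation(X, n_perm = 50, seed = 1), "coarse")
})

test_that("cluster permutation controls family-wise error on null data", {
  fp <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(r)
    X <- matrix(rnorm(8 * 40), 8)
    cr <- cluster_permutation(X, n_perm = 300, seed = r + 1000)
    if (any(cr$clusters$p <= 0.05)) fp <- fp + 1
  }
  # FWER <= alpha within Monte-Carlo uncertainty
  expect_lte(fp / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("two-dimensional cluster search respects 4-connectivity", {
  set.seed(7)
  X <- array(rnorm(8 * 6 * 20), c(8, 6, 20))
  X[, 2:4, 5:10] <- X[, 2:4, 5:10] + 2
  cr <- cluster_permutation(X, n_perm = 300, seed = 3)
  sp <- cr$clusters[cr$clusters$p <= 0.05, ]
  expect_gte(nrow(sp), 1)
  big <- which.max(sp$size)
  members <- cr$members[[sp$id[big]]]
  mask <- array(FALSE, c(6, 20))
  mask[members] <- TRUE
  expect_gt(mean(mask[2:4, 5:10]), 0.8)
})

test_that("vertex-wise permutation with BH calibrates and shrinks with alpha", {
  set.seed(8)
  null_acc <- matrix(0.25 + rnorm(8 * 50, sd = 0.05), 8)
  vp <- vertex_permutation_bh(null_acc, n_perm = 500, seed = 1)
  expect_lt(mean(vp$mask), 0.10)

  strong <- matrix(0.6 + rnorm(8 * 50, sd = 0.02), 8)
  vps <- vertex_permutation_bh(strong, n_perm = 500, seed = 1)
  expect_true(all(vps$mask))

  vp01 <- vertex_permutation_bh(null_acc, n_perm = 500, alpha = 0.01, seed = 1)
  expect_true(all(which(vp01$mask) %in% which(vp$mask)))
})
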