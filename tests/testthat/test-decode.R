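test_that("the CV harness is exact on separable data and honest at chance", {
  set.seed(1)
  n_per <- 25
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k) {
    sweep(matrix(rnorm(n_per * 2, sd = 0.3), n_per), 2, centers[k, ], "+")
  }))
  y <- rep(c("thumb", "index", "middle", "little"), each = n_per)
  res <- cv_ovr_linear(X, y, seed = 1)
  expect_equal(res$mean_accuracy, 1.0)
  expect_equal(sum(res$confusion), 100)
  expect_equal(rowSums(res$confusion), table(factor(y))[rownames(res$confusion)],
               ignore_attr = TRUE)
  expect_equal(res$mean_accuracy,
               sum(diag(res$confusion)) / sum(res$confusion), tolerance = 0.01)

  # permuted labels: within binomial CI of chance
  set.seed(2)
  Xn <- matrix(rnorm(400 * 10), 400)
  yn <- sample(rep(c("a", "b", "c", "d"), 100))
  resn <- cv_ovr_linear(Xn, yn, seed = 3)
  expect_lt(abs(resn$mean_accuracy - 0.25), chance_ci(400))

  # duplicating feature columns leaves accuracy unchanged
  res2 <- cv_ovr_linear(cbind(X, X), y, seed = 1)
  expect_equal(res2$mean_accuracy, res$mean_accuracy)

  expect_error(cv_ovr_linear(X[1:8, ], y[1:8]), "at least")
  expect_warning(cv_ovr_linear(matrix(0, 40, 3), rep(c("a", "b"), 20)),
                 "zero variance")
})

test_that("fold assignment is stratified, seeded and reproducible", {
  y <- factor(rep(c("a", "b", "c", "d"), each = 20))
  f1 <- fingermeg:::stratified_folds(y, 5, seed = 7)
  f2 <- fingermeg:::stratified_folds(y, 5, seed = 7)
  expect_identical(f1, f2)
  tab <- table(y, f1)
  expect_true(all(tab == 4))
  f3 <- fingermeg:::stratified_folds(y, 5, seed = 8)
  expect_false(identical(f1, f3))
})

test_that("fold-aware feature functions never see test trials", {
  src <- fx_src()
  fn <- pca_feature_fun(src, decim = 10L)
  train <- 1:40
  test <- 41:60
  a <- fn(train, test)
  # perturbing test trials must not change fitted loadings or train features
  src2 <- src
  src2$data[test, , ] <- src2$data[test, , ] * 5 + 1
  fn2 <- pca_feature_fun(src2, decim = 10L)
  b <- fn2(train, test)
  expect_equal(a$train, b$train, tolerance = 1e-12)

  amap <- activation_index(fx_fit(), fx_delta())
  fne <- a_epoch_feature_fun(src, amap, decim = 10L)
  fe <- fne(train, test)
  expect_equal(ncol(fe$train), 8 * length(seq(1, 900, by = 10)))
})

test_that("point-wise and window-wise series have the expected geometry", {
  src <- fx_src()
  pw <- pointwise_decode(src, decim = 150L, seed = 1)
  expect_equal(nrow(pw$series), ceiling(1200 / 150))
  expect_equal(pw$chance, 0.25)

  # pre-signal baseline at chance, peak near movement onset above it
  base_pts <- pw$series$accuracy[pw$series$time < -1]
  expect_lt(mean(base_pts), 0.25 + chance_ci(60) + 0.15)

  awm <- a_window_maps(fx_fit(), fx_delta(), window = 0.05, span = c(-0.5, 0.5))
  ww <- windowwise_decode(awm, seed = 1)
  expect_equal(nrow(ww$series), 20)
  expect_gt(max(ww$series$accuracy), 0.5)
})

test_that("feature schemes match their stated dimensionality and agree when
           extrema coincide", {
  src <- fx_src()
  amap <- activation_index(fx_fit(), fx_delta())
  ex <- extrema_vertices(amap)
  fe <- features_a_epoch(src, ex)
  expect_equal(dim(fe), c(60, 8 * 900))

  awm <- a_window_maps(fx_fit(), fx_delta())
  exw <- extrema_vertices(awm)
  fw <- features_a_window(src, exw)
  expect_equal(ncol(fw), ncol(fe)) # dimensionality parity by construction

  # force every window to pick the same 8 vertices: features must coincide
  exw_same <- exw
  for (w in unique(exw_same$window)) {
    exw_same[exw_same$window == w, c("max_vertex", "min_vertex")] <-
      ex[, c("max_vertex", "min_vertex")]
  }
  fw_same <- features_a_window(src, exw_same)
  expect_equal(sort(fw_same[1, ]), sort(fe[1, ]), tolerance = 1e-12)

  pcaf <- features_pca(src, decim = 5L)
  p <- roi_pca(src)
  expect_equal(dim(pcaf), c(60, p$n_components * 180))
})

test_that("power features separate amplitude-coded classes that phase hides", {
  sf <- 200
  tt <- seq(0, 2 - 1 / sf, by = 1 / sf)
  set.seed(11)
  n_per <- 20
  # class a: constant amplitude; class b: amplitude-modulated, random phase
  mk <- function(amp_mod) t(sapply(seq_len(n_per), function(i) {
    ph <- runif(1, 0, 2 * pi)
    env <- if (amp_mod) 1 + sin(2 * pi * 1 * tt) else rep(1, length(tt))
    env * sin(2 * pi * 20 * tt + ph) + rnorm(length(tt), sd = 0.1)
  }))
  X <- array(0, c(2 * n_per, 1, length(tt)))
  X[, 1, ] <- rbind(mk(FALSE), mk(TRUE))
  y <- rep(c("a", "b"), each = n_per)
  fpow <- features_power(X, sf, freqs = 20, decim = 4L)
  acc_pow <- cv_ovr_linear(fpow, y, seed = 1)$mean_accuracy
  acc_raw <- cv_ovr_linear(matrix(X[, 1, seq(1, 400, 4)], 2 * n_per), y,
                           seed = 1)$mean_accuracy
  expect_gt(acc_pow, 0.9)
  expect_lt(acc_raw, acc_pow)

  # permuted labels: chance
  yp <- sample(y)
  expect_lt(abs(cv_ovr_linear(fpow, yp, seed = 2)$mean_accuracy - 0.5),
            1.96 * sqrt(0.25 / 40) + 0.1)
})

test_that("virtual channels collect extrema of decodable windows only", {
  awm <- a_window_maps(fx_fit(), fx_delta())
  exw <- extrema_vertices(awm)
  vcs <- build_virtual_channels(exw, decodable_windows = c(20, 21, 25))
  expect_false(vcs$empty)
  expect_equal(nrow(vcs$entries), 3 * 4 * 2)
  expect_equal(nrow(vcs$decodable_timespans), 3)

  expect_warning(v0 <- build_virtual_channels(exw, integer(0)), "empty")
  expect_true(v0$empty)
})

test_that("single-window and combined schemes share folds; one window means
           combined equals single", {
  src <- fx_src()
  awm <- a_window_maps(fx_fit(), fx_delta())
  exw <- extrema_vertices(awm)
  vcs1 <- build_virtual_channels(exw, decodable_windows = 21L)
  svc1 <- single_vs_combined(src, vcs1, seed = 5)
  expect_equal(svc1$combined$mean_accuracy, svc1$single$mean_accuracy[1])
  expect_equal(length(svc1$combined$fold_accuracies), 5)
  expect_identical(svc1$combined$folds, svc1$single_results[[1]]$folds)

  vcs <- build_virtual_channels(exw, decodable_windows = c(19L, 21L, 23L))
  svc <- single_vs_combined(src, vcs, seed = 5)
  expect_equal(nrow(svc$single), 3)
  expect_equal(sum(!is.na(svc$comparison$window)), 3)
})

test_that("tidiers and plots expose decoding results coherently", {
  set.seed(12)
  X <- matrix(rnorm(80 * 5), 80)
  y <- rep(c("a", "b", "c", "d"), 20)
  res <- cv_ovr_linear(X, y, seed = 1)
  td <- tidy(res)
  expect_equal(nrow(td), 5)
  gl <- glance(res)
  expect_equal(gl$mean_accuracy, mean(td$accuracy))
  expect_equal(gl$chance, 0.25)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")

  pw <- pointwise_decode(fx_src(), decim = 400L, seed = 1)
  expect_s3_class(ggplot2::autoplot(pw), "ggplot")
  amap <- activation_index(fx_fit(), fx_delta())
  expect_s3_class(ggplot2::autoplot(amap), "ggplot")
})
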