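test_that("data covariance is pooled, symmetric and validated", {
  set.seed(1)
  n <- 1e5 / 4
  ep <- sensor_epochs(array(rnorm(4 * 4 * n), c(4, 4, n)), 100, 0,
                      labels = letters[1:4])
  C <- data_covariance(ep)
  expect_equal(C, t(C))
  expect_lt(max(abs(C - diag(4))), 0.05)

  # rank-1 data has one dominant eigenvalue
  arr <- array(0, c(2, 4, 50))
  pat <- c(1, 2, -1, 0.5)
  for (tr in 1:2) arr[tr, , ] <- outer(pat, rnorm(50))
  C1 <- data_covariance(sensor_epochs(arr, 100, 0, labels = c("a", "b")))
  ev <- eigen(C1, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / max(abs(ev[2]), 1e-300), 1e8)

  # duplicating trials leaves the covariance unchanged
  arr2 <- arr[c(1, 2, 1, 2), , ]
  C2 <- data_covariance(sensor_epochs(arr2, 100, 0, labels = letters[1:4]))
  expect_equal(C1, C2, tolerance = 1e-12)

  bad <- array(NaN, c(1, 2, 10))
  expect_error(data_covariance(sensor_epochs(bad, 10, 0, labels = "a")), "NaN")
})

test_that("LCMV weights satisfy unit gain and scale inversely with the lead field", {
  m <- fx_model()
  C <- data_covariance(fx_delta())
  fit <- fit_lcmv(m, C, reg = 0.05)
  lf_eff <- fingermeg:::effective_leadfield(m, fit)
  gains <- sapply(seq_len(nrow(fit$weights)), function(v) {
    sum(fit$weights[v, ] * lf_eff[, v])
  })
  expect_equal(gains, rep(1, length(gains)), tolerance = 1e-6)

  # fixed-orientation model: identity covariance gives closed-form weights,
  # and scaling a lead-field column by c scales the weight row by 1/c
  mfix <- list(leadfield = m$leadfield)
  ffix <- fit_lcmv(mfix, diag(nrow(m$leadfield)), reg = 0)
  l1 <- m$leadfield[, 1]
  expect_equal(ffix$weights[1, ], l1 / sum(l1^2), tolerance = 1e-6)
  mscaled <- list(leadfield = m$leadfield)
  mscaled$leadfield[, 1] <- 3 * mscaled$leadfield[, 1]
  fscaled <- fit_lcmv(mscaled, diag(nrow(m$leadfield)), reg = 0)
  expect_equal(fscaled$weights[1, ], ffix$weights[1, ] / 3, tolerance = 1e-9)

  expect_error(fit_lcmv(mfix, matrix(0, 24, 24), reg = 0), "reg > 0")
})

test_that("a simulated point source is localized to its vertex", {
  m <- fx_model()
  cfg <- meg_sim_config(n_trials_per_task = 3, snr = 100, amp_background = 0,
                        amp_alpha = 0, amp_beta = 0, amp_hgamma = 0,
                        active_vertices = list(thumb = 11L, index = 11L,
                                               middle = 11L, little = 11L))
  sim <- simulate_meg(m, cfg, seed = 4)
  fit <- fit_lcmv(m, data_covariance(sim$epochs), reg = 0.05)
  src <- reconstruct(sim$epochs, fit)
  pw <- apply(src$data, 2, function(x) var(as.vector(x)))
  am <- which.max(pw)
  d <- sqrt(rowSums(sweep(m$vertex_positions, 2, m$vertex_positions[11, ])^2))
  expect_lte(rank(d)[am], max(2, ceiling(0.05 * length(d))))

  # noise-free reconstruction at the true vertex tracks the source
  cfg0 <- meg_sim_config(n_trials_per_task = 2, snr = 1e9, amp_background = 0,
                         amp_alpha = 0, amp_beta = 0, amp_hgamma = 0,
                         amp_theta = 0, latency_jitter = 0, amp_jitter = 0,
                         active_vertices = list(thumb = 11L, index = 11L,
                                                middle = 11L, little = 11L))
  sim0 <- simulate_meg(m, cfg0, seed = 5)
  fit0 <- fit_lcmv(m, data_covariance(sim0$epochs), reg = 0.0001)
  src0 <- reconstruct(sim0$epochs, fit0)
  tvec <- epoch_times(sim0$epochs)
  truth <- exp(-0.5 * (tvec / 0.35)^2) * cos(2 * pi * 2.5 * tvec)
  expect_gt(abs(cor(src0$data[1, 11, ], truth)), 0.9)
})

test_that("reconstruction is linear and channel-checked", {
  fit <- fx_fit()
  ep <- fx_delta()
  src <- reconstruct(ep, fit)
  ep2 <- ep
  ep2$data <- 2 * ep$data
  expect_equal(reconstruct(ep2, fit)$data, 2 * src$data)
  ep0 <- ep
  ep0$data <- ep$data * 0
  expect_true(all(reconstruct(ep0, fit)$data == 0))
  bad <- ep
  bad$data <- ep$data[, 1:5, , drop = FALSE]
  bad$channel_names <- bad$channel_names[1:5]
  expect_error(reconstruct(bad, fit), "mismatch")
})

test_that("activation index reproduces the quadratic-form oracle", {
  fit <- fx_unit_fit()
  ep <- fx_oracle_epochs()
  # task window [1, 2) has channel-1 variance 4; baseline [0, 1) variance 1
  am <- activation_index(fit, ep, task_window = c(1, 2),
                         baseline_window = c(0, 1))
  expect_equal(am$A_trial[1, 1], (4 - 1) / (4 + 1), tolerance = 1e-12)

  # antisymmetry under window swap
  am_swap <- activation_index(fit, ep, task_window = c(0, 1),
                              baseline_window = c(1, 2))
  expect_equal(am_swap$A_trial[1, 1], -am$A_trial[1, 1], tolerance = 1e-12)

  # equal windows give exactly zero
  am0 <- activation_index(fit, ep, task_window = c(0, 1),
                          baseline_window = c(0, 1))
  expect_equal(am0$A_trial[1, 1], 0, tolerance = 1e-12)

  # bounds on real simulated data
  amr <- activation_index(fx_fit(), fx_delta())
  expect_true(all(amr$A_trial > -1 & amr$A_trial < 1, na.rm = TRUE))
})

test_that("windowed activation maps tile the span exactly", {
  fit <- fx_fit()
  ep <- fx_delta()
  awm <- a_window_maps(fit, ep)
  expect_equal(dim(awm$A), c(4, 40, 60))
  expect_equal(awm$window_starts[1], -1)
  expect_equal(diff(awm$window_starts)[1], 0.05)
  expect_error(a_window_maps(fit, ep, window = 0.0501), "integer number")
  expect_error(a_window_maps(fit, ep, span = c(-1, 1.98)), "divisible")

  # stationary input: trial-averaged A roughly constant across windows
  set.seed(8)
  n <- 1200
  arr <- array(rnorm(16 * 2 * n), c(16, 2, n))
  epn <- sensor_epochs(arr, 300, -2, labels = rep(c("a", "b"), 8))
  awn <- a_window_maps(fx_unit_fit(), epn)
  expect_lt(sd(apply(awn$A, 3, mean)), 0.05)
})

test_that("extrema selection handles ties, NaN and windowed maps", {
  map <- structure(list(
    A = matrix(c(0.9, 0.1, -0.5, 0.2,
                 0.9, 0.9, -0.5, -0.5), 2, 4, byrow = TRUE),
    tasks = c("t1", "t2"), window_length = NULL),
    class = "activation_map")
  ex <- extrema_vertices(map)
  expect_equal(ex$max_vertex, c(1L, 1L)) # tie in row 2 -> lowest index
  expect_equal(ex$min_vertex, c(3L, 3L))

  awm <- a_window_maps(fx_fit(), fx_delta())
  exw <- extrema_vertices(awm)
  expect_equal(nrow(exw), 60 * 4)

  nan_map <- map
  nan_map$A[] <- NaN
  expect_error(extrema_vertices(nan_map), "NaN")
})

test_that("ROI PCA retains the smallest component set past the variance target", {
  # rank-1 data -> one component carrying all variance
  arr <- array(0, c(3, 6, 40))
  pat <- rnorm(6)
  for (tr in 1:3) arr[tr, , ] <- outer(pat, rnorm(40))
  se <- source_epochs(arr, 100, 0, labels = c("a", "b", "a"))
  p1 <- roi_pca(se)
  expect_equal(p1$n_components, 1L)
  expect_gt(p1$explained[1], 0.999)

  # isotropic noise: need ~var_frac of the vertex count
  set.seed(9)
  arr2 <- array(rnorm(20 * 30 * 100), c(20, 30, 100))
  p2 <- roi_pca(source_epochs(arr2, 100, 0, labels = rep(c("a", "b"), 10)),
                var_frac = 0.70)
  expect_equal(p2$n_components / 30, 0.70, tolerance = 0.10)

  # retained set explains more than the target by construction
  p3 <- roi_pca(fx_src(), 0.70)
  expect_gt(sum(p3$explained[seq_len(p3$n_components)]), 0.70)
  expect_equal(dim(p3$scores), c(60, p3$n_components, 1200))

  expect_error(roi_pca(se, var_frac = 0), "var_frac")
  expect_error(roi_pca(se, var_frac = 1.2), "var_frac")
})
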