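test_that("vertex-wise decoding records four-class and per-class accuracy", {
  src <- fx_src()
  vw <- vertexwise_decode(src, windows = 20:21, vertices = 1:4, seed = 1)
  expect_equal(dim(vw$accuracy), c(60, 40))
  expect_equal(sum(!is.na(vw$accuracy)), 2 * 4)
  expect_equal(dim(vw$per_class), c(60, 40, 4))
  done <- vw$accuracy[20:21, 1:4]
  expect_true(all(done >= 0 & done <= 1))
})

test_that("a vertex carrying one task's signal prefers that task", {
  m <- fx_model()
  centers <- fingermeg:::maximin_vertices(m$vertex_positions, 4)
  av <- as.list(centers)
  names(av) <- c("thumb", "index", "middle", "little")
  cfg <- meg_sim_config(n_trials_per_task = 15, snr = 5, amp_background = 0.1,
                        active_vertices = av)
  sim <- simulate_meg(m, cfg, seed = 6)
  delta <- bandpass(sim$epochs, 0.5, 4, "delta")
  fit <- fit_lcmv(m, data_covariance(delta))
  src <- reconstruct(delta, fit)
  vw <- vertexwise_decode(src, windows = 21L,
                          vertices = c(av$thumb, av$index), seed = 1)
  expect_equal(names(which.max(vw$per_class[21, av$thumb, ])), "thumb")
  expect_equal(names(which.max(vw$per_class[21, av$index, ])), "index")
})

test_that("individual labeling takes the per-class argmax and leaves ties out", {
  pc <- array(NA_real_, c(2, 3, 4), dimnames = list(NULL, NULL,
              c("thumb", "index", "middle", "little")))
  pc[1, 1, ] <- c(0.9, 0.1, 0.1, 0.1)
  pc[1, 2, ] <- c(0.3, 0.3, 0.3, 0.3) # exact tie -> unassigned
  pc[2, 3, ] <- c(0.1, 0.2, 0.6, 0.1)
  lab <- label_individual(pc)
  expect_equal(lab[1, 1], "thumb")
  expect_true(is.na(lab[1, 2]))
  expect_equal(lab[2, 3], "middle")
  expect_true(is.na(lab[2, 2]))

  # relabeling the task axis permutes labels correspondingly
  perm <- c(4, 3, 2, 1)
  pcp <- pc[, , perm]
  labp <- label_individual(pcp)
  expect_equal(labp[1, 1], "thumb")
  expect_equal(labp[2, 3], "middle")
})

test_that("group voting assigns the majority label inside the significant mask", {
  tasks <- c("thumb", "index", "middle", "little")
  n_sub <- 6
  set.seed(20)
  # 2 windows x 5 vertices; vertex 1 unanimous thumb, vertex 2 majority
  # index (4 of 6), vertex 3 a 3-3 tie, vertices 4-5 at chance
  labs <- lapply(seq_len(n_sub), function(s) {
    m <- matrix(NA_character_, 2, 5)
    m[, 1] <- "thumb"
    m[, 2] <- if (s <= 4) "index" else "middle"
    m[, 3] <- if (s <= 3) "middle" else "little"
    m[, 4] <- sample(tasks, 1)
    m
  })
  accs <- lapply(seq_len(n_sub), function(s) {
    a <- matrix(0.25, 2, 5)
    a[, 1:3] <- 0.7 # strongly decodable vertices
    a + matrix(rnorm(10, sd = 0.01), 2, 5)
  })
  set.seed(20)
  dm <- suppressMessages(
    group_digit_map(labs, accs, tasks, n_perm = 500, seed = 2))
  expect_true(all(dm$significant[, 1:3]))
  expect_equal(unname(dm$labels[, 1]), rep("thumb", 2))
  expect_equal(unname(dm$labels[, 2]), rep("index", 2))
  expect_true(all(is.na(dm$labels[, 3]))) # tie left unassigned
  expect_true(all(is.na(dm$labels[!dm$significant])))
})

test_that("finger counts conserve totals and apply the stated threshold rule", {
  # constructed map whose maximum per-window total is 80
  tasks <- c("thumb", "index", "middle", "little")
  labels <- matrix(NA_character_, 2, 100)
  labels[1, 1:80] <- rep(tasks, each = 20)
  labels[2, 1:40] <- rep(tasks, each = 10)
  fc <- finger_counts(list(labels = labels, tasks = tasks))
  expect_equal(fc$threshold, 0.25 * 80 / 4) # = 5
  totals <- tapply(fc$counts$count, fc$counts$window, sum)
  expect_equal(as.numeric(totals), c(80, 40))
  expect_true(all(fc$counts$above_threshold == (fc$counts$count > 5)))

  # empty map: zero threshold, nothing flagged
  fc0 <- finger_counts(list(labels = matrix(NA_character_, 2, 10),
                            tasks = tasks))
  expect_equal(fc0$threshold, 0)
  expect_true(all(!fc0$counts$above_threshold))
})

test_that("significance masks shrink as alpha decreases", {
  tasks <- c("thumb", "index", "middle", "little")
  set.seed(21)
  labs <- lapply(1:6, function(s) matrix("thumb", 1, 8))
  accs <- lapply(1:6, function(s) matrix(0.25 + runif(8, 0, 0.3), 1))
  d1 <- suppressMessages(group_digit_map(labs, accs, tasks, alpha = 0.05,
                                         n_perm = 300, seed = 3))
  d2 <- suppressMessages(group_digit_map(labs, accs, tasks, alpha = 0.01,
                                         n_perm = 300, seed = 3))
  expect_true(all(which(d2$significant) %in% which(d1$significant)))
})
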