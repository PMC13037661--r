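#' Build a spherical-patch source model with a single-sphere lead field
#'
#' Constructs a desk-scale stand-in for a sensorimotor region of interest:
#' `n_vertices` source locations sampled on a spherical-cap cortical patch
#' inside a hemispherical array of `n_channels` radial magnetometers. The
#' lead field uses the closed-form magnetic field of a current dipole in a
#' homogeneous conducting sphere (Sarvas), for which radial dipole components
#' are externally silent; vertex orientations are therefore drawn tangential
#' to the sphere.
#'
#' @param n_vertices number of source locations (>= 2); default 200.
#' @param n_channels number of sensors (>= 8); default 64.
#' @param seed integer RNG seed; the model is deterministic given the seed.
#' @param cortex_radius,sensor_radius radii in meters of the source shell and
#'   sensor shell.
#' @param cap_angle angular radius (radians) of the ROI patch.
#' @param forward `"sphere"` for the dipole forward model, `"random"` for a
#'   smooth random gain matrix (unit-test fallback without geometry).
#' @return A `source_model` list: `vertex_positions` (n_vertices x 3, m),
#'   `vertex_orientations` (unit tangential 3-vectors), `leadfield`
#'   (n_channels x n_vertices, fixed orientation), `leadfield3`
#'   (n_channels x n_vertices x 3, Cartesian unit moments),
#'   `tangential_basis` (n_vertices x 3 x 2), `sensor_positions`.
#' @examples
#' m <- make_source_model(n_vertices = 20, n_channels = 16, seed = 1)
#' dim(m$leadfield)
#' @export
make_source_model <- function(n_vertices = 200, n_channels = 64, seed = 1,
                              cortex_radius = 0.08, sensor_radius = 0.12,
                              cap_angle = 0.35, forward = c("sphere", "random")) {
  stopifnot(n_vertices >= 2, n_channels >= 8)
  forward <- match.arg(forward)
  rng <- local_seed(seed)

  # ROI patch center: tilted off the vertex toward the left hemisphere, a
  # rough proxy for the hand knob of contralateral M1/S1.
  u <- c(-0.35, 0.10, 0.93)
  u <- u / sqrt(sum(u^2))
  basis <- orthonormal_basis(u)

  # Uniform sample on the spherical cap around u.
  cosmax <- cos(cap_angle)
  costh <- runif(n_vertices, cosmax, 1)
  sinth <- sqrt(pmax(0, 1 - costh^2))
  phi <- runif(n_vertices, 0, 2 * pi)
  dirs <- cbind(sinth * cos(phi), sinth * sin(phi), costh) %*% t(basis)
  pos <- cortex_radius * dirs

  # Tangential unit orientations (radial dipoles are silent in the sphere).
  # The orientation field is spatially smooth -- a common patch direction
  # with per-vertex jitter -- mirroring the locally coherent normals of a
  # cortical patch; fully random orientations would make adjacent coherent
  # sources sum to a field no single displaced dipole explains.
  g <- rnorm(3)
  g <- g / sqrt(sum(g^2))
  ori <- matrix(0, n_vertices, 3)
  tang <- array(0, c(n_vertices, 3, 2))
  for (v in seq_len(n_vertices)) {
    rad <- dirs[v, ]
    tang[v, , ] <- orthonormal_basis(rad)[, 1:2] # columns orthogonal to rad
    repeat {
      o <- g + 0.3 * rnorm(3)
      o <- o - sum(o * rad) * rad
      if (sqrt(sum(o^2)) > 0.1) break
    }
    ori[v, ] <- o / sqrt(sum(o^2))
  }

  # Sensor shell: Fibonacci points on the upper hemisphere, radial pickup.
  sens <- fibonacci_hemisphere(n_channels) * sensor_radius

  lf3 <- array(0, c(n_channels, n_vertices, 3))
  if (forward == "sphere") {
    for (v in seq_len(n_vertices)) {
      lf3[, v, ] <- sarvas_leadfield(pos[v, ], sens)
    }
  } else {
    # Smooth random gains: spatially correlated across sensors.
    for (k in 1:3) {
      g <- matrix(rnorm(n_channels * n_vertices), n_channels)
      lf3[, , k] <- smooth_gain(g)
    }
  }
  lf <- matrix(0, n_channels, n_vertices)
  for (v in seq_len(n_vertices)) {
    lf[, v] <- lf3[, v, ] %*% ori[v, ]
  }
  if (any(colSums(abs(lf)) < 1e-30)) {
    stop("lead field has an all-zero column; degenerate geometry", call. = FALSE)
  }
  structure(
    list(vertex_positions = pos, vertex_orientations = ori,
         leadfield = lf, leadfield3 = lf3, tangential_basis = tang,
         sensor_positions = sens, roi_labels = rep("SM1", n_vertices),
         forward = forward, seed = seed),
    class = "source_model"
  )
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d vertices, %d channels (%s forward)\n",
              nrow(x$vertex_positions), nrow(x$leadfield), x$forward))
  invisible(x)
}

# Radial component of the Sarvas single-sphere dipole field at each sensor,
# for the three Cartesian unit moments at source position r0. Returns a
# n_sensors x 3 gain matrix (T per A*m, up to the mu0/4pi constant absorbed
# into a fixed scale).
sarvas_leadfield <- function(r0, sensors) {
  n <- nrow(sensors)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- sensors[i, ]
    rn <- sqrt(sum(r^2))
    a <- r - r0
    an <- sqrt(sum(a^2))
    Fs <- an * (rn * an + rn^2 - sum(r0 * r))
    adotr <- sum(a * r)
    gradF <- (an^2 / rn + adotr / an + 2 * an + 2 * rn) * r -
      (an + 2 * rn + adotr / an) * r0
    rhat <- r / rn
    for (k in 1:3) {
      q <- c(0, 0, 0); q[k] <- 1
      qxr0 <- cross3(q, r0)
      B <- (Fs * qxr0 - sum(qxr0 * r) * gradF) / Fs^2
      out[i, k] <- sum(B * rhat)
    }
  }
  # mu0 / 4pi prefactor; keeps sensor values at a convenient numeric scale.
  out * 1e-7
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal basis whose third column is the unit vector u.
orthonormal_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  pick <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(u, pick)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  cbind(e1, e2, u)
}

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                # upper hemisphere, z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

smooth_gain <- function(g) {
  # Moving-average smoothing along the sensor dimension for the random
  # forward fallback.
  k <- stats::filter(rbind(g[c(1, 1), ], g, g[rep(nrow(g), 2), ]),
                     rep(1 / 5, 5), sides = 2)
  as.matrix(k[3:(nrow(g) + 2), , drop = FALSE])
}

# Seed helper: every stochastic operation is deterministic given its seed.
local_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Default configuration for the MEG simulator
#'
#' The defaults encode the study conditions the analysis assumes: four task
#' classes (thumb/index/middle/little), epochs of \[-2, 2) s at 300 Hz around
#' movement onset, finger-specific phase-locked low-frequency (delta/theta)
#' activations clustered at distinct ROI locations peaking near onset,
#' alpha/beta oscillations with a pre/during-movement power dip (ERD) and a
#' post-movement rebound (ERS) on task-shared vertices, weak high-gamma
#' bursts at onset, 1/f background at every vertex, and white sensor noise
#' scaled to a target SNR.
#'
#' @param ... named overrides of any default field.
#' @return a named list of simulation parameters.
#' @export
meg_sim_config <- function(...) {
  cfg <- list(
    tasks = c("thumb", "index", "middle", "little"),
    n_trials_per_task = 40,
    sfreq = 300, tmin = -2, tmax = 2,
    snr = 1,                    # sensor signal/noise variance ratio
    cluster_size = 1,           # vertices per task-specific cluster
    active_vertices = NULL,     # optional list(task -> vertex indices)
    n_shared = 6,               # vertices carrying alpha/beta rhythms
    amp_delta = 3, amp_theta = 1.8, amp_alpha = 0.8, amp_beta = 0.5,
    amp_hgamma = 0.15, amp_background = 0.3,
    f_delta = 2.5, f_theta = 6, f_alpha = 10, f_beta = 20, f_hgamma = 75,
    latency_jitter = 0.05,      # max |latency| jitter, s
    amp_jitter = 0.15
  )
  utils::modifyList(cfg, list(...))
}

#' Simulate forward-projected MEG epochs with ground truth
#'
#' Generates source time courses with the movement-related structure
#' described in [meg_sim_config()], projects them through the model's lead
#' field, adds white sensor noise at the configured SNR, and returns the
#' broadband sensor epochs together with the full generating ground truth.
#'
#' @param source_model a [make_source_model()] object.
#' @param config a [meg_sim_config()] list.
#' @param seed integer RNG seed.
#' @return list with elements `epochs` ([sensor_epochs()]) and
#'   `ground_truth` (task labels, per-band active vertex sets, shared
#'   vertices, per-trial latency jitters, band envelope samples).
#' @export
simulate_meg <- function(source_model, config = meg_sim_config(), seed = 1) {
  cfg <- config
  if (cfg$snr <= 0) stop("snr must be positive", call. = FALSE)
  n_vert <- nrow(source_model$vertex_positions)
  lf <- source_model$leadfield
  rng <- local_seed(seed)

  tasks <- cfg$tasks
  n_tasks <- length(tasks)
  labels <- factor(sample(rep(tasks, cfg$n_trials_per_task)), levels = tasks)
  n_tr <- length(labels)
  times <- seq(cfg$tmin, cfg$tmax - 1 / cfg$sfreq, by = 1 / cfg$sfreq)
  n_samp <- length(times)

  # Task-specific clusters: maximally separated seeds + nearest neighbours.
  if (is.null(cfg$active_vertices)) {
    centers <- maximin_vertices(source_model$vertex_positions, n_tasks)
    act <- lapply(centers, function(cc) {
      d <- rowSums(sweep(source_model$vertex_positions, 2,
                         source_model$vertex_positions[cc, ])^2)
      order(d)[seq_len(min(cfg$cluster_size, n_vert))]
    })
    names(act) <- tasks
  } else {
    act <- cfg$active_vertices
    if (!all(tasks %in% names(act))) stop("active_vertices must name every task",
                                          call. = FALSE)
  }
  all_active <- sort(unique(unlist(act)))
  shared <- setdiff(seq_len(n_vert), all_active)
  shared <- if (length(shared) >= cfg$n_shared) {
    sample(shared, cfg$n_shared)
  } else shared

  # Band envelopes on the common time grid.
  env_delta <- exp(-0.5 * (times / 0.35)^2)
  env_theta <- exp(-0.5 * (times / 0.20)^2)
  erd <- 1 - 0.6 * exp(-0.5 * ((times + 0.1) / 0.35)^2) +
    0.5 * exp(-0.5 * ((times - 0.9) / 0.30)^2)
  env_hg <- exp(-0.5 * ((times - 0.05) / 0.05)^2)

  # Fixed (trial-invariant) phases make delta/theta phase-locked; per-vertex
  # phase offsets give each cluster a distinct spatial pattern.
  ph_delta <- runif(n_vert, -0.4, 0.4)
  ph_theta <- runif(n_vert, -0.4, 0.4)

  jit <- runif(n_tr, -cfg$latency_jitter, cfg$latency_jitter)
  data <- array(0, c(n_tr, nrow(lf), n_samp))
  for (tr in seq_len(n_tr)) {
    S <- matrix(0, n_vert, n_samp)
    # 1/f background everywhere.
    if (cfg$amp_background > 0) {
      S <- S + cfg$amp_background * pink_noise_mat(n_vert, n_samp)
    }
    task <- as.character(labels[tr])
    av <- act[[task]]
    tj <- times - jit[tr]
    ed <- exp(-0.5 * (tj / 0.35)^2)
    et <- exp(-0.5 * (tj / 0.20)^2)
    ga <- 1 + cfg$amp_jitter * rnorm(1)
    for (v in av) {
      S[v, ] <- S[v, ] +
        ga * cfg$amp_delta * ed * cos(2 * pi * cfg$f_delta * tj + ph_delta[v]) +
        ga * cfg$amp_theta * et * cos(2 * pi * cfg$f_theta * tj + ph_theta[v])
    }
    # High-gamma burst on the task cluster, random phase (weak, induced).
    if (cfg$amp_hgamma > 0) {
      for (v in av) {
        S[v, ] <- S[v, ] + cfg$amp_hgamma * env_hg *
          cos(2 * pi * cfg$f_hgamma * tj + runif(1, 0, 2 * pi))
      }
    }
    # Alpha/beta sensorimotor rhythm on shared vertices, random phase per
    # trial (induced ERD/ERS).
    for (v in shared) {
      S[v, ] <- S[v, ] +
        cfg$amp_alpha * erd * cos(2 * pi * cfg$f_alpha * times + runif(1, 0, 2 * pi)) +
        cfg$amp_beta * erd * cos(2 * pi * cfg$f_beta * times + runif(1, 0, 2 * pi))
    }
    data[tr, , ] <- lf %*% S
  }

  # White sensor noise at the configured SNR (variance ratio against the
  # projected signal, pooled over channels and samples).
  sig_var <- var(as.vector(data))
  noise_sd <- sqrt(sig_var / cfg$snr)
  if (is.finite(noise_sd) && noise_sd > 0) {
    data <- data + array(rnorm(length(data), sd = noise_sd), dim(data))
  }

  epochs <- sensor_epochs(data, cfg$sfreq, cfg$tmin, band = "broadband",
                          labels = labels)
  gt <- list(
    task_labels = labels,
    active_vertex_sets = list(delta = act, theta = act),
    shared_vertices = shared,
    latency_jitter = jit,
    band_envelopes = list(delta = env_delta, theta = env_theta,
                          alpha_beta = erd, high_gamma = env_hg),
    config = cfg, seed = seed
  )
  list(epochs = epochs, ground_truth = gt)
}

# Greedy maximin selection of k well-separated vertex indices.
maximin_vertices <- function(pos, k) {
  n <- nrow(pos)
  d2 <- as.matrix(stats::dist(pos))^2
  sel <- which.max(rowSums(d2))
  while (length(sel) < k) {
    mind <- apply(d2[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    sel <- c(sel, which.max(mind))
  }
  as.integer(sel)
}

# Matrix of independent 1/f ("pink") noise rows, unit variance.
pink_noise_mat <- function(nrow, nsamp) {
  w <- matrix(rnorm(nsamp * nrow), nsamp, nrow)
  W <- stats::mvfft(w)
  f <- c(1, seq_len(nsamp - 1))
  f <- pmin(f, nsamp - f + 1) # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::mvfft(W, inverse = TRUE)) / nsamp
  x <- t(x)
  x / sd(as.vector(x))
}

#' Default configuration for the EMG simulator
#'
#' Epochs span \[0, 3) s with the visual cue at 0.5 s. Reaction times are
#' Gaussian around 643 ms (SD 90 ms); per-task burst durations center on
#' 241, 253, 289 and 295 ms, matching group-level movement times reported
#' for isolated extensions of the thumb, index, middle and little fingers.
#' Bursts are envelope-modulated white noise with a 5-ms rise/fall, with
#' per-task amplitudes and envelope shapes that make the four classes
#' learnable.
#'
#' @param ... named overrides.
#' @return a named list of EMG simulation parameters.
#' @export
emg_sim_config <- function(...) {
  cfg <- list(
    tasks = c("thumb", "index", "middle", "little"),
    n_trials_per_task = 40,
    sfreq = 1000, epoch_length = 4, cue_time = 0.5,
    baseline_sd = 0.05,
    rt_mean = 0.64265, rt_sd = 0.08974,
    duration_mean = c(thumb = 0.24118, index = 0.25272,
                      middle = 0.28860, little = 0.29450),
    duration_sd = 0.06,
    burst_amp = c(thumb = 0.45, index = 0.60, middle = 0.80, little = 0.50),
    shape_power = c(thumb = 0.3, index = 0.8, middle = 1.6, little = 2.6),
    rise_time = 0.005,
    # synchronized initial compound potential (ballistic AG1 burst)
    sync_amp = 3, sync_freq = 80, sync_ramp = 0.006, sync_tau = 0.025
  )
  utils::modifyList(cfg, list(...))
}

#' Simulate EMG epochs with known onsets and offsets
#'
#' Each trial is zero-mean baseline noise plus a burst of envelope-modulated
#' noise whose true onset and offset are recorded. Per-task amplitudes,
#' durations and envelope shapes differ so EMG classification is learnable.
#'
#' @param config an [emg_sim_config()] list.
#' @param seed integer RNG seed.
#' @return list with `epochs` ([emg_epochs()]) and `ground_truth`
#'   (`onset_sample`, `offset_sample`, `labels`, `rt_s`, `duration_s`).
#' @export
simulate_emg <- function(config = emg_sim_config(), seed = 1) {
  cfg <- config
  rng <- local_seed(seed)
  tasks <- cfg$tasks
  labels <- factor(sample(rep(tasks, cfg$n_trials_per_task)), levels = tasks)
  n_tr <- length(labels)
  n_samp <- round(cfg$epoch_length * cfg$sfreq)
  cue_sample <- round(cfg$cue_time * cfg$sfreq) + 1L

  data <- array(0, c(n_tr, 1L, n_samp))
  onset <- offset <- integer(n_tr)
  rts <- durs <- numeric(n_tr)
  tgrid <- (seq_len(n_samp) - 1L) / cfg$sfreq
  for (tr in seq_len(n_tr)) {
    task <- as.character(labels[tr])
    rt <- max(0.2, rnorm(1, cfg$rt_mean, cfg$rt_sd))
    dur <- max(0.12, rnorm(1, cfg$duration_mean[[task]], cfg$duration_sd))
    t_on <- cfg$cue_time + rt
    t_off <- t_on + dur
    if (t_off >= cfg$epoch_length) {
      stop(sprintf("trial %d: burst (%.3f-%.3f s) extends beyond the epoch",
                   tr, t_on, t_off), call. = FALSE)
    }
    env <- burst_envelope(tgrid, t_on, t_off, cfg$rise_time,
                          cfg$burst_amp[[task]], cfg$shape_power[[task]])
    sync <- sync_potential(tgrid, t_on, t_off, cfg$burst_amp[[task]], cfg)
    x <- rnorm(n_samp, sd = cfg$baseline_sd) + env * rnorm(n_samp) + sync
    data[tr, 1L, ] <- x
    onset[tr] <- as.integer(round(t_on * cfg$sfreq)) + 1L
    offset[tr] <- as.integer(round(t_off * cfg$sfreq)) + 1L
    rts[tr] <- rt
    durs[tr] <- dur
  }
  epochs <- emg_epochs(data, cfg$sfreq, t0 = 0, labels = labels,
                       cue_sample = cue_sample)
  gt <- list(onset_sample = onset, offset_sample = offset, labels = labels,
             rt_s = rts, duration_s = durs, config = cfg, seed = seed)
  list(epochs = epochs, ground_truth = gt)
}

# Burst amplitude envelope of the stochastic (interference-pattern)
# component: fast linear rise/fall over `rise` seconds with a task-specific
# power-law tilt across the plateau.
burst_envelope <- function(t, t_on, t_off, rise, amp, shape) {
  env <- numeric(length(t))
  inb <- t >= t_on & t < t_off
  u <- (t[inb] - t_on) / (t_off - t_on)
  plateau <- (1 - 0.5 * u)^shape
  ramp_up <- pmin(1, (t[inb] - t_on) / rise)
  ramp_dn <- pmin(1, (t_off - t[inb]) / rise)
  env[inb] <- amp * plateau * pmin(ramp_up, ramp_dn)
  env
}

# Deterministic synchronized compound potential at burst onset: brisk
# ballistic extensions begin with near-synchronous motor-unit recruitment
# (the initial agonist burst of the tri-phasic EMG pattern), which shows up
# as a large quasi-deterministic oscillatory transient rather than
# stationary interference noise.
sync_potential <- function(t, t_on, t_off, amp, cfg) {
  out <- numeric(length(t))
  inb <- t >= t_on & t < t_off
  tt <- t[inb] - t_on
  out[inb] <- cfg$sync_amp * amp * pmin(1, tt / cfg$sync_ramp) *
    exp(-tt / cfg$sync_tau) * sin(2 * pi * cfg$sync_freq * tt)
  out
}

#' Write simulation ground truth to a JSON sidecar
#'
#' @param ground_truth the `ground_truth` element of [simulate_meg()] or
#'   [simulate_emg()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$task_labels <- as.character(gt$task_labels)
  gt$labels <- if (!is.null(gt$labels)) as.character(gt$labels)
  gt$config <- NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
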