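# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: phase-coupled oscillators (phase measures), MVAR
# systems with known directed influence (GC/DTF/PDC), piecewise-stable
# topographies (microstates), and imbalanced feature cohorts (RSBagging).

# Best & Fisher (1979) rejection sampler for the von Mises distribution
# centred at 0; kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (u[2] < c_ * (2 - c_) || u[2] <= c_ * exp(1 - c_)) {
      i <- i + 1L
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  out
}

# coupling strength in [0,1] -> von Mises concentration; 1 = exact lock
kappa_from_strength <- function(s) {
  if (s >= 1) Inf else 10 * (s / (1 - s))^2
}

#' Coupling strength giving a target von Mises concentration
#'
#' Inverse of the strength-to-concentration map used by
#' [gen_oscillators()] (`kappa = 10 (s/(1-s))^2`), so oscillator pairs can
#' be generated with a prescribed phase-jitter concentration.
#'
#' @param kappa von Mises concentration (> 0).
#' @return Coupling strength in (0, 1).
#' @export
strength_from_kappa <- function(kappa) {
  if (kappa <= 0) stop("`kappa` must be > 0")
  q <- sqrt(kappa / 10)
  q / (1 + q)
}

#' Generate phase-coupled oscillator recordings
#'
#' Each channel carries a tone whose phase is redrawn uniformly per
#' `segment_s`-second segment (so downstream epochs see independent phase
#' observations). A coupling `(a, b, lag, strength)` replaces channel b's
#' segment phase with channel a's plus `lag` plus von Mises jitter whose
#' concentration grows with `strength` (`strength = 1`: exact lock;
#' `strength = 0`: independent). White sensor noise is added.
#'
#' @param n_channels number of channels.
#' @param tone_freq tone frequency in Hz (`fs > 2 tone_freq` required).
#' @param coupling list of couplings, each `list(a, b, lag, strength)`
#'   (channel indices, phase lag in radians, strength in \[0,1\]).
#' @param noise_sd white-noise standard deviation (signal amplitude is 1).
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param segment_s phase-segment length in seconds; match the downstream
#'   epoch length (default 2).
#' @param seed RNG seed.
#' @return A [recording()].
#' @export
gen_oscillators <- function(n_channels = 2L, tone_freq = 10, coupling = list(),
                            noise_sd = 0.1, fs = 250, duration_s = 60,
                            segment_s = 2, seed = 1L) {
  if (fs <= 2 * tone_freq) stop("`fs` must exceed twice the tone frequency")
  for (cp in coupling) {
    if (length(cp) != 4L) stop("each coupling is list(a, b, lag, strength)")
    if (cp[[4]] < 0 || cp[[4]] > 1) stop("coupling strength must be in [0, 1]")
    if (cp[[1]] > n_channels || cp[[2]] > n_channels) stop("coupling channel out of range")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  n <- round(duration_s * fs)
  seg_len <- round(segment_s * fs)
  n_seg <- ceiling(n / seg_len)
  phase <- matrix(stats::runif(n_channels * n_seg, 0, 2 * pi), n_channels, n_seg)
  for (cp in coupling) {
    kap <- kappa_from_strength(cp[[4]])
    jit <- if (is.infinite(kap)) numeric(n_seg) else rvonmises(n_seg, kap)
    phase[cp[[2]], ] <- phase[cp[[1]], ] + cp[[3]] + jit
  }
  t_idx <- seq_len(n) - 1L
  seg_of <- pmin((t_idx %/% seg_len) + 1L, n_seg)
  x <- matrix(0, n_channels, n)
  for (c in seq_len(n_channels)) {
    x[c, ] <- sin(2 * pi * tone_freq * t_idx / fs + phase[c, seg_of]) +
      noise_sd * stats::rnorm(n)
  }
  recording(x, fs, subject_id = "oscillators")
}

#' Simulate a recording from an MVAR model
#'
#' Exact simulation of `x_t = sum_k A_k x_{t-k} + e_t` with Gaussian noise
#' `e_t ~ N(0, Sigma)`; an initial burn-in is discarded so the series is
#' stationary. The model must be stable.
#'
#' @param coeffs list of coefficient matrices (or an [mvar_model()]).
#' @param noise_cov noise covariance (ignored when `coeffs` is a model).
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param burn_in samples discarded before recording starts.
#' @param seed RNG seed.
#' @return A [recording()] with the generating `mvar_model` in attribute
#'   `"model"`.
#' @export
gen_mvar <- function(coeffs, noise_cov = NULL, fs = 250, duration_s = 60,
                     burn_in = 500L, seed = 1L) {
  model <- if (inherits(coeffs, "mvar_model")) coeffs
           else mvar_model(coeffs, noise_cov, fs)
  n_ch <- nrow(model$coeffs[[1]])
  p <- model$order
  n <- round(duration_s * fs)
  L <- t(chol(model$noise_cov))
  rng <- local_rng(seed)
  on.exit(rng())
  total <- n + burn_in + p
  e <- L %*% matrix(stats::rnorm(n_ch * total), n_ch, total)
  x <- matrix(0, n_ch, total)
  for (t in (p + 1L):total) {
    xt <- e[, t]
    for (k in seq_len(p)) xt <- xt + model$coeffs[[k]] %*% x[, t - k]
    x[, t] <- xt
  }
  rec <- recording(x[, (burn_in + p + 1L):total, drop = FALSE], fs,
                   model$channel_labels, subject_id = "mvar")
  attr(rec, "model") <- model
  rec
}

#' Random zero-mean orthonormal scalp templates
#'
#' Utility for microstate simulations: `k` mutually orthogonal unit-norm
#' maps, each summing to zero across channels (average-reference
#' consistent).
#'
#' @param k number of templates.
#' @param n_channels channels per map.
#' @param seed RNG seed.
#' @return k x n_channels matrix with orthonormal rows.
#' @export
random_templates <- function(k, n_channels, seed = 1L) {
  if (k >= n_channels) stop("need k < n_channels for zero-mean orthonormal maps")
  rng <- local_rng(seed)
  on.exit(rng())
  m <- matrix(stats::rnorm(n_channels * k), n_channels, k)
  m <- m - rep(colMeans(m), each = n_channels)       # zero-mean columns
  t(qr.Q(qr(m))[, seq_len(k)])
}

#' Generate piecewise-stable microstate EEG
#'
#' Emits a sequence of scalp topographies: the active template is constant
#' within a segment whose length is drawn from a shifted geometric
#' distribution with mean `mean_duration_ms` (jitter 0 gives fixed-length
#' segments), consecutive segments always switch template, each segment's
#' polarity may flip at random (microstate analysis is polarity-invariant),
#' amplitude varies mildly per segment around `gfp_scale`, and white sensor
#' noise is added.
#'
#' @param templates k x n_channels matrix of maps (rows are centred and
#'   normalized internally), e.g. from [random_templates()].
#' @param mean_duration_ms mean segment duration (default 80, within the
#'   40-150 ms range typical of resting microstates).
#' @param duration_jitter fraction of the mean allotted to the geometric
#'   part, in \[0, 1); 0 = deterministic lengths (default 0.5).
#' @param gfp_scale target GFP scale in microvolts.
#' @param noise_sd sensor noise SD in microvolts.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param flip_polarity randomly negate segments (default TRUE).
#' @param seed RNG seed.
#' @return A [recording()] with attributes `"state_labels"` (true per-sample
#'   template index) and `"templates"` (the centred unit-norm maps).
#' @export
gen_microstate_eeg <- function(templates, mean_duration_ms = 80,
                               duration_jitter = 0.5, gfp_scale = 10,
                               noise_sd = 1, fs = 250, duration_s = 60,
                               flip_polarity = TRUE, seed = 1L) {
  templates <- as.matrix(templates)
  k <- nrow(templates)
  n_ch <- ncol(templates)
  if (n_ch < 2L) stop("templates need >= 2 channels")
  if (mean_duration_ms <= 0) stop("`mean_duration_ms` must be > 0")
  if (duration_jitter < 0 || duration_jitter >= 1) stop("`duration_jitter` in [0, 1)")
  templates <- templates - rowMeans(templates)
  templates <- norm_rows(templates)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- round(duration_s * fs)
  mean_len <- mean_duration_ms * fs / 1000
  floor_len <- max(1L, round(mean_len * (1 - duration_jitter)))
  geo_mean <- max(mean_len - floor_len, 0)
  labels <- integer(n)
  x <- matrix(0, n_ch, n)
  pos <- 0L
  state <- sample.int(k, 1L)
  while (pos < n) {
    len <- floor_len + if (geo_mean > 0) stats::rgeom(1L, 1 / (geo_mean + 1)) else 0L
    len <- min(len, n - pos)
    if (len > 0L) {
      amp <- gfp_scale * sqrt(n_ch) * stats::runif(1, 0.8, 1.2)
      u <- stats::runif(1)                     # drawn regardless, so the RNG
      sgn <- if (flip_polarity && u < 0.5) -1 else 1  # stream is flip-invariant
      idx <- (pos + 1L):(pos + len)
      x[, idx] <- sgn * amp * templates[state, ]
      labels[idx] <- state
      pos <- pos + len
    }
    state <- if (k > 1L) sample(setdiff(seq_len(k), state), 1L) else state
  }
  x <- x + noise_sd * matrix(stats::rnorm(n_ch * n), n_ch, n)
  rec <- recording(x, fs, subject_id = "microstates")
  attr(rec, "state_labels") <- labels
  attr(rec, "templates") <- templates
  rec
}

# Reference clinical cohort composition: per consciousness state, the
# subject count (female/male) and the B/L/R counts of stroke location and
# motor disturbance (remaining subjects have side "none").
table1_composition <- function() {
  data.frame(
    consciousness = consciousness_states(),
    female = c(37L, 18L, 13L, 3L, 0L, 1L),
    male = c(107L, 34L, 12L, 12L, 2L, 2L),
    loc_B = c(36L, 9L, 8L, 6L, 1L, 0L),
    loc_L = c(52L, 29L, 10L, 4L, 1L, 0L),
    loc_R = c(47L, 11L, 6L, 4L, 0L, 0L),
    motor_B = c(23L, 15L, 9L, 8L, 1L, 0L),
    motor_L = c(37L, 10L, 5L, 4L, 0L, 0L),
    motor_R = c(46L, 20L, 9L, 2L, 1L, 1L)
  )
}

expand_sides <- function(n, b, l, r) {
  c(rep("B", b), rep("L", l), rep("R", r), rep("none", n - b - l - r))
}

#' Generate a synthetic clinical cohort
#'
#' Produces a per-subject feature table and clinical label table. Two modes:
#' \itemize{
#'  \item `counts`: a named vector of per-class sizes; features are
#'    class-conditional Gaussians with unit covariance whose means differ by
#'    `separation` along a random direction (first class at the origin).
#'  \item `preset = "table1"`: reproduces a reference 241-subject
#'    stroke-cohort composition (consciousness-state, sex, motor-side and
#'    stroke-side counts). Features are Gaussian with mean shifts along orthogonal
#'    directions for the DoC state and for each side label, so every
#'    clinical task is learnable from one feature table.
#' }
#'
#' @param counts named vector of class sizes (ignored with a preset).
#' @param preset `"none"` or `"table1"`.
#' @param n_features feature dimensionality (default 190, the vectorized
#'   20-channel connectivity matrix).
#' @param separation mean shift between classes in feature-space units.
#' @param seed RNG seed.
#' @return List with `features` (matrix, one row per subject) and `labels`
#'   (`data.frame`; columns `subject_id` and `class` in counts mode, the
#'   full clinical table in preset mode).
#' @export
gen_cohort <- function(counts = NULL, preset = c("none", "table1"),
                       n_features = 190L, separation = 2, seed = 1L) {
  preset <- match.arg(preset)
  rng <- local_rng(seed)
  on.exit(rng())
  if (preset == "table1") {
    comp <- table1_composition()
    labels <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
      n <- comp$female[i] + comp$male[i]
      if (n == 0L) return(NULL)
      data.frame(
        consciousness = rep(comp$consciousness[i], n),
        sex = c(rep("F", comp$female[i]), rep("M", comp$male[i])),
        stroke_side = expand_sides(n, comp$loc_B[i], comp$loc_L[i], comp$loc_R[i]),
        motor_side = expand_sides(n, comp$motor_B[i], comp$motor_L[i], comp$motor_R[i])
      )
    }))
    labels <- data.frame(subject_id = sprintf("sub%03d", seq_len(nrow(labels))),
                         labels)
    dirs <- qr.Q(qr(matrix(stats::rnorm(n_features * 5L), n_features, 5L)))
    side_shift <- function(side) (side == "L") - (side == "R")
    mu <- outer(as.numeric(doc_label(labels$consciousness) == "positive"),
                dirs[, 1]) +
      outer(side_shift(labels$motor_side), dirs[, 2]) +
      outer(as.numeric(labels$motor_side == "B"), dirs[, 3]) +
      outer(side_shift(labels$stroke_side), dirs[, 4]) +
      outer(as.numeric(labels$stroke_side == "B"), dirs[, 5])
    feats <- separation * mu +
      matrix(stats::rnorm(nrow(labels) * n_features), nrow(labels), n_features)
    rownames(feats) <- labels$subject_id
    colnames(feats) <- sprintf("f%03d", seq_len(n_features))
    return(list(features = feats, labels = validate_clinical_labels(labels)))
  }
  if (is.null(counts) || is.null(names(counts)) || length(counts) < 2L)
    stop("`counts` must be a named vector of >= 2 class sizes")
  if (any(counts < 1L)) stop("all class counts must be >= 1")
  dir <- stats::rnorm(n_features)
  dir <- dir / sqrt(sum(dir^2))
  classes <- rep(names(counts), counts)
  mu <- outer(match(classes, names(counts)) - 1, separation * dir)
  feats <- mu + matrix(stats::rnorm(length(classes) * n_features),
                       length(classes), n_features)
  ids <- sprintf("sub%03d", seq_along(classes))
  rownames(feats) <- ids
  colnames(feats) <- sprintf("f%03d", seq_len(n_features))
  list(features = feats,
       labels = data.frame(subject_id = ids, class = classes))
}
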