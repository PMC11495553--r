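test_that("cross-spectra are Hermitian, span 1-45 Hz, and collapse for identical channels", {
  fs <- 250
  set.seed(1)
  x <- rnorm(20 * fs)
  arr <- array(0, dim = c(2, 2 * fs, 10))
  for (k in 1:10) {
    seg <- x[((k - 1) * 2 * fs + 1):(k * 2 * fs)]
    arr[1, , k] <- seg
    arr[2, , k] <- seg
  }
  S <- compute_spectra(epochs_from_array(arr, fs))
  expect_equal(range(S$freqs), c(1, 45))
  sl <- S$obs[3, 7, , ]
  expect_lt(max(abs(sl - Conj(t(sl)))), 1e-12 * max(abs(sl)))
  # identical channels: S_12 = S_11 = S_22, real
  expect_equal(S$obs[, , 1, 2], S$obs[, , 1, 1], tolerance = 1e-12)
  expect_lt(max(abs(Im(S$obs[, , 1, 2]))), 1e-12 * max(abs(S$obs)))
  expect_error(compute_spectra(epochs_from_array(arr[, , 1, drop = FALSE], fs)),
               "at least 2 epochs")
})

test_that("independent white noise decorrelates in the averaged cross-spectrum", {
  fs <- 250
  set.seed(2)
  arr <- array(rnorm(2 * 2 * fs * 200), dim = c(2, 2 * fs, 200))
  S <- compute_spectra(epochs_from_array(arr, fs))
  f <- which(S$freqs == 10)
  ratio <- Mod(mean(S$obs[, f, 1, 2])) /
    sqrt(mean(Re(S$obs[, f, 1, 1])) * mean(Re(S$obs[, f, 2, 2])))
  expect_lt(ratio, 0.2)
})

test_that("noiseless lagged sinusoids give PLV = 1 and COH = 1 at the tone", {
  rec <- gen_oscillators(2, tone_freq = 10, coupling = list(list(1, 2, pi / 3, 1)),
                         noise_sd = 0, fs = 250, duration_s = 60, seed = 3)
  S <- compute_spectra(epoch(rec, 2, 0))
  f <- which(S$freqs == 10)
  expect_equal(phase_measure(S, "PLV")$values[f, 1, 2], 1, tolerance = 1e-6)
  expect_equal(phase_measure(S, "COH")$values[f, 1, 2], 1, tolerance = 1e-6)
})

test_that("a purely real cross-spectrum zeroes the lag-index family by convention", {
  set.seed(4)
  dphi <- rep(0, 50)                        # zero-lag: Im S_12 identically 0
  S <- phase_obs(dphi)
  expect_identical(phase_measure(S, "wPLI")$values[1, 1, 2], 0)
  expect_identical(phase_measure(S, "PLI")$values[1, 1, 2], 0)
  expect_identical(phase_measure(S, "wPLI_de")$values[1, 1, 2], 0)
  expect_equal(phase_measure(S, "PLV")$values[1, 1, 2], 1)
})

test_that("PLV and PPC are calibrated on von Mises phase differences", {
  set.seed(5)
  dphi <- rsbagging:::rvonmises(2000, 1)
  S <- phase_obs(dphi)
  plv <- phase_measure(S, "PLV")$values[1, 1, 2]
  ppc <- phase_measure(S, "PPC")$values[1, 1, 2]
  expect_lt(abs(plv - besselI(1, 1) / besselI(1, 0)), 0.03)  # I1(1)/I0(1)
  expect_lt(abs(ppc - plv^2), 0.03)
})

test_that("PPC is unbiased under uniform phases while PLV is positively biased", {
  set.seed(6)
  n <- 500; reps <- 200
  ppc <- plv <- numeric(reps)
  for (r in seq_len(reps)) {
    S <- phase_obs(runif(n, -pi, pi))
    ppc[r] <- phase_measure(S, "PPC")$values[1, 1, 2]
    plv[r] <- phase_measure(S, "PLV")$values[1, 1, 2]
  }
  expect_lt(abs(mean(ppc)), 2 * sd(ppc) / sqrt(reps))
  # PLV null bias ~ sqrt(pi / (4 n))
  expect_lt(abs(mean(plv) - sqrt(pi / (4 * n))), 0.005)
  expect_gt(mean(plv), 10 * sd(plv) / sqrt(reps))
})

test_that("bounded measures stay in range on random observation sets", {
  set.seed(8)
  for (r in 1:150) {
    n_obs <- sample(3:12, 1)
    X <- matrix(complex(real = rnorm(n_obs * 3), imaginary = rnorm(n_obs * 3)), n_obs, 3)
    obs <- array(complex(real = 0), dim = c(n_obs, 1, 3, 3))
    for (k in seq_len(n_obs)) obs[k, 1, , ] <- X[k, ] %o% Conj(X[k, ])
    S <- spectral_obs(obs, 10)
    for (m in c("COH", "PLV", "PLI", "wPLI")) {
      v <- phase_measure(S, m)$values
      expect_true(all(v >= -1e-12 & v <= 1 + 1e-12), info = m)
    }
    for (m in c("PPC", "wPPC", "wPLI_de")) {
      v <- phase_measure(S, m)$values
      expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12), info = m)
    }
  }
})

test_that("COH and PLV are scale-invariant; PLI family is invariant to joint sign flips", {
  set.seed(9)
  n_obs <- 40
  X <- matrix(complex(real = rnorm(n_obs * 2), imaginary = rnorm(n_obs * 2)), n_obs, 2)
  build <- function(X) {
    obs <- array(complex(real = 0), dim = c(n_obs, 1, 2, 2))
    for (k in seq_len(n_obs)) obs[k, 1, , ] <- X[k, ] %o% Conj(X[k, ])
    spectral_obs(obs, 10)
  }
  S <- build(X)
  S_scaled <- build(X %*% diag(c(3.7, 0.2)))   # channel-wise amplitude rescale
  S_flipped <- build(-X)                       # both channels sign-flipped
  for (m in c("COH", "PLV")) {
    expect_equal(phase_measure(S_scaled, m)$values,
                 phase_measure(S, m)$values, tolerance = 1e-10, info = m)
  }
  for (m in c("PLI", "wPLI")) {
    expect_equal(phase_measure(S_flipped, m)$values,
                 phase_measure(S, m)$values, tolerance = 1e-10, info = m)
  }
})

test_that("CSD tracks the averaged cross-spectrum and POWCORR tracks shared envelopes", {
  fs <- 250; len <- 2 * fs; n_ep <- 200
  t_ <- (0:(len - 1)) / fs
  set.seed(10)
  # shared amplitude envelope, independent phases
  arr <- array(0, dim = c(2, len, n_ep))
  for (k in seq_len(n_ep)) {
    A <- exp(rnorm(1, 0, 1))
    arr[1, , k] <- A * sin(2 * pi * 10 * t_ + runif(1, 0, 2 * pi)) + 0.05 * rnorm(len)
    arr[2, , k] <- A * sin(2 * pi * 10 * t_ + runif(1, 0, 2 * pi)) + 0.05 * rnorm(len)
  }
  S <- compute_spectra(epochs_from_array(arr, fs))
  f <- which(S$freqs == 10)
  expect_gt(amplitude_measure(S, "POWCORR")$values[f, 1, 2], 0.5)
  expect_equal(amplitude_measure(S, "CSD")$values[f, 1, 2],
               Mod(mean(S$obs[, f, 1, 2])))

  # independent white noise: near-zero orthogonalized power correlation
  arr0 <- array(rnorm(2 * len * 200), dim = c(2, len, 200))
  S0 <- compute_spectra(epochs_from_array(arr0, fs))
  expect_lt(abs(amplitude_measure(S0, "POWCORR")$values[f, 1, 2]), 0.2)

  # identical channels: the orthogonalized residual is pure noise
  arr1 <- arr0; arr1[2, , ] <- arr1[1, , ]
  S1 <- compute_spectra(epochs_from_array(arr1, fs))
  expect_warning(pc <- amplitude_measure(S1, "POWCORR")$values[f, 1, 2],
                 "zero-variance")
  expect_lt(abs(pc), 0.2)
})

test_that("band averaging vectorizes the upper triangle at the montage dimension", {
  freqs <- 1:45
  n <- 20
  set.seed(11)
  vals <- array(rnorm(45 * n * n), dim = c(45, n, n))
  for (f in 1:45) vals[f, , ] <- vals[f, , ] + t(vals[f, , ])
  stk <- rsbagging:::connectivity_stack(vals, freqs, "COH",
                                        montage_1020()$labels, FALSE)
  v <- band_average_and_vectorize(stk, c(1, 45))
  expect_length(v, 190L)
  expect_match(names(v)[1], "^COH_Fp1-Fp2$")

  # constant across frequency: the vector is that matrix's upper triangle
  m1 <- vals[1, , ]
  stk1 <- rsbagging:::connectivity_stack(array(rep(m1, each = 1), c(1, n, n)),
                                         10, "COH", montage_1020()$labels, FALSE)
  expected <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) expected <- c(expected, m1[i, j])
  expect_equal(unname(band_average_and_vectorize(stk1, c(5, 15))), expected,
               tolerance = 1e-12)

  # 4 channels -> choose(4,2) features
  stk4 <- rsbagging:::connectivity_stack(array(rnorm(45 * 16), c(45, 4, 4)),
                                         freqs, "PLV", letters[1:4], FALSE)
  expect_length(band_average_and_vectorize(stk4), 6L)
  expect_error(band_average_and_vectorize(stk4, c(100, 200)), "no grid")
})
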