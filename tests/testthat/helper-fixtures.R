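# shared fixture builders; all seeded and built in code at test time

epochs_from_array <- function(arr, fs) {
  structure(list(epochs = arr, fs = fs, epoch_length_s = dim(arr)[2] / fs,
                 overlap_fraction = 0,
                 channel_labels = paste0("ch", seq_len(dim(arr)[1])),
                 subject_id = "test"),
            class = "eeg_epochs")
}

avg_ref <- function(rec) {
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

# two-channel spectral observations with unit power and prescribed
# per-observation phase differences at a single frequency
phase_obs <- function(dphi, freq = 10) {
  n <- length(dphi)
  obs <- array(complex(real = 0), dim = c(n, 1, 2, 2))
  obs[, 1, 1, 1] <- 1 + 0i
  obs[, 1, 2, 2] <- 1 + 0i
  obs[, 1, 1, 2] <- exp(1i * dphi)
  obs[, 1, 2, 1] <- exp(-1i * dphi)
  spectral_obs(obs, freq)
}

# random stable MVAR model: coefficients shrunk until the companion
# spectral radius drops below 0.95
rand_stable_mvar <- function(n_ch, p = 2, fs = 100, seed = 1) {
  set.seed(seed)
  coeffs <- lapply(seq_len(p), function(k)
    matrix(rnorm(n_ch^2, 0, 0.4 / sqrt(p * n_ch)), n_ch, n_ch))
  repeat {
    ok <- tryCatch({
      m <- mvar_model(coeffs, diag(runif(n_ch, 0.5, 1.5)) + 0.1, fs)
      TRUE
    }, error = function(e) FALSE)
    if (ok && rsbagging:::mvar_spectral_radius(coeffs) < 0.95) break
    coeffs <- lapply(coeffs, function(a) a * 0.9)
  }
  mvar_model(coeffs, diag(runif(n_ch, 0.5, 1.5)) + 0.1, fs)
}

# independent dense-grid oracle for GC/DTF/PDC: direct matrix inversion,
# written against the published formulas, sharing no code with the package
directed_oracle <- function(model, freqs) {
  n <- nrow(model$coeffs[[1]])
  Sig <- model$noise_cov
  out <- list(GC = array(0, c(length(freqs), n, n)),
              DTF = array(0, c(length(freqs), n, n)),
              PDC = array(0, c(length(freqs), n, n)))
  for (fi in seq_along(freqs)) {
    A <- diag(n) + 0i
    for (k in seq_along(model$coeffs)) {
      A <- A - model$coeffs[[k]] * exp(-2i * pi * freqs[fi] * k / model$fs)
    }
    H <- solve(A)
    S <- H %*% Sig %*% Conj(t(H))
    h2 <- Mod(H)^2
    out$DTF[fi, , ] <- h2 / rowSums(h2)
    a2 <- Mod(A)^2
    out$PDC[fi, , ] <- sweep(a2, 2, colSums(a2), "/")
    for (x in seq_len(n)) for (y in seq_len(n)) if (x != y) {
      syy <- Re(S[y, y])
      out$GC[fi, x, y] <-
        log(syy / (syy - (Sig[x, x] - Sig[y, x]^2 / Sig[y, y]) * Mod(H[y, x])^2))
    }
  }
  out
}
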