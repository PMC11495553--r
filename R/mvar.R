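#' Multivariate autoregressive model
#'
#' Container for an MVAR(p) model `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t`
#' with noise covariance `Sigma`. The companion-matrix spectral radius must
#' be below 1 (stable model).
#'
#' @param coeffs list of p square coefficient matrices.
#' @param noise_cov symmetric positive-definite noise covariance.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional channel names.
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(coeffs, noise_cov, fs, channel_labels = NULL) {
  if (!is.list(coeffs) || length(coeffs) < 1L) stop("`coeffs` must list >= 1 matrix")
  coeffs <- lapply(coeffs, as.matrix)
  n <- nrow(coeffs[[1]])
  if (!all(vapply(coeffs, function(a) all(dim(a) == c(n, n)), logical(1))))
    stop("all coefficient matrices must be ", n, " x ", n)
  noise_cov <- as.matrix(noise_cov)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8 * max(1, max(abs(noise_cov))))
    stop("`noise_cov` must be symmetric")
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  rho <- mvar_spectral_radius(coeffs)
  if (rho >= 1)
    stop(sprintf("unstable MVAR model (spectral radius %.3f >= 1); lower the order", rho))
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  structure(list(order = length(coeffs), coeffs = coeffs, noise_cov = noise_cov,
                 fs = fs, channel_labels = channel_labels),
            class = "mvar_model")
}

mvar_spectral_radius <- function(coeffs) {
  n <- nrow(coeffs[[1]]); p <- length(coeffs)
  comp <- matrix(0, n * p, n * p)
  comp[seq_len(n), ] <- do.call(cbind, coeffs)
  if (p > 1L) comp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels, spectral radius %.3f\n",
              x$order, nrow(x$coeffs[[1]]), mvar_spectral_radius(x$coeffs)))
  invisible(x)
}

#' Fit an MVAR model across epochs
#'
#' Pooled least-squares fit: lagged regressors are built within each epoch
#' (no lag crosses an epoch boundary) and stacked. With `order = "auto"` the
#' order minimizing AIC over `1..max_order` is selected.
#'
#' @param ep an `eeg_epochs` object.
#' @param order integer model order, or `"auto"`.
#' @param max_order upper bound for automatic order selection (default 20).
#' @return An [mvar_model()].
#' @export
fit_mvar <- function(ep, order = "auto", max_order = 20L) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  n <- d[1]; len <- d[2]; n_ep <- d[3]
  total <- len * n_ep
  if (identical(order, "auto")) {
    orders <- seq_len(min(max_order, floor(total / (10 * n)), len - 1L))
    if (length(orders) == 0L) stop("too few samples to fit any MVAR order")
    aic <- vapply(orders, function(p) mvar_ls(ep, p)$aic, numeric(1))
    p <- orders[which.min(aic)]
  } else {
    p <- as.integer(order)
    if (p < 1L) stop("order must be >= 1")
    if (total <= 10 * p * n)
      stop("order ", p, " exceeds sample support (need > ", 10 * p * n, " samples)")
    if (p >= len) stop("order must be smaller than the epoch length")
  }
  fit <- mvar_ls(ep, p)
  mvar_model(fit$coeffs, fit$sigma, ep$fs, ep$channel_labels)
}

mvar_ls <- function(ep, p) {
  d <- dim(ep$epochs)
  n <- d[1]; len <- d[2]; n_ep <- d[3]
  rows_per <- len - p
  Y <- matrix(0, rows_per * n_ep, n)
  Z <- matrix(0, rows_per * n_ep, n * p)
  for (e in seq_len(n_ep)) {
    x <- t(ep$epochs[, , e])                # samples x channels
    r <- ((e - 1L) * rows_per + 1L):(e * rows_per)
    Y[r, ] <- x[(p + 1L):len, ]
    for (k in seq_len(p)) {
      Z[r, ((k - 1L) * n + 1L):(k * n)] <- x[(p + 1L - k):(len - k), ]
    }
  }
  B <- tryCatch(solve(crossprod(Z), crossprod(Z, Y)),
                error = function(e) stop("singular MVAR design matrix; lower the order"))
  resid <- Y - Z %*% B
  T_eff <- nrow(Y)
  sigma <- crossprod(resid) / T_eff
  coeffs <- lapply(seq_len(p), function(k) t(B[((k - 1L) * n + 1L):(k * n), , drop = FALSE]))
  ld <- determinant(sigma, logarithm = TRUE)
  aic <- T_eff * as.numeric(ld$modulus) + 2 * p * n^2
  list(coeffs = coeffs, sigma = sigma, aic = aic)
}

# A(f) = I - sum_k A_k exp(-2*pi*i*f*k/fs) and its inverse H(f)
mvar_transfer <- function(model, f) {
  n <- nrow(model$coeffs[[1]])
  A <- diag(n) + 0i
  for (k in seq_len(model$order)) {
    A <- A - model$coeffs[[k]] * exp(-2i * pi * f * k / model$fs)
  }
  H <- tryCatch(solve(A), error = function(e)
    stop(sprintf("singular spectral matrix A(f) at f = %g Hz", f)))
  list(A = A, H = H)
}

#' Frequency-domain directed connectivity from an MVAR model
#'
#' From the spectral coefficient matrix `A(f) = I - sum_k A_k e^{-2 pi i f k / fs}`
#' and transfer matrix `H(f) = A(f)^{-1}` with `S(f) = H Sigma H^*`:
#' \itemize{
#'  \item GC (entry x,y = influence of x on y):
#'    `ln( S_yy / (S_yy - (Sig_xx - Sig_yx^2 / Sig_yy) |H_yx|^2) )`
#'  \item DTF: `|H_ij|^2` normalized by its row sum (entries in \[0,1\],
#'    rows sum to 1)
#'  \item PDC: `|A_ij|^2` normalized by its column sum (columns sum to 1)
#' }
#' Orientation: the GC matrix is indexed (source, target); DTF and PDC keep
#' the indexing of their printed normalizations, where entry (i, j)
#' quantifies the influence of channel j on channel i.
#'
#' @param model an [mvar_model()].
#' @param measure `"GC"`, `"DTF"` or `"PDC"`.
#' @param freqs frequency grid in Hz.
#' @return A `connectivity_stack` with `directed = TRUE`.
#' @export
directed_measure <- function(model, measure = c("GC", "DTF", "PDC"),
                             freqs = seq(1, 45, by = 1)) {
  stopifnot(inherits(model, "mvar_model"))
  measure <- match.arg(measure)
  n <- nrow(model$coeffs[[1]])
  Sig <- model$noise_cov
  vals <- array(0, dim = c(length(freqs), n, n))
  for (fi in seq_along(freqs)) {
    tf <- mvar_transfer(model, freqs[fi])
    if (measure == "DTF") {
      h2 <- Mod(tf$H)^2
      vals[fi, , ] <- h2 / rowSums(h2)
    } else if (measure == "PDC") {
      a2 <- Mod(tf$A)^2
      vals[fi, , ] <- sweep(a2, 2L, colSums(a2), "/")
    } else {
      Sf <- tf$H %*% Sig %*% Conj(t(tf$H))
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          if (x == y) next
          syy <- Re(Sf[y, y])
          corr <- Sig[x, x] - Sig[y, x]^2 / Sig[y, y]
          vals[fi, x, y] <- log(syy / (syy - corr * Mod(tf$H[y, x])^2))
        }
      }
    }
  }
  connectivity_stack(vals, freqs, measure, model$channel_labels, directed = TRUE)
}
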