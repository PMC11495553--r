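#' Per-epoch cross-spectral observations
#'
#' Computes one cross-spectral matrix observation per epoch: each channel is
#' demeaned, Hann-tapered and Fourier transformed, and the outer product
#' `X(f) X(f)^H` is retained on a 1 Hz grid covering `[f_lo, f_hi]`. These
#' observations are the common substrate of every nonparametric connectivity
#' measure in the package; phase differences are realised as `arg S_12` per
#' observation.
#'
#' @param ep an `eeg_epochs` object (see [epoch()]).
#' @param f_lo,f_hi band limits in Hz (defaults 1 and 45).
#' @param taper `"hann"` or `"none"`.
#' @param step_hz spacing of the frequency grid (default 1 Hz).
#' @return An object of class `spectral_obs`: complex array `obs` of shape
#'   n_obs x n_freq x n_ch x n_ch (Hermitian in the channel slices), `freqs`,
#'   `channel_labels`, `taper`.
#' @export
compute_spectra <- function(ep, f_lo = 1, f_hi = 45, taper = c("hann", "none"),
                            step_hz = 1) {
  stopifnot(inherits(ep, "eeg_epochs"))
  taper <- match.arg(taper)
  d <- dim(ep$epochs)
  n_ch <- d[1]; len <- d[2]; n_obs <- d[3]
  if (n_obs < 2L) stop("need at least 2 epochs for spectral observations")
  T_s <- len / ep$fs
  if (f_lo < 1 / T_s - 1e-9)
    stop("f_lo below the epoch frequency resolution 1/", T_s, " Hz")
  if (f_hi >= ep$fs / 2) stop("f_hi must lie below the Nyquist frequency")
  freqs <- seq(f_lo, f_hi, by = step_hz)
  bins <- round(freqs * T_s) + 1L          # DFT bin indices (1-based)
  if (any(duplicated(bins)))
    stop("frequency grid finer than the epoch resolution 1/", T_s, " Hz")
  freqs <- (bins - 1L) / T_s               # snap to resolvable grid
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1))) else rep(1, len)
  scale <- 1 / (ep$fs * sum(w^2))
  obs <- array(complex(real = 0), dim = c(n_obs, length(freqs), n_ch, n_ch))
  for (k in seq_len(n_obs)) {
    x <- ep$epochs[, , k]
    x <- x - rowMeans(x)
    X <- stats::mvfft(t(x * rep(w, each = n_ch)))[bins, , drop = FALSE]  # freq x ch
    for (f in seq_along(bins)) {
      obs[k, f, , ] <- scale * (X[f, ] %o% Conj(X[f, ]))
    }
  }
  structure(list(obs = obs, freqs = freqs, channel_labels = ep$channel_labels,
                 taper = taper, fs = ep$fs),
            class = "spectral_obs")
}

#' Construct spectral observations directly
#'
#' Builds the `spectral_obs` container from a precomputed complex
#' observation tensor; useful for calibration studies that specify
#' per-observation cross-spectra analytically (e.g. unit-magnitude
#' cross-spectra with prescribed phase differences).
#'
#' @param obs complex array, n_obs x n_freq x n_ch x n_ch; every channel
#'   slice must be Hermitian with a real non-negative diagonal.
#' @param freqs strictly increasing frequency grid (Hz).
#' @param channel_labels optional channel names.
#' @return A `spectral_obs` object.
#' @export
spectral_obs <- function(obs, freqs, channel_labels = NULL) {
  d <- dim(obs)
  if (length(d) != 4L || d[3] != d[4]) stop("`obs` must be n_obs x n_freq x n_ch x n_ch")
  if (length(freqs) != d[2]) stop("`freqs` length must match dim 2 of `obs`")
  if (is.unsorted(freqs, strictly = TRUE)) stop("`freqs` must be strictly increasing")
  chk <- obs[1, 1, , ]
  if (max(abs(chk - Conj(t(chk)))) > 1e-8 * max(1, max(abs(chk))))
    stop("observation slices must be Hermitian")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[3]))
  structure(list(obs = obs, freqs = freqs, channel_labels = channel_labels,
                 taper = "external", fs = NA_real_),
            class = "spectral_obs")
}

#' @export
print.spectral_obs <- function(x, ...) {
  d <- dim(x$obs)
  cat(sprintf("<spectral_obs> %d observations, %d frequencies (%g-%g Hz), %d channels\n",
              d[1], d[2], min(x$freqs), max(x$freqs), d[3]))
  invisible(x)
}

connectivity_stack <- function(values, freqs, measure, labels, directed) {
  structure(list(values = values, freqs = freqs, measure = measure,
                 channel_labels = labels, directed = directed),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("<connectivity_stack> %s: %d x %d channels over %d frequencies (%s)\n",
              x$measure, dim(x$values)[2], dim(x$values)[3], dim(x$values)[1],
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

phase_measures <- function() c("COH", "PLV", "PLI", "wPLI", "wPLI_de", "PPC", "wPPC")
amplitude_measures <- function() c("CSD", "POWCORR")
directed_measures <- function() c("GC", "DTF", "PDC")

#' All connectivity measure names
#' @return Character vector of the eleven supported measures plus PLI.
#' @export
connectivity_measures <- function() {
  c(phase_measures(), amplitude_measures(), directed_measures())
}

div0 <- function(num, den) ifelse(abs(den) < .Machine$double.eps, 0, num / den)

#' Phase-synchronization measures from spectral observations
#'
#' Computes one of the phase-coupling measures per channel pair and
#' frequency. With `S_12^{(j)}` the per-observation cross-spectrum:
#' \itemize{
#'  \item COH: magnitude-squared coherence `|mean S_12|^2 / (mean S_11 mean S_22)`
#'  \item PLV: `|mean(S_12 / |S_12|)|`
#'  \item PLI: `|mean sign(Im S_12)|`
#'  \item wPLI: `|mean Im S_12| / mean |Im S_12|`
#'  \item wPLI_de: debiased squared wPLI (pairwise products over distinct
#'    observations)
#'  \item PPC: unbiased population analogue of squared PLV
#'  \item wPPC: PPC weighted by cross-spectral magnitude
#' }
#' Ratios with a zero denominator (e.g. a purely real cross-spectrum for
#' wPLI, or a zero-power channel for COH) are set to 0 by convention.
#'
#' @param S a `spectral_obs` object.
#' @param measure one of `"COH"`, `"PLV"`, `"PLI"`, `"wPLI"`, `"wPLI_de"`,
#'   `"PPC"`, `"wPPC"`.
#' @return A `connectivity_stack` (n_freq x n_ch x n_ch, symmetric slices).
#' @export
phase_measure <- function(S, measure = phase_measures()) {
  stopifnot(inherits(S, "spectral_obs"))
  measure <- match.arg(measure)
  d <- dim(S$obs)
  n_obs <- d[1]; n_f <- d[2]; n_ch <- d[3]
  if (n_obs < 2L) stop("need at least 2 observations")
  vals <- array(0, dim = c(n_f, n_ch, n_ch))
  for (f in seq_len(n_f)) {
    Sf <- S$obs[, f, , , drop = FALSE]
    dim(Sf) <- c(n_obs, n_ch, n_ch)
    for (i in seq_len(n_ch - 1L)) {
      for (j in (i + 1L):n_ch) {
        s12 <- Sf[, i, j]
        v <- switch(measure,
          COH = div0(Mod(mean(s12))^2, mean(Re(Sf[, i, i])) * mean(Re(Sf[, j, j]))),
          PLV = Mod(mean(div0c(s12, Mod(s12)))),
          PLI = abs(mean(sign(Im(s12)))),
          wPLI = div0(abs(mean(Im(s12))), mean(abs(Im(s12)))),
          wPLI_de = {
            im <- Im(s12)
            num <- sum(im)^2 - sum(im^2)
            den <- sum(abs(im))^2 - sum(im^2)
            div0(num, den)
          },
          PPC = {
            z <- div0c(s12, Mod(s12))
            (Mod(sum(z))^2 - n_obs) / (n_obs * (n_obs - 1))
          },
          wPPC = {
            m <- Mod(s12)
            div0(Mod(sum(s12))^2 - sum(m^2), sum(m)^2 - sum(m^2))
          })
        vals[f, i, j] <- v
        vals[f, j, i] <- v
      }
    }
  }
  connectivity_stack(vals, S$freqs, measure, S$channel_labels, directed = FALSE)
}

div0c <- function(num, den) {
  out <- num / den
  out[abs(den) < .Machine$double.eps] <- 0 + 0i
  out
}

#' Amplitude-based measures from spectral observations
#'
#' `CSD` is the magnitude of the observation-averaged cross-spectrum.
#' `POWCORR` is the orthogonalized log-power envelope correlation: for each
#' ordered pair, the component of one signal's Fourier coefficient orthogonal
#' to the other (`Y_perp_X = Im(Y conj(X) / |X|)`, so its power is
#' `Im(S_yx)^2 / S_xx`) is correlated on the log scale with the other
#' signal's log power across observations; the two directions are averaged.
#' Shared zero-lag signal cancels in the orthogonalized residual, making
#' POWCORR robust to volume conduction.
#'
#' @param S a `spectral_obs` object.
#' @param measure `"CSD"` or `"POWCORR"`.
#' @return A `connectivity_stack` (symmetric slices).
#' @export
amplitude_measure <- function(S, measure = amplitude_measures()) {
  stopifnot(inherits(S, "spectral_obs"))
  measure <- match.arg(measure)
  d <- dim(S$obs)
  n_obs <- d[1]; n_f <- d[2]; n_ch <- d[3]
  vals <- array(0, dim = c(n_f, n_ch, n_ch))
  eps <- .Machine$double.eps
  warned <- FALSE
  for (f in seq_len(n_f)) {
    Sf <- S$obs[, f, , , drop = FALSE]
    dim(Sf) <- c(n_obs, n_ch, n_ch)
    for (i in seq_len(n_ch - 1L)) {
      for (j in (i + 1L):n_ch) {
        if (measure == "CSD") {
          v <- Mod(mean(Sf[, i, j]))
        } else {
          pxx <- Re(Sf[, i, i]); pyy <- Re(Sf[, j, j])
          orth_ji <- Im(Sf[, j, i])^2 / pmax(pxx, eps)   # y orthogonal to x
          orth_ij <- Im(Sf[, i, j])^2 / pmax(pyy, eps)   # x orthogonal to y
          lp <- function(p) log(pmax(p, eps))
          ok <- function(a, b) stats::sd(a) > 0 && stats::sd(b) > 0
          r1 <- if (ok(lp(pxx), lp(orth_ji))) stats::cor(lp(pxx), lp(orth_ji)) else NA_real_
          r2 <- if (ok(lp(pyy), lp(orth_ij))) stats::cor(lp(pyy), lp(orth_ij)) else NA_real_
          if ((is.na(r1) || is.na(r2)) && !warned) {
            warning("zero-variance power envelope; POWCORR entry set to 0")
            warned <- TRUE
          }
          v <- mean(c(r1, r2), na.rm = TRUE)
          if (is.nan(v)) v <- 0
        }
        vals[f, i, j] <- v
        vals[f, j, i] <- v
      }
    }
  }
  connectivity_stack(vals, S$freqs, measure, S$channel_labels, directed = FALSE)
}

#' Band-average a connectivity stack and vectorize the upper triangle
#'
#' Averages the per-frequency matrices arithmetically over the requested
#' band and unfolds the upper triangle (`i < j` in montage order) into the
#' feature vector consumed by classifiers; 20 channels give the canonical
#' 190-element vector. For directed measures the upper triangle is the
#' default reduction; set `directed_full = TRUE` to keep all ordered pairs.
#'
#' @param stack a `connectivity_stack`.
#' @param band numeric length-2 band limits in Hz (default `c(1, 45)`).
#' @param directed_full emit all `n(n-1)` ordered pairs for directed
#'   measures instead of the upper triangle.
#' @return Named numeric vector; names are `<measure>_<chanA>-<chanB>`.
#' @export
band_average_and_vectorize <- function(stack, band = c(1, 45),
                                       directed_full = FALSE) {
  stopifnot(inherits(stack, "connectivity_stack"))
  sel <- which(stack$freqs >= band[1] - 1e-9 & stack$freqs <= band[2] + 1e-9)
  if (length(sel) == 0L) stop("band [", band[1], ", ", band[2],
                              "] contains no grid frequencies")
  m <- apply(stack$values[sel, , , drop = FALSE], c(2, 3), mean)
  labs <- stack$channel_labels
  n <- length(labs)
  if (stack$directed && directed_full) {
    idx <- which(row(m) != col(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }
  out <- m[idx]
  names(out) <- paste0(stack$measure, "_", labs[idx[, 1]], "-", labs[idx[, 2]])
  out
}

#' Connectivity feature vector(s) for one subject
#'
#' End-to-end extraction of band-averaged connectivity features from an
#' epoched recording. Nonparametric measures share one set of Hann-tapered
#' spectral observations; GC is computed from bivariate MVAR models per
#' channel pair, DTF and PDC from one full multivariate model.
#'
#' @param ep an `eeg_epochs` object.
#' @param measures subset of [connectivity_measures()].
#' @param band band limits in Hz for averaging.
#' @param mvar_order MVAR order or `"auto"` (AIC, see [fit_mvar()]).
#' @param directed_full see [band_average_and_vectorize()].
#' @return Named numeric vector concatenating the per-measure features.
#' @export
connectivity_features <- function(ep, measures = connectivity_measures(),
                                  band = c(1, 45), mvar_order = 5,
                                  directed_full = FALSE) {
  measures <- match.arg(measures, connectivity_measures(), several.ok = TRUE)
  out <- numeric(0)
  nonpar <- intersect(measures, c(phase_measures(), amplitude_measures()))
  if (length(nonpar)) {
    S <- compute_spectra(ep, f_lo = max(band[1], 1 / ep$epoch_length_s),
                         f_hi = band[2])
    for (ms in nonpar) {
      stk <- if (ms %in% phase_measures()) phase_measure(S, ms)
             else amplitude_measure(S, ms)
      out <- c(out, band_average_and_vectorize(stk, band, directed_full))
    }
  }
  dir <- intersect(measures, directed_measures())
  if (length(dir)) {
    freqs <- seq(max(1, band[1]), band[2], by = 1)
    if ("GC" %in% dir) {
      out <- c(out, gc_pairwise_features(ep, freqs, band, mvar_order, directed_full))
    }
    other <- setdiff(dir, "GC")
    if (length(other)) {
      mod <- fit_mvar(ep, order = mvar_order)
      for (ms in other) {
        stk <- directed_measure(mod, ms, freqs)
        out <- c(out, band_average_and_vectorize(stk, band, directed_full))
      }
    }
  }
  out
}

# Bivariate spectral GC per ordered channel pair, band-averaged, then
# reduced like any directed stack.
gc_pairwise_features <- function(ep, freqs, band, mvar_order, directed_full) {
  labs <- ep$channel_labels
  n <- length(labs)
  gm <- array(0, dim = c(length(freqs), n, n))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sub <- ep
      sub$epochs <- ep$epochs[c(i, j), , , drop = FALSE]
      sub$channel_labels <- labs[c(i, j)]
      mod <- fit_mvar(sub, order = mvar_order)
      stk <- directed_measure(mod, "GC", freqs)
      gm[, i, j] <- stk$values[, 1, 2]
      gm[, j, i] <- stk$values[, 2, 1]
    }
  }
  stack <- connectivity_stack(gm, freqs, "GC", labs, directed = TRUE)
  band_average_and_vectorize(stack, band, directed_full)
}
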