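#' Global field power
#'
#' GFP at sample t is the root mean square of the average-referenced channel
#' values: the spatial standard deviation of the scalp map. Input that is not
#' average-referenced is re-referenced with a warning.
#'
#' @param rec a [recording()].
#' @return Object of class `gfp_series`: numeric `values` (one per sample,
#'   microvolts) and `fs`.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  mu <- colMeans(x)
  scale <- max(abs(x), 1e-12)
  if (max(abs(mu)) > 1e-9 * scale) {
    warning("input is not average-referenced; re-referencing for GFP")
    x <- sweep(x, 2L, mu)
  }
  structure(list(values = sqrt(colMeans(x^2)), fs = rec$fs), class = "gfp_series")
}

#' Local maxima of a GFP series
#'
#' Returns sample indices where GFP is strictly greater than both
#' neighbours. Scalp maps at these peaks are the standard clustering input
#' for microstate segmentation (topographies are most stable at GFP peaks).
#'
#' @param gfp a `gfp_series` from [compute_gfp()].
#' @return Integer vector of peak sample indices.
#' @export
gfp_peaks <- function(gfp) {
  v <- gfp$values
  n <- length(v)
  if (n < 3L) stop("GFP series too short for peak detection")
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
}

norm_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), .Machine$double.eps)

#' Polarity-invariant modified k-means clustering of scalp maps
#'
#' Clusters maps (rows) into `k` topographic prototypes ignoring polarity:
#' assignment maximizes the squared spatial projection onto a prototype, and
#' each prototype update is the first principal eigenvector of the scatter
#' matrix of its assigned maps, so a map and its sign flip are treated
#' identically. Iterations stop when the relative change in global explained
#' variance (GEV) falls below `tol`; the best of `restarts` seeded
#' initializations is returned. An emptied cluster is re-seeded from the
#' currently worst-explained map.
#'
#' @param maps numeric matrix, one average-referenced map per row.
#' @param k number of prototypes, `2 <= k <= nrow(maps)` (k = 1 permitted
#'   for degenerate single-template checks).
#' @param restarts number of random initializations (>= 1, default 20).
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param tol relative GEV convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @return Object of class `microstate_prototypes`: `k`, `maps` (k x n_ch,
#'   unit-norm rows), `training_gev`.
#' @export
modified_kmeans <- function(maps, k, restarts = 20L, seed = 1L, tol = 1e-6,
                            max_iter = 200L) {
  maps <- as.matrix(maps)
  if (k < 1L || k > nrow(maps)) stop("`k` must be between 1 and the number of maps")
  if (restarts < 1L) stop("`restarts` must be >= 1")
  denom <- sum(maps^2)
  if (denom <= 0) stop("all maps are zero")
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    protos <- norm_rows(maps[sample.int(nrow(maps), k), , drop = FALSE])
    gev <- -Inf
    for (it in seq_len(max_iter)) {
      proj <- maps %*% t(protos)                 # n_maps x k
      assign_ <- max.col(proj^2, ties.method = "first")
      for (c in seq_len(k)) {
        idx <- which(assign_ == c)
        if (length(idx) == 0L) {
          expl <- proj[cbind(seq_len(nrow(maps)), assign_)]^2 / rowSums(maps^2)
          idx <- which.min(expl)
          assign_[idx] <- c
        }
        sc <- crossprod(maps[idx, , drop = FALSE])
        protos[c, ] <- eigen(sc, symmetric = TRUE)$vectors[, 1]
      }
      proj <- maps %*% t(protos)
      gev_new <- sum(proj[cbind(seq_len(nrow(maps)), max.col(proj^2, ties.method = "first"))]^2) / denom
      if (is.finite(gev) && abs(gev_new - gev) < tol * max(gev, .Machine$double.eps)) {
        gev <- gev_new
        break
      }
      gev <- gev_new
    }
    if (is.null(best) || gev > best$training_gev) {
      best <- list(k = as.integer(k), maps = norm_rows(protos), training_gev = gev)
    }
  }
  structure(best, class = "microstate_prototypes")
}

#' @export
print.microstate_prototypes <- function(x, ...) {
  cat(sprintf("<microstate_prototypes> k = %d, training GEV = %.3f\n",
              x$k, x$training_gev))
  invisible(x)
}

#' Assign each EEG sample to a microstate prototype
#'
#' Each sample map is labelled with the prototype of maximal absolute
#' spatial correlation (polarity ignored). Samples with zero GFP inherit the
#' neighbouring label. Optionally, runs shorter than `min_duration_ms` are
#' merged into the preceding run (temporal smoothing; default off).
#'
#' @param rec a [recording()] (average-referenced; re-referenced if not).
#' @param protos a `microstate_prototypes`.
#' @param min_duration_ms minimum accepted run length in ms (0 = no
#'   smoothing).
#' @return Object of class `microstate_segmentation`: integer `labels`
#'   (1..k, one per sample), `k`, `fs`.
#' @export
backfit <- function(rec, protos, min_duration_ms = 0) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(protos, "microstate_prototypes"))
  if (ncol(protos$maps) != n_channels(rec))
    stop("prototype channel count does not match the recording")
  x <- sweep(rec$data, 2L, colMeans(rec$data))
  act <- protos$maps %*% x                      # k x samples
  labels <- max.col(t(act^2), ties.method = "first")
  zero <- colSums(x^2) < .Machine$double.eps
  if (any(zero)) {
    labels[zero] <- NA_integer_
    labels <- fill_na_forward(labels)
  }
  if (min_duration_ms > 0) {
    labels <- smooth_min_duration(labels, round(min_duration_ms * rec$fs / 1000))
  }
  structure(list(labels = labels, k = protos$k, fs = rec$fs),
            class = "microstate_segmentation")
}

fill_na_forward <- function(v) {
  if (all(is.na(v))) stop("all samples have zero field power")
  idx <- which(!is.na(v))
  filled <- v[idx][findInterval(seq_along(v), idx)]
  filled[seq_along(v) < idx[1]] <- v[idx[1]]    # leading NAs take first label
  filled
}

smooth_min_duration <- function(labels, min_len) {
  if (min_len <= 1L) return(labels)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) return(labels)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(labels)
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    labels <- inverse.rle(r)
  }
}

#' Microstate statistical parameters
#'
#' Per-state summary of a segmentation: mean GFP over the state's samples
#' (microvolts), mean run duration (ms), occurrence (runs per second),
#' coverage (fraction of samples) and GEV, the fraction of GFP-weighted
#' topographic variance explained:
#' `gev_k = sum_{t in k} (GFP_t corr(v_t, map_k))^2 / sum_t GFP_t^2`.
#' A state that never occurs yields zeros with a warning.
#'
#' @param seg a `microstate_segmentation`.
#' @param rec the [recording()] the segmentation labels.
#' @param protos the `microstate_prototypes` used.
#' @return `data.frame` with one row per state: `state`, `mean_gfp`,
#'   `duration_ms`, `occurrence`, `coverage`, `gev`.
#' @export
microstate_parameters <- function(seg, rec, protos) {
  stopifnot(inherits(seg, "microstate_segmentation"),
            inherits(rec, "eeg_recording"),
            inherits(protos, "microstate_prototypes"))
  if (length(seg$labels) != n_samples(rec))
    stop("segmentation length does not match the recording")
  x <- sweep(rec$data, 2L, colMeans(rec$data))
  n_ch <- nrow(x)
  gfp <- sqrt(colMeans(x^2))
  total_gfp2 <- sum(gfp^2)
  act <- protos$maps %*% x                      # k x samples
  r <- rle(seg$labels)
  total_s <- length(seg$labels) / seg$fs
  out <- data.frame(state = seq_len(seg$k), mean_gfp = 0, duration_ms = 0,
                    occurrence = 0, coverage = 0, gev = 0)
  for (k in seq_len(seg$k)) {
    runs <- r$lengths[r$values == k]
    sel <- seg$labels == k
    if (length(runs) == 0L) {
      warning("state ", k, " never occurs; parameters set to 0")
      next
    }
    out$mean_gfp[k] <- mean(gfp[sel])
    out$duration_ms[k] <- mean(runs) * 1000 / seg$fs
    out$occurrence[k] <- length(runs) / total_s
    out$coverage[k] <- sum(sel) / length(seg$labels)
    out$gev[k] <- sum(act[k, sel]^2 / n_ch) / total_gfp2
  }
  out
}

#' Microstate feature vector for one subject
#'
#' Full chain: GFP, maps at GFP peaks, polarity-invariant k-means,
#' backfitting, parameter extraction; the five parameters (mean GFP,
#' duration, occurrence, coverage, GEV) of the k states are concatenated in
#' order of descending coverage, yielding a length-`5k` vector comparable
#' across subjects.
#'
#' @param rec a [recording()], ideally preprocessed.
#' @param k number of microstate classes, 2..30.
#' @param protos optional pre-fitted group-level `microstate_prototypes`
#'   (fit on training subjects only to avoid test-set leakage); when given,
#'   clustering is skipped and `k`/`restarts`/`seed` are ignored.
#' @param restarts,seed,tol clustering controls, see [modified_kmeans()].
#' @param min_duration_ms smoothing passed to [backfit()].
#' @return Named numeric vector of length `5 k`
#'   (`ms<rank>_<parameter>` names).
#' @export
microstate_features <- function(rec, k = 4L, protos = NULL, restarts = 20L,
                                seed = 1L, tol = 1e-6, min_duration_ms = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(protos)) {
    if (k < 2L || k > 30L) stop("`k` must be in 2..30")
    gfp <- compute_gfp(rec)
    peaks <- gfp_peaks(gfp)
    if (length(peaks) < k) stop("fewer GFP peaks than clusters")
    x <- sweep(rec$data, 2L, colMeans(rec$data))
    protos <- modified_kmeans(t(x[, peaks, drop = FALSE]), k = k,
                              restarts = restarts, seed = seed, tol = tol)
  }
  seg <- backfit(rec, protos, min_duration_ms = min_duration_ms)
  par <- microstate_parameters(seg, rec, protos)
  par <- par[order(-par$coverage, par$state), ]
  vals <- as.matrix(par[, c("mean_gfp", "duration_ms", "occurrence", "coverage", "gev")])
  out <- as.numeric(t(vals))
  names(out) <- as.vector(t(outer(seq_len(nrow(par)),
                                  c("mean_gfp", "duration_ms", "occurrence",
                                    "coverage", "gev"),
                                  function(i, p) paste0("ms", i, "_", p))))
  out
}
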