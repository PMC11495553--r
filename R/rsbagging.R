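#' Binary dataset for imbalanced classification
#'
#' Wraps a feature matrix and binary labels. The positive class is the
#' minority class (clinical convention here: the condition of interest is
#' rare), unless overridden.
#'
#' @param X numeric matrix or data.frame, samples in rows.
#' @param y binary labels (factor, character or 0/1).
#' @param positive label value to treat as positive; default the minority.
#' @return Object of class `rsb_dataset` with `X`, `y` (factor, levels
#'   negative first) and `positive`.
#' @export
rsb_dataset <- function(X, y, positive = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric")
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  tab <- table(y)
  if (length(tab) != 2L) stop("exactly two classes required, got ", length(tab))
  if (is.null(positive)) positive <- names(tab)[which.min(tab)]
  if (!positive %in% names(tab)) stop("positive label not present in y")
  negative <- setdiff(names(tab), positive)
  structure(list(X = X, y = factor(y, levels = c(negative, positive)),
                 positive = positive),
            class = "rsb_dataset")
}

#' @export
print.rsb_dataset <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("<rsb_dataset> %d samples x %d features; %s: %d (positive), %s: %d\n",
              nrow(x$X), ncol(x$X), x$positive, tab[[x$positive]],
              setdiff(levels(x$y), x$positive), tab[[setdiff(levels(x$y), x$positive)]]))
  invisible(x)
}

#' RSBagging configuration
#'
#' @param N number of base SVM models (default 11; odd so that a hard vote
#'   cannot tie).
#' @param alpha soft-vote abstention threshold in \[0.5, 1\]: a test sample
#'   is labelled only if the mean positive probability or its complement
#'   reaches `alpha`; otherwise it abstains.
#' @param svm_C SVM cost parameter.
#' @param svm_gamma Gaussian-kernel width, or `"auto"` for
#'   `1 / (n_features * var(X))` on the z-scored training features.
#' @param seed RNG seed governing splits and undersampling.
#' @param test_fraction held-out fraction for [stratified_split()].
#' @param repeats number of split/train/evaluate repetitions in [run_task()].
#' @param replace_within sample majority indices with replacement inside a
#'   subset (default `FALSE`: each subset is a plain subset of the majority
#'   class; diversity comes from resampling across subsets).
#' @return Object of class `rsb_config`.
#' @export
rsb_config <- function(N = 11L, alpha = 0.5, svm_C = 1, svm_gamma = "auto",
                       seed = 1L, test_fraction = 0.3, repeats = 20L,
                       replace_within = FALSE) {
  if (N < 1L) stop("`N` must be >= 1")
  if (!(alpha >= 0.5 && alpha <= 1)) stop("`alpha` must be in [0.5, 1]")
  if (svm_C <= 0) stop("`svm_C` must be > 0")
  if (!(test_fraction > 0 && test_fraction < 1)) stop("`test_fraction` in (0,1)")
  if (repeats < 1L) stop("`repeats` must be >= 1")
  structure(list(N = as.integer(N), alpha = alpha, svm_C = svm_C,
                 svm_gamma = svm_gamma, seed = as.integer(seed),
                 test_fraction = test_fraction, repeats = as.integer(repeats),
                 replace_within = isTRUE(replace_within)),
            class = "rsb_config")
}

#' Stratified train/test split
#'
#' Splits so that each class contributes `round(n_class * test_fraction)`
#' samples to the test set (clamped to leave at least one sample per class
#' on each side), preserving the class imbalance of the original cohort in
#' the test set.
#'
#' @param D an [rsb_dataset()].
#' @param test_fraction fraction in (0,1).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return List with `train` and `test` datasets (disjoint, exhaustive) and
#'   `test_indices`.
#' @export
stratified_split <- function(D, test_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(D, "rsb_dataset"))
  tab <- table(D$y)
  if (any(tab < 2L)) stop("every class needs >= 2 samples to split")
  rng <- local_rng(seed)
  test_idx <- integer(0)
  for (cl in levels(D$y)) {
    idx <- which(D$y == cl)
    n_test <- min(max(round(length(idx) * test_fraction), 1L), length(idx) - 1L)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  rng()
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(D$y), test_idx)
  list(train = rsb_dataset(D$X[train_idx, , drop = FALSE], D$y[train_idx], D$positive),
       test = rsb_dataset(D$X[test_idx, , drop = FALSE], D$y[test_idx], D$positive),
       test_indices = test_idx)
}

# run code under a temporary seed, restoring the caller's RNG state;
# returns the restore function (call it when done)
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Balanced random-undersampled training subsets
#'
#' Builds `N` balanced subsets: each keeps the full minority class and pairs
#' it with an equally sized random sample of the majority class, drawn
#' without replacement within a subset (so each majority part is a genuine
#' subset of the majority class) and independently across subsets.
#'
#' @param train an [rsb_dataset()].
#' @param N number of subsets.
#' @param seed RNG seed.
#' @param replace_within draw majority indices with replacement (default
#'   `FALSE`).
#' @return List of `N` lists with `indices` (row indices into `train$X`) and
#'   `majority_indices`.
#' @export
make_balanced_subsets <- function(train, N, seed = 1L, replace_within = FALSE) {
  stopifnot(inherits(train, "rsb_dataset"))
  min_idx <- which(train$y == train$positive)
  maj_idx <- which(train$y != train$positive)
  if (length(min_idx) < 2L) stop("minority class needs >= 2 samples")
  if (length(min_idx) > length(maj_idx))
    stop("minority class larger than majority; invert labels upstream")
  rng <- local_rng(seed)
  on.exit(rng())
  lapply(seq_len(N), function(n) {
    maj <- sample(maj_idx, length(min_idx), replace = replace_within)
    list(indices = c(min_idx, maj), majority_indices = maj)
  })
}

# Platt-style sigmoid calibration of SVM decision values: minimizes the
# cross-entropy of p = 1/(1+exp(a*d+b)) against Platt's smoothed targets.
platt_fit <- function(dec, y_pos) {
  np <- sum(y_pos); nn <- sum(!y_pos)
  t <- ifelse(y_pos, (np + 1) / (np + 2), 1 / (nn + 2))
  log1pexp <- function(f) ifelse(f > 30, f, log1p(exp(pmin(f, 30))))
  obj <- function(par) sum(log1pexp(par[1] * dec + par[2]) - (1 - t) * (par[1] * dec + par[2]))
  grad <- function(par) {
    f <- par[1] * dec + par[2]
    s <- 1 / (1 + exp(-pmin(pmax(f, -30), 30)))      # = 1 - p
    g <- s - (1 - t)
    c(sum(g * dec), sum(g))
  }
  init_a <- if (mean(dec[y_pos]) >= mean(dec[!y_pos])) -1 else 1
  fit <- stats::optim(c(init_a, 0), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(a = fit$par[1], b = fit$par[2])
}

platt_prob <- function(cal, dec) 1 / (1 + exp(pmin(pmax(cal$a * dec + cal$b, -30), 30)))

#' Train an RSBagging ensemble
#'
#' Fits one Gaussian-kernel SVM per balanced subset (features z-scored with
#' training-set statistics only) and calibrates each model's decision values
#' to positive-class probabilities with a Platt-style sigmoid fitted on its
#' own subset. Fully deterministic given `cfg$seed`.
#'
#' @param train an [rsb_dataset()].
#' @param cfg an [rsb_config()].
#' @return Object of class `rsbagging_ensemble`.
#' @export
train_ensemble <- function(train, cfg = rsb_config()) {
  stopifnot(inherits(train, "rsb_dataset"), inherits(cfg, "rsb_config"))
  center <- colMeans(train$X)
  scale_ <- apply(train$X, 2L, stats::sd)
  scale_[scale_ < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(train$X, 2L, center), 2L, scale_, "/")
  gamma <- if (identical(cfg$svm_gamma, "auto")) {
    1 / (ncol(Xs) * max(mean(apply(Xs, 2L, stats::var)), .Machine$double.eps))
  } else cfg$svm_gamma
  subsets <- make_balanced_subsets(train, cfg$N, seed = cfg$seed,
                                   replace_within = cfg$replace_within)
  models <- lapply(subsets, function(s) {
    ys <- droplevels(train$y[s$indices])
    if (nlevels(ys) < 2L) stop("degenerate subset with a single class")
    xsub <- Xs[s$indices, , drop = FALSE]
    m <- e1071::svm(x = xsub, y = ys, kernel = "radial",
                    cost = cfg$svm_C, gamma = gamma, scale = FALSE)
    dec <- attr(stats::predict(m, xsub, decision.values = TRUE),
                "decision.values")[, 1]
    list(svm = m, platt = platt_fit(dec, ys == train$positive))
  })
  structure(list(base_models = models, config = cfg,
                 subset_indices = lapply(subsets, `[[`, "indices"),
                 center = center, scale = scale_, gamma = gamma,
                 positive = train$positive, levels = levels(train$y)),
            class = "rsbagging_ensemble")
}

#' @export
print.rsbagging_ensemble <- function(x, ...) {
  cat(sprintf("<rsbagging_ensemble> N = %d base SVMs (gamma = %.4g), alpha = %g, positive = %s\n",
              length(x$base_models), x$gamma, x$config$alpha, x$positive))
  invisible(x)
}

#' Abstaining soft-vote prediction
#'
#' Averages the calibrated positive-class probabilities of the base models;
#' a sample is labelled positive if the mean probability `p` reaches
#' `alpha`, negative if `1 - p` reaches `alpha`, and abstains otherwise.
#' At `alpha = 0.5`, a tie `p = 0.5` goes to the positive (minority) class,
#' so no binary sample ever abstains.
#'
#' @param object a trained `rsbagging_ensemble`.
#' @param X feature matrix (raw scale; the ensemble applies its stored
#'   z-scoring).
#' @param alpha optional threshold overriding the training configuration.
#' @param ... unused.
#' @return Object of class `rsb_prediction`: `p_positive` (mean calibrated
#'   probability) and `decision` (`"positive"`, `"negative"` or
#'   `"ABSTAIN"`).
#' @export
predict.rsbagging_ensemble <- function(object, X, alpha = NULL, ...) {
  if (length(object$base_models) == 0L) stop("empty ensemble")
  X <- as.matrix(X)
  if (ncol(X) != length(object$center)) stop("feature dimension mismatch")
  if (is.null(alpha)) alpha <- object$config$alpha
  if (!(alpha >= 0.5 && alpha <= 1)) stop("`alpha` must be in [0.5, 1]")
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  probs <- vapply(object$base_models, function(m) {
    dec <- attr(stats::predict(m$svm, Xs, decision.values = TRUE),
                "decision.values")[, 1]
    platt_prob(m$platt, dec)
  }, numeric(nrow(Xs)))
  p <- if (is.matrix(probs)) rowMeans(probs) else mean(probs)
  decision <- ifelse(p >= alpha, "positive",
                     ifelse(1 - p >= alpha, "negative", "ABSTAIN"))
  structure(list(p_positive = p, decision = decision, alpha = alpha,
                 positive = object$positive, levels = object$levels),
            class = "rsb_prediction")
}

#' Classify a soft-vote probability at a threshold
#'
#' Threshold rule shared by [predict.rsbagging_ensemble()] and alpha
#' sweeps: positive if `p >= alpha`, negative if `1 - p >= alpha`, abstain
#' otherwise.
#' @param p_positive mean positive-class probabilities.
#' @param alpha threshold in \[0.5, 1\].
#' @return Character vector in `positive` / `negative` / `ABSTAIN`.
#' @export
decide_at_alpha <- function(p_positive, alpha) {
  if (!(alpha >= 0.5 && alpha <= 1)) stop("`alpha` must be in [0.5, 1]")
  ifelse(p_positive >= alpha, "positive",
         ifelse(1 - p_positive >= alpha, "negative", "ABSTAIN"))
}

#' Confusion counts and the five evaluation metrics
#'
#' Abstained samples are excluded from the confusion counts but retained in
#' the Predict Rate denominator. With TP/TN/FP/FN over predicted samples:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN), and
#' Predict Rate = (TP+FP+TN+FN)/(N+ + N-), all expressed as percentages.
#'
#' @param pred an `rsb_prediction`, or a character vector of decisions in
#'   `positive`/`negative`/`ABSTAIN`.
#' @param y_true true labels; either `positive`/`negative` strings, a
#'   factor whose positive level matches the prediction's, or a logical
#'   vector (TRUE = positive).
#' @return Object of class `rsb_report`: counts `TP`, `TN`, `FP`, `FN`,
#'   metrics `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `predict_rate` (percent), `n_test`, and `all_abstained`.
#' @export
evaluate <- function(pred, y_true) {
  decision <- if (inherits(pred, "rsb_prediction")) pred$decision else as.character(pred)
  pos <- if (inherits(pred, "rsb_prediction")) pred$positive else "positive"
  truth <- if (is.logical(y_true)) ifelse(y_true, "positive", "negative")
           else ifelse(as.character(y_true) == pos | as.character(y_true) == "positive",
                       "positive", "negative")
  if (length(decision) != length(truth)) stop("prediction and label lengths differ")
  kept <- decision != "ABSTAIN"
  TP <- sum(kept & decision == "positive" & truth == "positive")
  TN <- sum(kept & decision == "negative" & truth == "negative")
  FP <- sum(kept & decision == "positive" & truth == "negative")
  FN <- sum(kept & decision == "negative" & truth == "positive")
  n <- length(truth)
  all_abst <- !any(kept)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN, n_test = n,
    accuracy = pct(TP + TN, TP + TN + FP + FN),
    sensitivity = pct(TP, TP + FN),
    specificity = pct(TN, TN + FP),
    f1 = pct(2 * TP, 2 * TP + FP + FN),
    predict_rate = 100 * (TP + FP + TN + FN) / n,
    all_abstained = all_abst
  ), class = "rsb_report")
}

#' @export
print.rsb_report <- function(x, ...) {
  if (x$all_abstained) {
    cat("<rsb_report> all samples abstained; metrics undefined\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<rsb_report> TP=%d TN=%d FP=%d FN=%d | accuracy %.2f%% ",
                     "sensitivity %.2f%% specificity %.2f%% F1 %.2f%% predict rate %.2f%%\n"),
              x$TP, x$TN, x$FP, x$FN, x$accuracy, x$sensitivity,
              x$specificity, x$f1, x$predict_rate))
  invisible(x)
}

task_names <- function() {
  c("doc", "motor_LR", "motor_single_bilateral", "location_LR",
    "location_single_bilateral")
}

# build the binary dataset for one clinical task; non-DoC tasks first drop
# DoC-positive subjects (consciousness affects the EEG)
task_dataset <- function(X, labels, task) {
  task <- match.arg(task, task_names())
  labels <- validate_clinical_labels(labels)
  if (nrow(X) != nrow(labels)) stop("feature and label tables differ in rows")
  if (task == "doc") {
    y <- as.character(doc_label(labels$consciousness))
    return(rsb_dataset(X, y, positive = "positive"))
  }
  keep <- labels$consciousness == "awake"
  side <- if (startsWith(task, "motor")) labels$motor_side else labels$stroke_side
  if (endsWith(task, "_LR")) {
    sel <- keep & side %in% c("L", "R")
    y <- side[sel]
  } else {
    sel <- keep & side %in% c("B", "L", "R")
    y <- ifelse(side[sel] == "B", "bilateral", "single")
  }
  if (length(unique(y)) < 2L) stop("task ", task, " has a class with no subjects")
  rsb_dataset(X[sel, , drop = FALSE], y)
}

#' Run a clinical classification task end to end
#'
#' Repeats the full protocol: stratified split, balanced undersampled
#' subsets, ensemble training, abstaining soft-vote prediction and
#' evaluation. Non-DoC tasks first exclude DoC-positive subjects. Repeat r
#' uses seed `cfg$seed + r - 1` for the split and the subsets.
#'
#' @param features numeric matrix or data.frame of per-subject features
#'   (rows align with `labels`); a `subject_id` column is used for
#'   alignment checking if present.
#' @param labels clinical label table (see [read_clinical_labels()]).
#' @param task one of `"doc"`, `"motor_LR"`, `"motor_single_bilateral"`,
#'   `"location_LR"`, `"location_single_bilateral"`.
#' @param cfg an [rsb_config()].
#' @return Object of class `rsb_task_report`: `task`, `per_repeat`
#'   data.frame of the five metrics, their `mean` and `sd`, the dataset
#'   class sizes and the configuration.
#' @export
run_task <- function(features, labels, task, cfg = rsb_config()) {
  if (is.data.frame(features)) {
    if ("subject_id" %in% names(features)) {
      if (!identical(as.character(features$subject_id),
                     as.character(labels$subject_id)))
        stop("feature and label subject_id columns do not align")
      features <- features[, setdiff(names(features), "subject_id"), drop = FALSE]
    }
    features <- as.matrix(features)
  }
  D <- task_dataset(features, labels, task)
  metrics <- c("accuracy", "sensitivity", "specificity", "f1", "predict_rate")
  per <- matrix(NA_real_, nrow = cfg$repeats, ncol = length(metrics),
                dimnames = list(NULL, metrics))
  for (r in seq_len(cfg$repeats)) {
    seed_r <- cfg$seed + r - 1L
    sp <- stratified_split(D, cfg$test_fraction, seed = seed_r)
    cfg_r <- cfg; cfg_r$seed <- seed_r
    ens <- train_ensemble(sp$train, cfg_r)
    rep_ <- evaluate(stats::predict(ens, sp$test$X), sp$test$y)
    per[r, ] <- unlist(rep_[metrics])
  }
  tab <- table(D$y)
  structure(list(task = task, per_repeat = as.data.frame(per),
                 mean = colMeans(per, na.rm = TRUE),
                 sd = apply(per, 2L, stats::sd, na.rm = TRUE),
                 class_sizes = stats::setNames(as.integer(tab), names(tab)),
                 positive = D$positive, config = cfg),
            class = "rsb_task_report")
}

#' @export
print.rsb_task_report <- function(x, ...) {
  cat(sprintf("<rsb_task_report> task %s (positive = %s; classes %s)\n",
              x$task, x$positive,
              paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
                    collapse = ", ")))
  for (m in names(x$mean)) {
    cat(sprintf("  %-13s %6.2f%% +/- %.2f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Metric table over an alpha sweep
#'
#' Trains once per repeat and re-thresholds the soft-vote probabilities at
#' each `alpha`, reproducing the trade-off in which Predict Rate decreases
#' while the other metrics typically increase with alpha.
#'
#' @param features,labels,task,cfg as in [run_task()].
#' @param alphas thresholds to evaluate (default `seq(0.5, 0.6, 0.02)`).
#' @return `data.frame` with columns `alpha` and the mean of the five
#'   metrics over repeats.
#' @export
sweep_alpha <- function(features, labels, task, cfg = rsb_config(),
                        alphas = seq(0.5, 0.6, by = 0.02)) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(names(features), "subject_id"),
                                   drop = FALSE])
  }
  D <- task_dataset(features, labels, task)
  metrics <- c("accuracy", "sensitivity", "specificity", "f1", "predict_rate")
  acc <- array(NA_real_, dim = c(cfg$repeats, length(alphas), length(metrics)))
  for (r in seq_len(cfg$repeats)) {
    seed_r <- cfg$seed + r - 1L
    sp <- stratified_split(D, cfg$test_fraction, seed = seed_r)
    cfg_r <- cfg; cfg_r$seed <- seed_r
    ens <- train_ensemble(sp$train, cfg_r)
    p <- stats::predict(ens, sp$test$X)$p_positive
    for (a in seq_along(alphas)) {
      rep_ <- evaluate(decide_at_alpha(p, alphas[a]), sp$test$y == D$positive)
      acc[r, a, ] <- unlist(rep_[metrics])
    }
  }
  out <- data.frame(alpha = alphas)
  for (m in seq_along(metrics)) {
    out[[metrics[m]]] <- apply(matrix(acc[, , m], nrow = cfg$repeats), 2L,
                               mean, na.rm = TRUE)
  }
  out
}
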