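test_that("stratified splitting preserves class composition and is deterministic", {
  set.seed(1)
  X <- matrix(rnorm(241 * 4), 241)
  y <- rep(c("positive", "negative"), c(97, 144))
  D <- rsb_dataset(X, y, positive = "positive")
  sp <- stratified_split(D, 0.3, seed = 7)
  expect_equal(unname(table(sp$test$y)["positive"]), 29L)   # round(97 * .3)
  expect_equal(unname(table(sp$test$y)["negative"]), 43L)   # round(144 * .3)
  expect_setequal(c(sp$test_indices, setdiff(1:241, sp$test_indices)), 1:241)
  sp2 <- stratified_split(D, 0.3, seed = 7)
  expect_identical(sp$test_indices, sp2$test_indices)

  bal <- rsb_dataset(matrix(rnorm(100 * 2), 100), rep(c("a", "b"), 50))
  spb <- stratified_split(bal, 0.2, seed = 1)
  expect_equal(as.vector(table(spb$test$y)), c(10L, 10L))
  one <- rsb_dataset(matrix(rnorm(6), 3), c("a", "a", "b"))
  expect_error(stratified_split(one, 0.3, 1), ">= 2 samples")
})

test_that("balanced subsets keep all minority samples and distinct majority draws", {
  set.seed(2)
  X <- matrix(rnorm(55 * 3), 55)
  y <- rep(c("pos", "neg"), c(5, 50))
  D <- rsb_dataset(X, y)
  subs <- make_balanced_subsets(D, N = 10, seed = 3)
  min_idx <- which(D$y == "pos")
  for (s in subs) {
    expect_length(s$indices, 10L)
    expect_true(all(min_idx %in% s$indices))
    expect_length(s$majority_indices, 5L)
    expect_false(anyDuplicated(s$majority_indices) > 0)
    expect_true(all(D$y[s$majority_indices] == "neg"))
  }
  # across many subsets the union of majority picks covers nearly everything
  subs200 <- make_balanced_subsets(D, N = 200, seed = 4)
  covered <- unique(unlist(lapply(subs200, `[[`, "majority_indices")))
  expect_gt(length(covered) / 50, 0.95)
})

test_that("separable data trains perfect base models and N=1 matches a single SVM", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40 * 2, mean = 0), 40),
             matrix(rnorm(160 * 2, mean = 6), 160))
  y <- rep(c("case", "ctrl"), c(40, 160))
  D <- rsb_dataset(X, y)
  ens <- train_ensemble(D, rsb_config(N = 5, seed = 1))
  for (i in seq_along(ens$base_models)) {
    m <- ens$base_models[[i]]
    idx <- ens$subset_indices[[i]]
    Xs <- sweep(sweep(D$X[idx, ], 2, ens$center), 2, ens$scale, "/")
    expect_equal(mean(predict(m$svm, Xs) == D$y[idx]), 1)
  }
  # degenerate ensemble: N = 1 at alpha = 0.5 equals its one undersampled SVM
  ens1 <- train_ensemble(D, rsb_config(N = 1, seed = 2))
  Xnew <- rbind(matrix(rnorm(20 * 2, mean = 0), 20),
                matrix(rnorm(20 * 2, mean = 6), 20))
  pr <- predict(ens1, Xnew)
  Xs <- sweep(sweep(Xnew, 2, ens1$center), 2, ens1$scale, "/")
  single <- unname(as.character(predict(ens1$base_models[[1]]$svm, Xs)))
  expect_identical(unname(ifelse(pr$decision == "positive", "case", "ctrl")),
                   single)
  expect_true(all(pr$decision != "ABSTAIN"))
})

test_that("the abstaining soft vote follows the threshold arithmetic", {
  expect_identical(decide_at_alpha(0.55, 0.6), "ABSTAIN")
  expect_identical(decide_at_alpha(0.55, 0.5), "positive")
  expect_identical(decide_at_alpha(0.5, 0.5), "positive")    # tie -> minority
  expect_identical(decide_at_alpha(0.39, 0.6), "negative")
  expect_error(decide_at_alpha(0.5, 0.4), "alpha")
})

test_that("predict rate is 100% at alpha 0.5 and non-increasing over a sweep", {
  set.seed(6)
  X <- rbind(matrix(rnorm(30 * 3), 30), matrix(rnorm(120 * 3, mean = 1.2), 120))
  y <- rep(c("pos", "neg"), c(30, 120))
  D <- rsb_dataset(X, y)
  sp <- stratified_split(D, 0.3, seed = 1)
  ens <- train_ensemble(sp$train, rsb_config(N = 7, seed = 1))
  p <- predict(ens, sp$test$X)$p_positive
  rates <- vapply(seq(0.5, 0.9, by = 0.05), function(a) {
    evaluate(decide_at_alpha(p, a), sp$test$y == "pos")$predict_rate
  }, numeric(1))
  expect_equal(rates[1], 100)
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("evaluate reproduces the metric formulas and a brute-force confusion count", {
  rep_ <- evaluate(c("positive", "positive", "negative", "negative", "negative",
                     "positive", "negative"),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(rep_[c("TP", "TN", "FP", "FN")], list(TP = 2L, TN = 3L, FP = 1L, FN = 1L),
               ignore_attr = TRUE)
  expect_equal(rep_$accuracy, 100 * 5 / 7, tolerance = 1e-12)
  expect_equal(round(rep_$accuracy, 2), 71.43)
  expect_equal(round(rep_$sensitivity, 2), 66.67)
  expect_equal(rep_$specificity, 75)
  expect_equal(round(rep_$f1, 2), 66.67)
  expect_equal(rep_$predict_rate, 100)

  # abstentions leave the confusion counts but stay in the denominator
  dec <- c(rep("ABSTAIN", 3), rep("positive", 4), rep("negative", 3))
  expect_equal(evaluate(dec, rep(c(TRUE, FALSE), 5))$predict_rate, 70)

  # brute-force equivalence on 1000 random prediction/label pairs
  set.seed(7)
  dec <- sample(c("positive", "negative", "ABSTAIN"), 1000, replace = TRUE)
  tru <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  got <- evaluate(dec, tru)
  tab <- table(factor(dec, c("positive", "negative", "ABSTAIN")), tru)
  expect_identical(got$TP, unname(tab["positive", "TRUE"]))
  expect_identical(got$FP, unname(tab["positive", "FALSE"]))
  expect_identical(got$TN, unname(tab["negative", "FALSE"]))
  expect_identical(got$FN, unname(tab["negative", "TRUE"]))
  n_pred <- sum(dec != "ABSTAIN")
  expect_equal(got$accuracy, 100 * (got$TP + got$TN) / n_pred)
  expect_equal(got$predict_rate, 100 * n_pred / 1000)
})

test_that("a coin-flip predictor scores near 50% accuracy on balanced data", {
  set.seed(8)
  n <- 1000
  dec <- sample(c("positive", "negative"), n, replace = TRUE)
  tru <- rep(c(TRUE, FALSE), n / 2)
  acc <- evaluate(dec, tru)$accuracy
  expect_lt(abs(acc - 50), 3 * 100 * 0.5 / sqrt(n))
})

test_that("averaging more base models never increases the vote variance", {
  set.seed(9)
  X <- rbind(matrix(rnorm(24 * 2), 24), matrix(rnorm(120 * 2, mean = 1), 120))
  y <- rep(c("pos", "neg"), c(24, 120))
  D <- rsb_dataset(X, y)
  xstar <- matrix(c(0.5, 0.5), 1)
  votes <- function(N) vapply(1:15, function(s) {
    ens <- train_ensemble(D, rsb_config(N = N, seed = 100 + s))
    predict(ens, xstar)$p_positive
  }, numeric(1))
  expect_lte(var(votes(51)), var(votes(5)))
})

test_that("run_task builds the clinical tasks with the printed class sizes", {
  coh <- gen_cohort(preset = "table1", n_features = 12, separation = 2, seed = 1)
  cfg <- rsb_config(N = 5, seed = 3, repeats = 2)
  doc <- run_task(coh$features, coh$labels, "doc", cfg)
  expect_equal(unname(doc$class_sizes["positive"]), 97L)
  expect_equal(unname(doc$class_sizes["negative"]), 144L)
  motor <- run_task(coh$features, coh$labels, "motor_LR", cfg)
  expect_setequal(unname(motor$class_sizes), c(37L, 46L))
  expect_identical(motor$positive, "L")
  loc <- run_task(coh$features, coh$labels, "location_LR", cfg)
  expect_setequal(unname(loc$class_sizes), c(52L, 47L))
  msb <- run_task(coh$features, coh$labels, "motor_single_bilateral", cfg)
  expect_equal(unname(msb$class_sizes["bilateral"]), 23L)
  expect_equal(unname(msb$class_sizes["single"]), 83L)
  lsb <- run_task(coh$features, coh$labels, "location_single_bilateral", cfg)
  expect_equal(unname(lsb$class_sizes["bilateral"]), 36L)
  expect_equal(unname(lsb$class_sizes["single"]), 99L)

  # fixed seed, one repeat: bitwise-reproducible report
  cfg1 <- rsb_config(N = 3, seed = 11, repeats = 1)
  r1 <- run_task(coh$features, coh$labels, "doc", cfg1)
  r2 <- run_task(coh$features, coh$labels, "doc", cfg1)
  expect_identical(r1$per_repeat, r2$per_repeat)
})

test_that("alpha sweeps trade predict rate against the other metrics", {
  coh <- gen_cohort(c(neg = 120, pos = 30), n_features = 6, separation = 1.5,
                    seed = 2)
  labels <- data.frame(subject_id = coh$labels$subject_id,
                       consciousness = ifelse(coh$labels$class == "pos",
                                              "stupor", "awake"),
                       motor_side = "none", stroke_side = "none")
  sw <- sweep_alpha(coh$features, labels, "doc",
                    rsb_config(N = 5, seed = 1, repeats = 3),
                    alphas = seq(0.5, 0.9, by = 0.1))
  expect_equal(sw$predict_rate[1], 100)
  expect_true(all(diff(sw$predict_rate) <= 1e-9))
})
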