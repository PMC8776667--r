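toy_manifest <- function(n_pat, slices, labels = c("SCN", "MCN")) {
  do.call(rbind, lapply(labels, function(lb) {
    do.call(rbind, lapply(seq_len(n_pat), function(i) {
      data.frame(label = lb, patient_id = sprintf("%s%02d", lb, i),
                 slice_index = seq_len(slices))
    }))
  }))
}

test_that("image-mode splits are stratified, exhaustive and deterministic", {
  m <- toy_manifest(10, 5)   # 100 images, 50 per class
  sp <- split_spec(0.8, "image", seed = 4)
  s1 <- split_dataset(m, sp)
  s2 <- split_dataset(m, sp)
  expect_identical(s1, s2)
  expect_length(s1$train, 80)
  expect_length(s1$test, 20)
  expect_setequal(c(s1$train, s1$test), seq_len(100))
  expect_equal(as.vector(table(m$label[s1$train])), c(40, 40))
})

test_that("patient-mode splits never straddle a patient", {
  m <- toy_manifest(10, 5)
  s <- split_dataset(m, split_spec(0.8, "patient", seed = 2))
  expect_length(intersect(m$patient_id[s$train], m$patient_id[s$test]), 0)
  expect_setequal(c(s$train, s$test), seq_len(nrow(m)))
  expect_true(all(c("SCN", "MCN") %in% m$label[s$test]))
  m2 <- m; m2$patient_id <- NULL
  expect_error(split_dataset(m2, split_spec(0.8, "patient")),
               class = "cystct_input_error")
})

test_that("confusion counts equal a brute-force tally", {
  y_true <- c("MCN", "MCN", "SCN", "SCN", "MCN", "SCN", "MCN", "SCN", "SCN", "MCN")
  y_pred <- c("MCN", "SCN", "SCN", "MCN", "MCN", "SCN", "MCN", "SCN", "MCN", "SCN")
  cc <- confusion_counts(y_true, y_pred, positive = "MCN")
  expect_equal(cc$tp, 3); expect_equal(cc$fn, 2)
  expect_equal(cc$fp, 2); expect_equal(cc$tn, 3)
  perfect <- confusion_counts(y_true, y_true)
  expect_equal(perfect$fp + perfect$fn, 0)
  allpos <- confusion_counts(y_true, rep("MCN", 10))
  expect_equal(allpos$tn, 0)
  expect_equal(allpos$fp, 5)
  expect_error(confusion_counts(y_true, y_pred[1:5]), class = "cystct_input_error")
})

test_that("the six indicators follow their defining formulas", {
  cc <- confusion_counts(c("MCN", "SCN"), c("MCN", "SCN"))
  m <- compute_metrics(cc)
  expect_equal(unlist(m[c("precision", "sensitivity", "specificity",
                          "accuracy", "f1")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1, f1 = 1))
  # precision = sensitivity = s  =>  f1 = s
  cc2 <- structure(list(tp = 3, fp = 1, tn = 5, fn = 1, positive = "MCN"),
                   class = "confusion_counts")
  m2 <- compute_metrics(cc2)
  expect_equal(m2$precision, m2$sensitivity)
  expect_equal(m2$f1, m2$precision)
  # accuracy is the prevalence-weighted combination of sens and spec
  set.seed(3)
  for (i in 1:10) {
    k <- as.list(rmultinom(1, 50, rep(0.25, 4))[, 1] + 1)
    names(k) <- c("tp", "fp", "tn", "fn")
    cc3 <- structure(c(k, positive = "MCN"), class = "confusion_counts")
    m3 <- compute_metrics(cc3)
    npos <- k$tp + k$fn; nneg <- k$tn + k$fp
    expect_equal(m3$accuracy,
                 (npos * m3$sensitivity + nneg * m3$specificity) / (npos + nneg))
  }
  # degenerate predictors warn and report 0 rather than crash
  cc4 <- structure(list(tp = 0, fp = 0, tn = 4, fn = 2, positive = "MCN"),
                   class = "confusion_counts")
  expect_warning(m4 <- compute_metrics(cc4), "precision")
  expect_equal(m4$precision, 0)
  expect_error(compute_metrics(structure(list(tp = 0, fp = 0, tn = 0, fn = 0,
                                              positive = "MCN"),
                                         class = "confusion_counts")),
               class = "cystct_input_error")
})

test_that("AUC is the Mann-Whitney pair probability", {
  y <- c("MCN", "SCN", "MCN", "SCN")
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.3, 0.4)), 0.5)
  expect_equal(roc_auc(y, c(0.9, 0.1, 0.8, 0.2)), 1)
  expect_equal(roc_auc(y, rep(0.5, 4)), 0.5)
  expect_error(roc_auc(rep("MCN", 4), runif(4)), class = "cystct_label_error")
  # exhaustive pair-count oracle on small random vectors
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:12, 1)
    yy <- sample(c("SCN", "MCN"), n, replace = TRUE)
    if (length(unique(yy)) < 2) next
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(yy, sc), oracle_auc(yy, sc, "MCN"))
  }
})

test_that("rank AUC equals the trapezoidal area under the empirical ROC", {
  skip_if_not_installed("pROC")
  for (s in 1:5) {
    set.seed(s)
    y <- sample(c("SCN", "MCN"), 40, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    sc <- rnorm(40) + (y == "MCN")
    rp <- roc_points(y, sc)
    trap <- -sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
    expect_equal(roc_auc(y, sc), abs(trap), tolerance = 1e-12)
    pr <- pROC::auc(pROC::roc(y, sc, levels = c("SCN", "MCN"),
                              direction = "<", quiet = TRUE))
    expect_equal(roc_auc(y, sc), as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("the paired AUC permutation test behaves at its extremes", {
  set.seed(4)
  y <- rep(c("MCN", "SCN"), 25)
  s_good <- (y == "MCN") + rnorm(50, 0, 0.1)
  res_same <- auc_permutation_test(y, s_good, s_good, n_perm = 200, seed = 1)
  expect_equal(res_same$delta, 0)
  expect_equal(res_same$p_value, 1)
  res_diff <- auc_permutation_test(y, s_good, rnorm(50), n_perm = 200, seed = 1)
  expect_lt(res_diff$p_value, 0.05)
  expect_gt(res_diff$auc1, res_diff$auc2)
})
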