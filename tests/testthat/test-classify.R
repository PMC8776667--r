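test_that("base classifier probabilities are normalised and sensible", {
  blobs <- make_blobs(120, sep = 3, seed = 1)
  for (kind in c("knn", "softmax", "bayes", "svm")) {
    m <- fit_base(blobs$X, blobs$y, base_config(kind, seed = 2))
    p <- predict_proba(m, blobs$X)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-8)
    expect_true(all(p >= 0 & p <= 1))
  }
  # softmax separates two disjoint blobs perfectly in-sample
  sep <- make_blobs(120, sep = 8, seed = 2)
  msoft <- fit_base(sep$X, sep$y, base_config("softmax", regularization = 0.01))
  psoft <- predict_proba(msoft, sep$X)[, "MCN"]
  expect_equal(mean((psoft >= 0.5) == (sep$y == "MCN")), 1)
  expect_error(fit_base(blobs$X, rep("MCN", 120), base_config("knn")),
               class = "cystct_label_error")
  Xbad <- blobs$X; Xbad[1, 1] <- NA
  expect_error(fit_base(Xbad, blobs$y, base_config("knn")),
               class = "cystct_input_error")
})

test_that("1-NN assigns a training point its own label with probability 1", {
  blobs <- make_blobs(40, sep = 2, seed = 3)
  m <- fit_base(blobs$X, blobs$y, base_config("knn", k = 1))
  p <- predict_proba(m, blobs$X)
  pred <- colnames(p)[apply(p, 1, which.max)]
  expect_equal(pred, blobs$y)
  expect_true(all(apply(p, 1, max) == 1))
})

test_that("Gaussian naive Bayes is symmetric and honest about noise", {
  # symmetric two-Gaussian toy: equal priors/variance, means +-1 -> 0.5 at 0
  X <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  y <- c("SCN", "SCN", "SCN", "MCN", "MCN", "MCN")
  m <- fit_base(X, y, base_config("bayes"))
  p <- predict_proba(m, matrix(0))
  expect_equal(unname(p[1, "MCN"]), 0.5, tolerance = 1e-9)
  # uninformative features -> chance-level test accuracy
  set.seed(11)
  n <- 500
  Xn <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  yn <- rep(c("SCN", "MCN"), n)
  tr <- seq_len(n)
  mb <- fit_base(Xn[tr, ], yn[tr], base_config("bayes"))
  acc <- mean((predict_proba(mb, Xn[-tr, ])[, "MCN"] >= 0.5) == (yn[-tr] == "MCN"))
  expect_lt(abs(acc - 0.5), 0.1)
})

test_that("majority vote keeps strict three-voter semantics", {
  expect_equal(majority_vote(c("SCN", "SCN", "MCN")), "SCN")
  expect_equal(majority_vote(c("MCN", "MCN", "MCN")), "MCN")
  expect_error(majority_vote(c("SCN", "MCN")), class = "cystct_vote_error")
  expect_error(majority_vote(c("SCN", "MCN", "SCN", "MCN")), class = "cystct_vote_error")
})

test_that("stacking discovers the informative base classifier", {
  d <- make_stacking_data(400, seed = 5)
  dt <- make_stacking_data(200, seed = 6)
  bases <- list(base_config("knn", columns = 1),
                base_config("knn", columns = 2),
                base_config("knn", columns = 3))
  fit <- mmrf(d$X, d$y, base_configs = bases, cv_folds = 5, seed = 1)
  acc <- mean(as.character(predict(fit, dt$X, type = "class")) == dt$y)
  expect_gte(acc, 0.95)
  fused_auc <- roc_auc(dt$y, predict(fit, dt$X, type = "prob"))
  all_p <- predict(fit, dt$X, type = "all")
  expect_gte(fused_auc, roc_auc(dt$y, all_p[[2]]))
  expect_gte(fused_auc, roc_auc(dt$y, all_p[[3]]))
  # the informative base dominates the meta-forest importance
  imp <- randomForest::importance(fit$meta_model)[, 1]
  expect_equal(unname(which.max(imp)), 1)
})

test_that("meta-training uses only out-of-fold base probabilities", {
  # with a 1-NN base, an in-sample probability would equal the label exactly;
  # out-of-fold probabilities on noisy data cannot be perfect
  set.seed(8)
  n <- 120
  y <- rep(c("SCN", "MCN"), n / 2)
  X <- cbind(ifelse(y == "MCN", 0.3, -0.3) + rnorm(n), rnorm(n))
  fit <- mmrf(X, y, base_configs = list(base_config("knn", k = 1),
                                        base_config("softmax"),
                                        base_config("bayes")),
              cv_folds = 4, seed = 2)
  in_sample <- as.numeric(y == "MCN")
  expect_false(all(fit$oof[, 1] == in_sample))
  # and the stored folds really partition the data
  expect_setequal(unique(fit$fold_id), 1:4)
  # reconstruct one base's out-of-fold column from the stored partition
  cfg <- base_config("knn", k = 1)
  cfg$seed <- derive_seed(2, "base1")
  recon <- rep(NA_real_, n)
  for (f in 1:4) {
    tr <- fit$fold_id != f
    m <- fit_base(X[tr, , drop = FALSE], factor(y)[tr], cfg, positive = "MCN")
    recon[!tr] <- predict_proba(m, X[!tr, , drop = FALSE])[, "MCN"]
  }
  expect_equal(recon, unname(fit$oof[, 1]))
})

test_that("identical bases reduce stacking to the shared base; votes agree", {
  blobs <- make_blobs(120, sep = 4, seed = 9)
  test <- make_blobs(60, sep = 4, seed = 10)
  bases <- replicate(3, base_config("knn", k = 5), simplify = FALSE)
  fit <- mmrf(blobs$X, blobs$y, base_configs = bases, cv_folds = 4, seed = 3)
  shared <- fit_base(blobs$X, blobs$y, base_config("knn", k = 5,
                                                   seed = fit$base_models[[1]]$config$seed))
  p_base <- predict_proba(shared, test$X)[, "MCN"]
  pred_base <- ifelse(p_base >= 0.5, "MCN", "SCN")
  pred_stack <- as.character(predict(fit, test$X, type = "class"))
  expect_equal(pred_stack, pred_base)
  # unanimous confident bases match the majority vote
  all_p <- predict(fit, test$X, type = "all")
  conf <- all_p[[1]] %in% c(0, 1) & all_p[[1]] == all_p[[2]] & all_p[[2]] == all_p[[3]]
  if (any(conf)) {
    votes <- vapply(which(conf), function(i) {
      majority_vote(ifelse(unlist(all_p[i, 1:3]) >= 0.5, "MCN", "SCN"))
    }, "")
    expect_equal(votes, as.character(all_p$class[conf]))
  }
})

test_that("mmrf refits are seed-deterministic and validate their inputs", {
  d <- make_stacking_data(120, seed = 12)
  f1 <- mmrf(d$X, d$y, cv_folds = 4, seed = 7)
  f2 <- mmrf(d$X, d$y, cv_folds = 4, seed = 7)
  newX <- make_stacking_data(60, seed = 13)$X
  expect_identical(predict(f1, newX), predict(f2, newX))
  expect_identical(f1$oof, f2$oof)
  expect_error(mmrf(d$X, d$y, cv_folds = 1), class = "cystct_param_error")
  expect_error(predict(f1, newX[, 1:2]), class = "cystct_input_error")
  expect_output(print(f1), "Stacked random-forest")
  s <- summary(f1)
  expect_length(s$oof_auc, 3)
})
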