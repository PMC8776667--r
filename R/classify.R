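# Classification layer. Base learners (KNN, softmax = L2-regularised
# logistic regression, Gaussian naive Bayes, SVM) each expose calibrated
# class probabilities; their probabilities are fused either by majority
# voting on hard labels or by the stacked random-forest model fitted by
# mmrf(), the package's central estimator. The meta-model is trained on
# out-of-fold base probabilities only, so it never sees a base model's
# prediction on a point that model was trained on (no target leakage).
#
# The positive class is MCN throughout (the clinically actionable class):
# all single-probability outputs are P(MCN), and hard labels threshold that
# probability at 0.5 with ties going to the positive class.

#' Base-classifier configuration
#'
#' @param kind `"knn"`, `"softmax"`, `"bayes"` or `"svm"`.
#' @param k neighbour count for KNN; odd, so binary votes cannot tie.
#' @param regularization ridge penalty (softmax) or cost (svm); > 0.
#' @param kernel SVM kernel, `"linear"` or `"rbf"`.
#' @param columns optional integer feature-column subset this base sees.
#' @param seed integer seed for any stochastic fitting step.
#' @return A list of class `"base_config"`.
#' @export
base_config <- function(kind = c("knn", "softmax", "bayes", "svm"),
                        k = 5L, regularization = 1, kernel = c("rbf", "linear"),
                        columns = NULL, seed = 1L) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  if (k < 1 || k %% 2 == 0) cyst_error("k must be odd and >= 1", "cystct_param_error")
  if (regularization <= 0) cyst_error("regularization must be > 0", "cystct_param_error")
  structure(list(kind = kind, k = as.integer(k), regularization = regularization,
                 kernel = kernel, columns = columns, seed = as.integer(seed)),
            class = "base_config")
}

resolve_positive <- function(levels, positive = NULL) {
  if (!is.null(positive)) {
    if (!(positive %in% levels)) cyst_error("positive class not among labels", "cystct_label_error")
    return(positive)
  }
  if ("MCN" %in% levels) "MCN" else levels[2]
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) cyst_error("feature matrix must be numeric", "cystct_input_error")
  if (anyNA(X) || any(!is.finite(X))) {
    cyst_error("NaN/Inf in feature matrix", "cystct_input_error")
  }
  y <- factor(y)
  if (nlevels(y) != 2) {
    cyst_error("labels must contain exactly two classes", "cystct_label_error")
  }
  if (length(y) != nrow(X)) cyst_error("X rows and y length differ", "cystct_input_error")
  list(X = X, y = y)
}

#' Fit one base classifier
#'
#' Features are standardised internally with training-set statistics only.
#' Every fit is deterministic given `config$seed`.
#'
#' @param X numeric feature matrix (rows = images).
#' @param y binary labels (factor or character).
#' @param config a [base_config()].
#' @param positive positive class; defaults to `"MCN"` when present.
#' @return A fitted model of class `"cystct_base"` exposing
#'   [predict_proba()].
#' @export
fit_base <- function(X, y, config = base_config(), positive = NULL) {
  stopifnot(inherits(config, "base_config"))
  xy <- check_xy(X, y); X <- xy$X; y <- xy$y
  if (!is.null(config$columns)) X <- X[, config$columns, drop = FALSE]
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd); sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  positive <- resolve_positive(levels(y), positive)
  inner <- with_seed(config$seed, switch(config$kind,
    knn = list(train = Xs, y = y),
    softmax = {
      Xg <- if (ncol(Xs) == 1) cbind(Xs, 0) else Xs  # glmnet needs >= 2 columns
      glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                     lambda = config$regularization, standardize = FALSE)
    },
    bayes = e1071::naiveBayes(as.data.frame(Xs), y),
    svm = e1071::svm(Xs, y, kernel = ifelse(config$kernel == "rbf", "radial", "linear"),
                     cost = config$regularization, probability = TRUE)
  ))
  structure(list(kind = config$kind, config = config, inner = inner,
                 mu = mu, sd = sd, levels = levels(y), positive = positive),
            class = "cystct_base")
}

#' Class-probability predictions
#'
#' @param model a fitted model.
#' @param X feature matrix matching the training dimension.
#' @param ... unused.
#' @return Matrix with one column per class (training level order); rows
#'   sum to 1. KNN probabilities are neighbour vote fractions, Bayes the
#'   Gaussian naive-Bayes posterior, softmax the logistic posterior, SVM a
#'   Platt-calibrated score.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @export
predict_proba.cystct_base <- function(model, X, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.null(model$config$columns)) X <- X[, model$config$columns, drop = FALSE]
  if (ncol(X) != length(model$mu)) {
    cyst_error("feature dimension differs from training", "cystct_input_error")
  }
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  lv <- model$levels
  p_pos <- switch(model$kind,
    knn = {
      pred <- with_seed(model$config$seed,
        class::knn(model$inner$train, Xs, model$inner$y,
                   k = model$config$k, prob = TRUE, use.all = TRUE))
      win <- attr(pred, "prob")
      ifelse(as.character(pred) == model$positive, win, 1 - win)
    },
    softmax = {
      Xg <- if (ncol(Xs) == 1) cbind(Xs, 0) else Xs
      p2 <- as.numeric(stats::predict(model$inner, newx = Xg, type = "response"))
      # glmnet's response is P(second level)
      if (model$positive == lv[2]) p2 else 1 - p2
    },
    bayes = {
      pr <- stats::predict(model$inner, as.data.frame(Xs), type = "raw")
      pr[, model$positive]
    },
    svm = {
      pr <- attr(stats::predict(model$inner, Xs, probability = TRUE), "probabilities")
      pr[, model$positive]
    }
  )
  neg <- setdiff(lv, model$positive)
  out <- cbind(1 - p_pos, p_pos)
  colnames(out) <- c(neg, model$positive)
  out[, lv, drop = FALSE]
}

#' @export
#' @method print cystct_base
print.cystct_base <- function(x, ...) {
  cat(sprintf("<cystct_base %s: %d features, classes %s (positive %s)>\n",
              x$kind, length(x$mu), paste(x$levels, collapse = "/"), x$positive))
  invisible(x)
}

#' Majority vote over exactly three binary predictions
#'
#' With three binary voters the mode is always unique; any other voter
#' count is rejected to keep the three-classifier semantics explicit.
#'
#' @param labels character/factor vector of exactly 3 binary votes.
#' @return The modal label (character).
#' @export
majority_vote <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) != 3) {
    cyst_error("majority_vote expects exactly 3 votes", "cystct_vote_error")
  }
  if (length(unique(labels)) > 2) {
    cyst_error("votes must be binary", "cystct_vote_error")
  }
  tab <- sort(table(labels), decreasing = TRUE)
  names(tab)[1]
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit the stacked random-forest fusion model (MMRF)
#'
#' The package's central estimator. Three (by default) base classifiers are
#' cross-validated on the training set; the out-of-fold positive-class
#' probabilities form a meta-feature matrix (one column per base) on which
#' a random forest is fitted; the bases are then refit on the full training
#' set for deployment. Because every meta-training probability comes from a
#' fold the producing base model never saw, the forest learns how much to
#' trust each base without target leakage — effectively weighting the more
#' accurate classifiers higher.
#'
#' @param X numeric feature matrix (rows = images).
#' @param y binary labels.
#' @param base_configs list of [base_config()]s, one per base classifier
#'   (default: KNN, softmax, Gaussian naive Bayes).
#' @param ntree,meta random-forest size (`ntree`, default 200) or a full
#'   list of `randomForest` arguments via `meta`.
#' @param cv_folds stratified folds for out-of-fold probabilities (>= 2).
#' @param seed integer seed fixing folds, base fits and the forest.
#' @param positive positive class; defaults to `"MCN"` when present.
#' @return An object of class `"mmrf"` with components `base_models`,
#'   `meta_model`, `oof` (meta-training matrix), `fold_id`, `levels`,
#'   `positive`.
#' @seealso [predict.mmrf()], [majority_vote()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 4), 200)
#' y <- ifelse(X[, 1] + rnorm(200, 0, 0.5) > 0, "MCN", "SCN")
#' fit <- mmrf(X, y, cv_folds = 3, seed = 1)
#' head(predict(fit, X))
#' @export
mmrf <- function(X, y,
                 base_configs = list(base_config("knn"), base_config("softmax"),
                                     base_config("bayes")),
                 ntree = 200L, meta = list(ntree = ntree),
                 cv_folds = 5L, seed = 1L, positive = NULL) {
  xy <- check_xy(X, y); X <- xy$X; y <- xy$y
  if (cv_folds < 2) cyst_error("cv_folds must be >= 2", "cystct_param_error")
  positive <- resolve_positive(levels(y), positive)
  fold_id <- stratified_folds(y, cv_folds, derive_seed(seed, "folds"))
  for (f in seq_len(cv_folds)) {
    if (nlevels(droplevels(y[fold_id != f])) < 2) {
      cyst_error("a training fold contains a single class; use fewer folds or more data",
                 "cystct_fold_error")
    }
  }
  nb <- length(base_configs)
  oof <- matrix(NA_real_, nrow(X), nb)
  colnames(oof) <- vapply(seq_len(nb), function(i) {
    sprintf("p%d_%s", i, base_configs[[i]]$kind)
  }, "")
  for (i in seq_len(nb)) {
    cfg <- base_configs[[i]]
    cfg$seed <- derive_seed(seed, sprintf("base%d", i))
    for (f in seq_len(cv_folds)) {
      tr <- fold_id != f
      m <- fit_base(X[tr, , drop = FALSE], y[tr], cfg, positive = positive)
      oof[!tr, i] <- predict_proba(m, X[!tr, , drop = FALSE])[, positive]
    }
  }
  meta_args <- utils::modifyList(list(ntree = 200L), meta)
  meta_model <- with_seed(derive_seed(seed, "meta"), {
    do.call(randomForest::randomForest,
            c(list(x = oof, y = y), meta_args))
  })
  base_models <- lapply(seq_len(nb), function(i) {
    cfg <- base_configs[[i]]
    cfg$seed <- derive_seed(seed, sprintf("base%d", i))
    fit_base(X, y, cfg, positive = positive)
  })
  structure(list(base_models = base_models, meta_model = meta_model,
                 oof = oof, fold_id = fold_id, cv_folds = cv_folds,
                 levels = levels(y), positive = positive, seed = seed,
                 n = nrow(X)),
            class = "mmrf")
}

mmrf_base_probs <- function(object, X) {
  P <- vapply(object$base_models, function(m) {
    predict_proba(m, X)[, object$positive]
  }, numeric(nrow(as.matrix(X))))
  P <- matrix(P, ncol = length(object$base_models))
  colnames(P) <- colnames(object$oof)
  P
}

#' Predict from a fitted MMRF model
#'
#' Base-classifier probabilities are computed for the new data and fused by
#' the random-forest meta-model. Hard labels threshold the fused P(positive)
#' at 0.5; a probability of exactly 0.5 is assigned to the positive class.
#'
#' @param object an [mmrf()] fit.
#' @param newdata feature matrix with the training dimension.
#' @param type `"prob"` for fused positive-class probabilities, `"class"`
#'   for hard labels, `"all"` for a data.frame with base probabilities too.
#' @param ... unused.
#' @return Numeric vector, factor, or data.frame according to `type`.
#' @export
predict.mmrf <- function(object, newdata, type = c("prob", "class", "all"), ...) {
  type <- match.arg(type)
  P <- mmrf_base_probs(object, newdata)
  fused <- stats::predict(object$meta_model, P, type = "prob")[, object$positive]
  if (type == "prob") return(unname(fused))
  cls <- factor(ifelse(fused >= 0.5, object$positive,
                       setdiff(object$levels, object$positive)),
                levels = object$levels)
  if (type == "class") return(cls)
  data.frame(P, fused = unname(fused), class = cls)
}

#' @export
#' @method print mmrf
print.mmrf <- function(x, ...) {
  kinds <- vapply(x$base_models, function(m) m$kind, "")
  cat("Stacked random-forest fusion model (MMRF)\n")
  cat(sprintf("  bases: %s | meta: random forest (%d trees)\n",
              paste(kinds, collapse = ", "), x$meta_model$ntree))
  cat(sprintf("  n = %d, %d-fold out-of-fold stacking, positive class %s\n",
              x$n, x$cv_folds, x$positive))
  invisible(x)
}

#' @export
#' @method summary mmrf
summary.mmrf <- function(object, ...) {
  y <- object$meta_model$y
  oof_auc <- apply(object$oof, 2, function(s) roc_auc(y, s, positive = object$positive))
  imp <- randomForest::importance(object$meta_model)[, 1]
  out <- list(model = object, oof_auc = oof_auc, importance = imp)
  class(out) <- "summary.mmrf"
  out
}

#' @export
#' @method print summary.mmrf
print.summary.mmrf <- function(x, ...) {
  print(x$model)
  cat("  out-of-fold AUC per base:\n")
  for (nm in names(x$oof_auc)) {
    cat(sprintf("    %-12s %.3f  (meta importance %.1f)\n",
                nm, x$oof_auc[nm], x$importance[nm]))
  }
  invisible(x)
}

#' Meta-model importance of each base classifier
#'
#' @param x an [mmrf()] fit.
#' @param ... passed to [barplot()].
#' @return Invisibly, the importance vector.
#' @export
plot.mmrf <- function(x, ...) {
  imp <- randomForest::importance(x$meta_model)[, 1]
  graphics::barplot(imp, ylab = "meta-forest importance",
                    xlab = "base classifier", ...)
  invisible(imp)
}
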