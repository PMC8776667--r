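# Dataset splitting and the six evaluation indicators (precision,
# sensitivity, specificity, accuracy, F1, AUC), computed against the known
# class of each image. Splitting supports the image-level 80/20 random
# split and a patient-level variant in which all slices of a patient fall
# on the same side (the default, since same-patient slices are correlated).

#' Train/test split specification
#'
#' @param train_fraction fraction of images used for training, in (0, 1).
#' @param mode `"patient"` (whole patients per side; default) or `"image"`
#'   (stratified random split of images, which lets slices of one patient
#'   appear on both sides).
#' @param seed integer seed.
#' @return A list of class `"split_spec"`.
#' @export
split_spec <- function(train_fraction = 0.8, mode = c("patient", "image"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1) {
    cyst_error("train_fraction must be in (0, 1)", "cystct_param_error")
  }
  structure(list(train_fraction = train_fraction, mode = mode,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split a manifest into train and test indices
#'
#' Image mode draws a stratified random sample of images per class. Patient
#' mode assigns whole patients to one side, approximating the requested
#' image fraction per class; both sides are guaranteed nonempty and the
#' split is disjoint, exhaustive and seed-deterministic.
#'
#' @param manifest data.frame with a `label` column (and `patient_id` for
#'   patient mode).
#' @param spec a [split_spec()].
#' @return List with integer vectors `train` and `test`.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (nrow(manifest) < 2 || is.null(manifest$label)) {
    cyst_error("manifest must be nonempty with a label column", "cystct_input_error")
  }
  lab <- as.character(manifest$label)
  with_seed(spec$seed, {
    train <- integer(0)
    if (spec$mode == "image") {
      for (lv in unique(lab)) {
        idx <- which(lab == lv)
        n_tr <- round(spec$train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        train <- c(train, sample(idx, n_tr))
      }
    } else {
      if (is.null(manifest$patient_id)) {
        cyst_error("patient-mode split requires patient_id", "cystct_input_error")
      }
      pid <- as.character(manifest$patient_id)
      for (lv in unique(lab)) {
        pats <- unique(pid[lab == lv])
        pats <- sample(pats)
        target <- spec$train_fraction * sum(lab == lv)
        got <- 0L; chosen <- character(0)
        for (p in pats) {
          if (got >= target && length(chosen) > 0) break
          if (length(chosen) == length(pats) - 1L) break  # keep one patient for test
          chosen <- c(chosen, p)
          got <- got + sum(pid == p & lab == lv)
        }
        train <- c(train, which(pid %in% chosen & lab == lv))
      }
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(nrow(manifest)), train))
  })
}

#' Confusion counts against a declared positive class
#'
#' @param y_true,y_pred equal-length binary label vectors.
#' @param positive the positive class (default `"MCN"` when present).
#' @return A list of class `"confusion_counts"` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    cyst_error("y_true and y_pred lengths differ", "cystct_input_error")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  positive <- resolve_positive(sort(unique(y_true)), positive)
  structure(list(
    tp = sum(y_true == positive & y_pred == positive),
    fp = sum(y_true != positive & y_pred == positive),
    tn = sum(y_true != positive & y_pred != positive),
    fn = sum(y_true == positive & y_pred != positive),
    positive = positive
  ), class = "confusion_counts")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("zero denominator for %s; reporting 0", what), call. = FALSE)
    return(0)
  }
  num / den
}

#' F1 score from precision and sensitivity
#'
#' The harmonic mean `2 * precision * sensitivity / (precision +
#' sensitivity)`, ranging from 0 to 1; defined as 0 when both inputs are 0.
#'
#' @param precision,sensitivity fractions in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, sensitivity) {
  if (precision < 0 || precision > 1 || sensitivity < 0 || sensitivity > 1) {
    cyst_error("precision and sensitivity must lie in [0, 1]", "cystct_param_error")
  }
  if (precision + sensitivity == 0) return(0)
  2 * precision * sensitivity / (precision + sensitivity)
}

#' The six evaluation indicators from confusion counts
#'
#' precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/total and F1 = 2 * precision *
#' sensitivity / (precision + sensitivity). Zero-denominator cases return 0
#' with a warning so degenerate predictors do not abort batch comparisons.
#' AUC is added separately via [roc_auc()] since it needs scores, not
#' counts.
#'
#' @param counts a [confusion_counts()] object.
#' @param auc optional AUC to carry in the report.
#' @return A list of class `"metrics_report"` with fields `precision`,
#'   `sensitivity`, `specificity`, `accuracy`, `f1` (and `auc` if given),
#'   all fractions in `[0, 1]`.
#' @export
compute_metrics <- function(counts, auc = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) cyst_error("all confusion counts are zero", "cystct_input_error")
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  sensitivity <- safe_ratio(counts$tp, counts$tp + counts$fn, "sensitivity")
  specificity <- safe_ratio(counts$tn, counts$tn + counts$fp, "specificity")
  accuracy <- (counts$tp + counts$tn) / total
  f1 <- f1_score(precision, sensitivity)
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, accuracy = accuracy, f1 = f1,
                 auc = auc, counts = counts),
            class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$precision, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("accuracy  %.2f%%  F1 %.2f%%", 100 * x$accuracy, 100 * x$f1))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.2f", x$auc))
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, ties counted one half — equivalently the trapezoidal
#' area under the empirical ROC. Invariant to strictly monotone transforms
#' of the scores.
#'
#' @param y_true binary labels containing both classes.
#' @param scores numeric scores, higher = more positive.
#' @param positive positive class (default `"MCN"` when present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  positive <- resolve_positive(sort(unique(y_true)), positive)
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    cyst_error("both classes must be present for AUC", "cystct_label_error")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param y_true binary labels.
#' @param scores numeric scores.
#' @param positive positive class.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  positive <- resolve_positive(sort(unique(y_true)), positive)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- y_true == positive
  out <- t(vapply(ths, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !pos) / max(sum(!pos), 1),
      tpr = sum(pred & pos) / max(sum(pos), 1))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = ths, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

#' Full metrics report from predictions
#'
#' @param y_true binary labels.
#' @param y_pred hard predictions.
#' @param scores optional positive-class scores for AUC.
#' @param positive positive class.
#' @return A `metrics_report`.
#' @export
metrics_from_predictions <- function(y_true, y_pred, scores = NULL,
                                     positive = NULL) {
  cc <- confusion_counts(y_true, y_pred, positive)
  auc <- if (!is.null(scores)) roc_auc(y_true, scores, positive)
  compute_metrics(cc, auc = auc)
}

#' Paired permutation test for an AUC difference
#'
#' Tests whether two score vectors for the same cases differ in AUC, by
#' randomly swapping the two scores within cases. A nonparametric
#' substitute for a named AUC-comparison test.
#'
#' @param y_true binary labels.
#' @param scores1,scores2 score vectors for the same cases.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param positive positive class.
#' @return List with `auc1`, `auc2`, `delta`, `p_value`.
#' @export
auc_permutation_test <- function(y_true, scores1, scores2, n_perm = 2000L,
                                 seed = 1L, positive = NULL) {
  a1 <- roc_auc(y_true, scores1, positive)
  a2 <- roc_auc(y_true, scores2, positive)
  obs <- abs(a1 - a2)
  n <- length(y_true)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      swap <- stats::runif(n) < 0.5
      s1 <- ifelse(swap, scores2, scores1)
      s2 <- ifelse(swap, scores1, scores2)
      d <- abs(roc_auc(y_true, s1, positive) - roc_auc(y_true, s2, positive))
      if (d >= obs - 1e-12) count <- count + 1L
    }
    count
  })
  list(auc1 = a1, auc2 = a2, delta = a1 - a2,
       p_value = (exceed + 1) / (n_perm + 1))
}
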