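# End-to-end experiment orchestration: data -> ROI -> preprocessing ->
# features -> classifier -> metrics, under one global seed that fans out to
# per-stage seeds. Experiments are the unit of comparison: the manual-ROI
# arm vs the multichannel arm, extractor families against each other, and
# single classifiers vs fusion, all on identical data and splits.

#' Experiment configuration
#'
#' @param data either a [phantom_params()] object (a phantom dataset is
#'   generated) or a manifest data.frame / CSV path with columns
#'   `path,mask_path,label,patient_id,slice_index`.
#' @param n_per_class,slices_per_patient phantom dataset size (ignored for
#'   manifest data). Defaults give 20 patients x 5 slices per class.
#' @param preprocessing `"multichannel"` (rectangular patch with 2-px
#'   margin, three channels) or `"manual_roi"` (outline-masked
#'   single-channel image, tight box).
#' @param extractor extractor name: one of the texture families
#'   (`"glcm"`, `"lbp"`, `"hog"`, `"gabor"`, `"wavelet"`) or `"deep"`.
#' @param extractor_params list of arguments for the extractor (for
#'   `"deep"`, arguments of [extractor_config()]).
#' @param classifier `"knn"`, `"softmax"`, `"bayes"`, `"svm"`, `"voting"`
#'   or `"mmrf"`.
#' @param classifier_params list of arguments for [base_config()] /
#'   [mmrf()].
#' @param window,canny preprocessing parameter objects.
#' @param split a [split_spec()]; its seed is overridden by the global seed
#'   derivation so paired experiments share splits.
#' @param seed global experiment seed.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(data = phantom_params(),
                              n_per_class = 20L, slices_per_patient = 5L,
                              preprocessing = c("multichannel", "manual_roi"),
                              extractor = "glcm", extractor_params = list(),
                              classifier = "svm", classifier_params = list(),
                              window = window_spec(), canny = canny_params(),
                              split = split_spec(), seed = 1L) {
  preprocessing <- match.arg(preprocessing)
  if (!(extractor %in% c(texture_extractors, "deep"))) {
    cyst_error(sprintf("unknown extractor: %s", extractor), "cystct_param_error")
  }
  if (!(classifier %in% c("knn", "softmax", "bayes", "svm", "voting", "mmrf"))) {
    cyst_error(sprintf("unknown classifier: %s", classifier), "cystct_param_error")
  }
  structure(list(data = data, n_per_class = as.integer(n_per_class),
                 slices_per_patient = as.integer(slices_per_patient),
                 preprocessing = preprocessing,
                 extractor = extractor, extractor_params = extractor_params,
                 classifier = classifier, classifier_params = classifier_params,
                 window = window, canny = canny, split = split,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load a dataset manifest
#'
#' @param path CSV path with header `path,mask_path,label,patient_id,slice_index`.
#' @return data.frame; relative image paths are resolved against the CSV's
#'   directory.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) cyst_error(sprintf("no such file: %s", path), "cystct_io_error")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "mask_path", "label", "patient_id", "slice_index")
  if (!all(need %in% names(m))) {
    cyst_error("manifest must have columns path,mask_path,label,patient_id,slice_index",
               "cystct_input_error")
  }
  base <- dirname(path)
  fix <- function(p) ifelse(nzchar(p) & !grepl("^(/|[A-Za-z]:)", p), file.path(base, p), p)
  m$path <- fix(m$path); m$mask_path <- fix(m$mask_path)
  m
}

resolve_dataset <- function(config) {
  d <- config$data
  if (inherits(d, "phantom_params")) {
    d$seed <- derive_seed(config$seed, "phantoms")
    ds <- generate_dataset(config$n_per_class, config$slices_per_patient,
                           params = d, write = FALSE)
    list(manifest = ds$manifest, samples = ds$samples)
  } else {
    m <- if (is.character(d)) load_manifest(d) else d
    list(manifest = m, samples = NULL)
  }
}

get_sample <- function(dataset, i) {
  if (!is.null(dataset$samples)) return(dataset$samples[[i]])
  row <- dataset$manifest[i, ]
  s <- read_slice(row$path, row$mask_path)
  list(image = s$image, mask = s$mask, label = row$label,
       patient_id = row$patient_id, slice_index = row$slice_index)
}

# One image -> feature vector, per the configured preprocessing + extractor.
featurize_sample <- function(sample, config, deep_fn = NULL) {
  if (config$preprocessing == "multichannel") {
    box <- expand_box(tight_bounding_box(sample$mask), 2L, dim(sample$image))
    patch <- extract_patch(sample$image, box)
    mc <- assemble_multichannel(patch, config$window, config$canny)
  } else {
    blanked <- masked_roi_image(sample$image, sample$mask,
                                fill = config$window$level - config$window$width / 2)
    box <- tight_bounding_box(sample$mask)
    patch <- extract_patch(blanked, box)
    w <- window_image(patch, config$window)
    # single-channel path: texture reads the windowed plane; the deep
    # extractor sees it replicated with empty edge/gradient channels
    mc <- structure(list(windowed = w,
                         edges = matrix(0, nrow(w), ncol(w)),
                         gradient = matrix(0, nrow(w), ncol(w))),
                    class = "multichannel_image")
  }
  if (config$extractor == "deep") {
    deep_fn(mc)
  } else {
    do.call(texture_features,
            c(list(patch = mc$windowed, method = config$extractor),
              config$extractor_params))
  }
}

featurize_dataset <- function(dataset, config, progress = FALSE) {
  n <- nrow(dataset$manifest)
  deep_fn <- NULL
  if (config$extractor == "deep") {
    ep <- config$extractor_params
    if (is.null(ep$weight_seed)) ep$weight_seed <- derive_seed(config$seed, "deep")
    deep_fn <- deep_feature_extractor(do.call(extractor_config, ep))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- featurize_sample(get_sample(dataset, i), config, deep_fn)
  }
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  X
}

fit_and_score <- function(X, y, train, test, config) {
  cls <- config$classifier
  seed <- derive_seed(config$seed, "classifier")
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  Xte <- X[test, , drop = FALSE]
  positive <- resolve_positive(levels(factor(y)))
  neg <- setdiff(levels(factor(y)), positive)
  if (cls %in% c("knn", "softmax", "bayes", "svm")) {
    cfg <- do.call(base_config, utils::modifyList(list(kind = cls, seed = seed),
                                                  config$classifier_params))
    model <- fit_base(Xtr, ytr, cfg, positive = positive)
    score <- predict_proba(model, Xte)[, positive]
    pred <- ifelse(score >= 0.5, positive, neg)
  } else if (cls == "mmrf") {
    model <- do.call(mmrf, c(list(X = Xtr, y = ytr, seed = seed,
                                  positive = positive),
                             config$classifier_params))
    score <- predict(model, Xte, type = "prob")
    pred <- as.character(predict(model, Xte, type = "class"))
  } else { # voting over the three single classifiers
    kinds <- c("knn", "softmax", "bayes")
    probs <- sapply(seq_along(kinds), function(i) {
      cfg <- base_config(kinds[i], seed = derive_seed(seed, kinds[i]))
      predict_proba(fit_base(Xtr, ytr, cfg, positive = positive), Xte)[, positive]
    })
    probs <- matrix(probs, ncol = length(kinds))
    votes <- probs >= 0.5
    pred <- ifelse(rowSums(votes) >= 2, positive, neg)
    score <- rowMeans(probs)   # mean probability scores the vote for AUC
    model <- NULL
  }
  list(model = model, pred = pred, score = score, positive = positive)
}

#' Run one end-to-end experiment
#'
#' Generates or loads the dataset, extracts features per the configured
#' preprocessing and extractor, splits (patient-level by default), trains
#' the configured classifier and evaluates the six indicators on the test
#' side. Fully deterministic given `config$seed`. When `outdir` is given,
#' writes `predictions.csv`, `metrics.json`, `roc.csv` and
#' `provenance.json`.
#'
#' @param config an [experiment_config()].
#' @param outdir optional output directory.
#' @return An object of class `"cystct_experiment"`: `metrics`
#'   (a `metrics_report`), `predictions` (data.frame), `model`, `config`,
#'   `split`.
#' @export
run_experiment <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dataset <- resolve_dataset(config)
  manifest <- dataset$manifest
  X <- featurize_dataset(dataset, config)
  y <- as.character(manifest$label)
  spl <- config$split
  spl$seed <- derive_seed(config$seed, "split")
  idx <- split_dataset(manifest, spl)
  scored <- fit_and_score(X, factor(y), idx$train, idx$test, config)
  y_test <- y[idx$test]
  metrics <- metrics_from_predictions(y_test, scored$pred, scored$score,
                                      positive = scored$positive)
  predictions <- data.frame(
    index = idx$test,
    patient_id = manifest$patient_id[idx$test],
    slice_index = manifest$slice_index[idx$test],
    truth = y_test, pred = scored$pred,
    score = round(scored$score, 10)
  )
  out <- structure(list(metrics = metrics, predictions = predictions,
                        model = scored$model, config = config, split = idx,
                        n_train = length(idx$train), n_test = length(idx$test)),
                   class = "cystct_experiment")
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

write_experiment <- function(exp, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) cyst_error(sprintf("cannot create %s", outdir), "cystct_io_error")
  utils::write.csv(exp$predictions, file.path(outdir, "predictions.csv"),
                   row.names = FALSE)
  m <- exp$metrics
  jsonlite::write_json(
    list(precision = m$precision, sensitivity = m$sensitivity,
         specificity = m$specificity, accuracy = m$accuracy, f1 = m$f1,
         auc = m$auc,
         counts = m$counts[c("tp", "fp", "tn", "fn")]),
    file.path(outdir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  rp <- roc_points(exp$predictions$truth, exp$predictions$score)
  utils::write.csv(rp, file.path(outdir, "roc.csv"), row.names = FALSE)
  cfg <- exp$config
  jsonlite::write_json(
    list(preprocessing = cfg$preprocessing, extractor = cfg$extractor,
         classifier = cfg$classifier, seed = cfg$seed,
         split = unclass(cfg$split),
         window = unclass(cfg$window), canny = unclass(cfg$canny),
         n_train = exp$n_train, n_test = exp$n_test,
         package_version = as.character(utils::packageVersion("cystct")),
         r_version = R.version.string),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
#' @method print cystct_experiment
print.cystct_experiment <- function(x, ...) {
  cat(sprintf("<cystct_experiment %s + %s + %s | train %d / test %d>\n",
              x$config$preprocessing, x$config$extractor, x$config$classifier,
              x$n_train, x$n_test))
  print(x$metrics)
  invisible(x)
}

#' Consolidated comparison table over experiments
#'
#' One row per experiment with the six indicators in the conventional
#' column order (precision, sensitivity, specificity, accuracy, F1, AUC).
#' All experiments must share the same data and split seed so the
#' comparison is paired.
#'
#' @param experiments named list of `cystct_experiment` objects (or
#'   `experiment_config`s, which are run first).
#' @return data.frame of class `"cystct_comparison"`; metrics are fractions,
#'   printed as percentages to 2 decimals (AUC to 2 decimals).
#' @export
compare_table <- function(experiments) {
  if (length(experiments) < 2) {
    cyst_error("need at least two experiments to compare", "cystct_input_error")
  }
  experiments <- lapply(experiments, function(e) {
    if (inherits(e, "experiment_config")) run_experiment(e) else e
  })
  seeds <- vapply(experiments, function(e) e$config$seed, 1L)
  if (length(unique(seeds)) != 1) {
    cyst_error("experiments must share the same seed (paired comparison)",
               "cystct_input_error")
  }
  splits <- lapply(experiments, function(e) e$split)
  if (length(unique(vapply(splits, function(s) paste(s$test, collapse = ","), ""))) != 1) {
    cyst_error("experiments must share the same split (paired comparison)",
               "cystct_input_error")
  }
  rows <- lapply(experiments, function(e) {
    m <- e$metrics
    data.frame(precision = m$precision, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               f1 = m$f1, auc = if (is.null(m$auc)) NA_real_ else m$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- if (!is.null(names(experiments))) names(experiments) else
    vapply(experiments, function(e) {
      paste(e$config$preprocessing, e$config$extractor, e$config$classifier, sep = "+")
    }, "")
  class(out) <- c("cystct_comparison", "data.frame")
  out
}

#' @export
#' @method print cystct_comparison
print.cystct_comparison <- function(x, ...) {
  disp <- data.frame(
    Precision = sprintf("%.2f%%", 100 * x$precision),
    Sensitivity = sprintf("%.2f%%", 100 * x$sensitivity),
    Specificity = sprintf("%.2f%%", 100 * x$specificity),
    Accuracy = sprintf("%.2f%%", 100 * x$accuracy),
    `F1 score` = sprintf("%.2f%%", 100 * x$f1),
    AUC = sprintf("%.2f", x$auc),
    check.names = FALSE, row.names = rownames(x)
  )
  print(disp)
  invisible(x)
}
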