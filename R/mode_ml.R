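#' Assemble a labeled mode dataset from detection summaries
#'
#' Converts detection-run summaries into the 14-feature records the mode
#' classifiers consume: flow rate (mL/min), particle size (µm), and the
#' 12-outlet particle distribution as fractions of the assigned total.
#' Zero-total summaries are excluded with a warning; a missing or invalid
#' mode label is an error.
#'
#' @param summaries List of entries, each a list with elements `summary` (a
#'   `dld_run_summary`), `flow_rate` (mL/min), `particle_size` (µm), `mode`
#'   (one of `"zigzag"`, `"mixed"`, `"bumped"`).
#' @return A `mode_dataset` (see [mode_dataset()]).
#' @export
assemble_dataset <- function(summaries) {
  rows <- list()
  for (i in seq_along(summaries)) {
    e <- summaries[[i]]
    if (is.null(e$mode) || is.na(e$mode)) {
      stop("labeling error: summary ", i, " has no mode label", call. = FALSE)
    }
    counts <- as.numeric(e$summary$channel_counts)
    if (length(counts) != 12L) {
      stop("dimension error: summary ", i, " has ", length(counts),
           " outlets; the mode features need 12", call. = FALSE)
    }
    if (sum(counts) == 0) {
      warning("summary ", i, " has zero assigned particles; excluded")
      next
    }
    rec <- data.frame(flow_rate_ml_min = e$flow_rate,
                      particle_size_um = e$particle_size)
    frac <- counts / sum(counts)
    for (k in 1:12) rec[[sprintf("outlet_%02d", k)]] <- frac[k]
    rec$mode <- e$mode
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0L) stop("empty input: no usable summaries", call. = FALSE)
  mode_dataset(do.call(rbind, rows))
}

#' Stratified k-fold splits
#'
#' Partitions the index set into `folds` test folds preserving per-class
#' proportions as closely as possible: each class's members are shuffled and
#' dealt evenly, with per-class remainders placed on the currently smallest
#' folds. Every fold serves once as the test set; per-fold class counts
#' deviate from exact proportionality by at most one record per class.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param folds Number of folds.
#' @param seed Integer seed (fixes the shuffles).
#' @return List of length `folds`; each element is
#'   `list(train_idx, test_idx)`, test sets disjoint and covering all
#'   indices.
#' @export
stratified_splits <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < folds)) {
    stop("stratification error: class '",
         names(tab)[which(tab < folds)[1]], "' has fewer than ", folds,
         " records", call. = FALSE)
  }
  set.seed(seed)
  assign_fold <- integer(n)
  totals <- integer(folds)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% folds
    extra <- length(idx) %% folds
    sizes <- rep(base, folds)
    if (extra > 0) {
      open <- seq_len(folds)
      for (e in seq_len(extra)) {
        pick <- open[order(totals[open] + sizes[open], open)][1]
        sizes[pick] <- sizes[pick] + 1L
        open <- setdiff(open, pick)
      }
    }
    pos <- 1L
    for (f in seq_len(folds)) {
      if (sizes[f] > 0L) {
        assign_fold[idx[pos:(pos + sizes[f] - 1L)]] <- f
        pos <- pos + sizes[f]
      }
    }
    totals <- totals + sizes
  }
  lapply(seq_len(folds), function(f) {
    list(train_idx = sort(which(assign_fold != f)),
         test_idx = sort(which(assign_fold == f)))
  })
}

# ---- complement naive Bayes ------------------------------------------------
# Complement NB (Rennie et al.): per class, feature weights are log
# probabilities estimated from all records NOT in the class; prediction
# takes the class whose complement matches the record least. Requires
# non-negative features, which the mode features satisfy by construction
# (positive flow rate and size, distribution fractions >= 0).

cnb_fit <- function(x, y, alpha = 1) {
  y <- as.factor(y)
  if (any(x < 0)) stop("CNB requires non-negative features", call. = FALSE)
  classes <- levels(y)
  p <- ncol(x)
  w <- matrix(0, length(classes), p,
              dimnames = list(classes, colnames(x)))
  for (ci in seq_along(classes)) {
    comp <- colSums(x[y != classes[ci], , drop = FALSE])
    theta <- (alpha + comp) / (alpha * p + sum(comp))
    w[ci, ] <- log(theta)
  }
  structure(list(weights = w, classes = classes, alpha = alpha),
            class = "cnb_model")
}

cnb_predict <- function(model, x) {
  scores <- x %*% t(model$weights)      # complement match per class
  factor(model$classes[apply(scores, 1, which.min)], levels = model$classes)
}

# ---- feature standardization (distance-based families) ---------------------

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0 | is.na(sg)] <- 1
  list(center = mu, scale = sg)
}

apply_scaler <- function(scaler, x) {
  if (is.null(scaler)) return(x)
  scale(x, center = scaler$center, scale = scaler$scale)
}

# one deterministic fit + test-accuracy evaluation for one family on one split
fit_split <- function(features, labels, split, family, k_range, svm_cost,
                      svm_gamma, seed) {
  xtr <- features[split$train_idx, , drop = FALSE]
  ytr <- labels[split$train_idx]
  xte <- features[split$test_idx, , drop = FALSE]
  yte <- labels[split$test_idx]
  if (family == "CNB") {
    fit <- cnb_fit(xtr, ytr)
    acc <- mean(cnb_predict(fit, xte) == yte)
    return(list(accuracy = acc, chosen_k = NA_integer_))
  }
  scaler <- fit_scaler(xtr)
  xtr_s <- apply_scaler(scaler, xtr)
  xte_s <- apply_scaler(scaler, xte)
  if (family == "KNN") {
    ks <- k_range[k_range <= nrow(xtr_s)]
    accs <- vapply(ks, function(k) {
      set.seed(seed + k)  # class::knn breaks ties at random
      mean(class::knn(xtr_s, xte_s, ytr, k = k) == yte)
    }, numeric(1))
    best <- max(accs)
    list(accuracy = best, chosen_k = ks[which(accs == best)[1]])
  } else {  # SVM_RBF
    fit <- e1071::svm(xtr_s, ytr, kernel = "radial", cost = svm_cost,
                      gamma = if (is.null(svm_gamma)) 1 / ncol(xtr_s) else svm_gamma)
    acc <- mean(predict(fit, xte_s) == yte)
    list(accuracy = acc, chosen_k = NA_integer_)
  }
}

#' Train a DLD separation-mode classifier
#'
#' Trains one of the three comparable classifier families — complement naive
#' Bayes (CNB), k-nearest neighbors (KNN), or a radial-basis-function
#' support vector machine (SVM-RBF) — under stratified k-fold
#' cross-validation. Each split is fitted on its training part and scored on
#' its test part; KNN additionally sweeps the neighbor count over `k_range`
#' on every split and keeps the smallest k attaining that split's maximum
#' accuracy. The model refitted on the best-accuracy split's training data
#' is what is returned (and persisted) — note this selects on test data, a
#' deliberate mirroring of the tool's protocol; all split accuracies are
#' recorded so the optimism stays visible. Ties among splits go to the
#' lowest split index.
#'
#' KNN and SVM-RBF operate on standardized features (fitted on each split's
#' training part); with 14 features mixing mL/min, µm and fractions, raw
#' distances would be scale-dominated. CNB uses the raw non-negative
#' features.
#'
#' @param dataset A `mode_dataset`.
#' @param family `"CNB"`, `"KNN"` or `"SVM_RBF"`.
#' @param folds Number of stratified folds.
#' @param seed Integer seed (splits and KNN tie-breaking).
#' @param k_range KNN neighbor counts to sweep.
#' @param svm_cost,svm_gamma SVM-RBF regularization cost and kernel width
#'   (`NULL` gamma = 1/n_features).
#' @return A `dld_mode_model`: `family`, `fit`, `scaler`, `chosen_k` (KNN),
#'   `split_accuracies`, `best_split`, `best_split_accuracy`,
#'   `split_chosen_k`, `seed`, `classes`.
#' @export
train_mode_model <- function(dataset, family = c("CNB", "KNN", "SVM_RBF"),
                             folds = 5L, seed = 1L, k_range = 2:55,
                             svm_cost = 1, svm_gamma = NULL) {
  stopifnot(inherits(dataset, "mode_dataset"))
  family <- match.arg(family)
  features <- dataset$features
  labels <- dataset$labels
  splits <- stratified_splits(labels, folds = folds, seed = seed)
  res <- lapply(splits, fit_split, features = features, labels = labels,
                family = family, k_range = k_range, svm_cost = svm_cost,
                svm_gamma = svm_gamma, seed = seed)
  accs <- vapply(res, `[[`, numeric(1), "accuracy")
  ks <- vapply(res, `[[`, integer(1), "chosen_k")
  best <- which.max(accs)  # tie -> lowest split index
  tr <- splits[[best]]$train_idx
  xtr <- features[tr, , drop = FALSE]
  ytr <- labels[tr]
  chosen_k <- ks[best]
  scaler <- NULL
  if (family == "CNB") {
    fit <- cnb_fit(xtr, ytr)
  } else {
    scaler <- fit_scaler(xtr)
    xtr_s <- apply_scaler(scaler, xtr)
    if (family == "KNN") {
      fit <- list(train = xtr_s, labels = ytr)  # KNN is lazy: store the split
    } else {
      fit <- e1071::svm(xtr_s, ytr, kernel = "radial", cost = svm_cost,
                        gamma = if (is.null(svm_gamma)) 1 / ncol(xtr_s) else svm_gamma)
    }
  }
  structure(list(family = family, fit = fit, scaler = scaler,
                 chosen_k = chosen_k, split_accuracies = accs,
                 best_split = best, best_split_accuracy = accs[best],
                 split_chosen_k = ks, seed = seed,
                 classes = levels(labels)),
            class = "dld_mode_model")
}

#' @export
print.dld_mode_model <- function(x, ...) {
  cat(sprintf("dld_mode_model [%s]: split accuracies %s; best split %d (%.1f%%)%s\n",
              x$family,
              paste(sprintf("%.3f", x$split_accuracies), collapse = ", "),
              x$best_split, 100 * x$best_split_accuracy,
              if (!is.na(x$chosen_k)) sprintf("; k = %d", x$chosen_k) else ""))
  invisible(x)
}

#' Predict modes for a feature matrix
#'
#' @param object A `dld_mode_model`.
#' @param newdata Numeric matrix, one row per record, 14 columns.
#' @param ... Unused.
#' @return Factor of predicted modes.
#' @export
predict.dld_mode_model <- function(object, newdata, ...) {
  if (ncol(newdata) != 14L) {
    stop("dimension error: expected 14 feature columns, got ", ncol(newdata),
         call. = FALSE)
  }
  switch(object$family,
    CNB = cnb_predict(object$fit, newdata),
    KNN = {
      xs <- apply_scaler(object$scaler, newdata)
      set.seed(object$seed)
      class::knn(object$fit$train, xs, object$fit$labels, k = object$chosen_k)
    },
    SVM_RBF = {
      xs <- apply_scaler(object$scaler, newdata)
      p <- predict(object$fit, xs)
      factor(as.character(p), levels = object$classes)
    })
}

#' Predict the DLD mode of a single run
#'
#' @param model A `dld_mode_model`.
#' @param flow_rate Flow rate, mL/min.
#' @param particle_size Nominal particle diameter, µm.
#' @param distribution 12 per-outlet values (counts or fractions; normalized
#'   to fractions internally).
#' @return One of `"zigzag"`, `"mixed"`, `"bumped"`.
#' @export
predict_mode <- function(model, flow_rate, particle_size, distribution) {
  if (length(distribution) != 12L) {
    stop("dimension error: distribution must have 12 outlet values",
         call. = FALSE)
  }
  s <- sum(distribution)
  if (s > 0) distribution <- distribution / s
  x <- matrix(c(flow_rate, particle_size, distribution), nrow = 1)
  colnames(x) <- c("flow_rate_ml_min", "particle_size_um",
                   sprintf("outlet_%02d", 1:12))
  as.character(predict(model, x))
}

#' Evaluate a mode model on labeled records
#'
#' Produces the standard evaluation report: a confusion matrix (rows = true
#' mode, columns = predicted) and per-class precision, recall and f1-score
#' plus overall accuracy.
#'
#' @param model A `dld_mode_model`.
#' @param features Numeric matrix (n x 14).
#' @param labels True modes (factor or character).
#' @return A `mode_evaluation`: `confusion`, `report` (data frame with
#'   `precision`, `recall`, `f1`, `support` per class), `accuracy`.
#' @export
evaluate_mode_model <- function(model, features, labels) {
  if (length(labels) == 0L || anyNA(labels)) {
    stop("labeling error: evaluation needs labeled test records",
         call. = FALSE)
  }
  truth <- factor(labels, levels = model$classes)
  if (anyNA(truth)) {
    stop("labeling error: unknown mode label in test records", call. = FALSE)
  }
  pred <- factor(predict(model, features), levels = model$classes)
  confusion <- table(true = truth, predicted = pred)
  prec <- rec <- f1 <- numeric(length(model$classes))
  for (i in seq_along(model$classes)) {
    tp <- confusion[i, i]
    prec[i] <- if (sum(confusion[, i]) > 0) tp / sum(confusion[, i]) else 0
    rec[i] <- if (sum(confusion[i, ]) > 0) tp / sum(confusion[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  structure(list(
    confusion = confusion,
    report = data.frame(mode = model$classes, precision = prec, recall = rec,
                        f1 = f1, support = as.integer(rowSums(confusion))),
    accuracy = mean(pred == truth)), class = "mode_evaluation")
}

#' @export
print.mode_evaluation <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("\nclassification report:\n")
  rep <- x$report
  rep$precision <- sprintf("%.3f", rep$precision)
  rep$recall <- sprintf("%.3f", rep$recall)
  rep$f1 <- sprintf("%.3f", rep$f1)
  print(rep, row.names = FALSE)
  cat(sprintf("\naccuracy: %.3f\n", x$accuracy))
  invisible(x)
}

#' Persist a mode model
#'
#' Writes the model as an RDS artifact plus a JSON metadata sidecar
#' (`<path>.json`) recording the family, seed, split accuracies and chosen
#' k, so a saved model's provenance is inspectable without loading it.
#'
#' @param model A `dld_mode_model`.
#' @param path Output file path (e.g. `model_cnb.rds`).
#' @return Invisibly, `path`.
#' @export
save_mode_model <- function(model, path) {
  stopifnot(inherits(model, "dld_mode_model"))
  saveRDS(model, path)
  jsonlite::write_json(list(
    family = model$family, seed = model$seed,
    split_accuracies = model$split_accuracies,
    best_split = model$best_split, chosen_k = model$chosen_k,
    classes = model$classes),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a persisted mode model
#'
#' @param path Path given to [save_mode_model()].
#' @return A `dld_mode_model`.
#' @export
load_mode_model <- function(path) {
  if (!file.exists(path)) stop("I/O error: no model at ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "dld_mode_model")) {
    stop("integrity error: ", path, " is not a mode model", call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!identical(meta$family, model$family)) {
      stop("integrity error: sidecar family '", meta$family,
           "' does not match model family '", model$family, "'",
           call. = FALSE)
    }
  }
  model
}

#' Write a mode dataset to CSV
#'
#' @param dataset A `mode_dataset`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_mode_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mode_dataset"))
  write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mode dataset from CSV
#'
#' Expects the columns `flow_rate_ml_min`, `particle_size_um`,
#' `outlet_01`..`outlet_12`, `mode`.
#'
#' @param path CSV path.
#' @return A `mode_dataset`.
#' @export
read_mode_dataset <- function(path) {
  if (!file.exists(path)) stop("I/O error: no dataset at ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: dataset has no records", call. = FALSE)
  bad <- which(is.na(df$flow_rate_ml_min) | is.na(df$particle_size_um))
  if (length(bad)) {
    stop("parse error: malformed record at row ", bad[1], call. = FALSE)
  }
  mode_dataset(df)
}
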