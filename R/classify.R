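# ---------------------------------------------------------------------------
# Class-weighted RBF-SVM training with exhaustive hyperparameter search and
# the three evaluation regimes (subject-specific CV, leave-one-subject-out,
# generic-from-simulation).  The error condition is the positive class
# throughout.  All randomness (fold splits, downsampling) is consumed from
# the global RNG stream; seed with set.seed() for reproducibility.
# ---------------------------------------------------------------------------

#' Hyperparameter search grid
#'
#' The full grid is cost 10^-6..10^6 (13 values) by gamma 10^-5..10^5
#' (11 values), searched exhaustively (143 pairs).
#' @param cost_exponents,gamma_exponents powers of ten.
#' @return list of class `svm_grid`.
#' @export
svm_grid <- function(cost_exponents = -6:6, gamma_exponents = -5:5) {
  structure(list(cost_values = 10^cost_exponents,
                 gamma_values = 10^gamma_exponents), class = "svm_grid")
}

#' Reduced desk-scale grid (7 x 6)
#'
#' Centered decades of the full grid for faster exhaustive search.
#' @export
reduced_svm_grid <- function() svm_grid(-3:3, -4:1)

#' Evaluation configuration
#'
#' @param n_folds outer stratified folds.
#' @param n_repeats cross-validation repeats.
#' @param grid an [svm_grid()].
#' @param inner_folds stratified folds of the inner model-selection CV.
#' @param channels,windows feature extraction settings
#'   (see [window_mean_features()]).
#' @param max_train_trials cap on the balanced pooled training set used by
#'   the LOSO and generic regimes (`Inf` = no cap); subsampling is
#'   class-balanced.
#' @return list of class `eval_config`.
#' @export
eval_config <- function(n_folds = 10, n_repeats = 10, grid = svm_grid(),
                        inner_folds = 5,
                        channels = default_feature_channels(),
                        windows = default_feature_windows(),
                        max_train_trials = Inf) {
  structure(list(n_folds = n_folds, n_repeats = n_repeats, grid = grid,
                 inner_folds = inner_folds, channels = channels,
                 windows = windows, max_train_trials = max_train_trials),
            class = "eval_config")
}

#' Randomly downsample the majority class to balance
#'
#' The minority class is kept entirely; a uniformly random subset of the
#' majority class of equal size is kept.
#' @param labels factor with both classes present.
#' @return integer vector of kept trial indices (sorted).
#' @export
downsample_majority <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0) || length(tab) < 2)
    stop("both classes must be present for downsampling", call. = FALSE)
  n_min <- min(tab)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  sort(keep)
}

#' Stratified fold assignment
#'
#' Within each class, shuffled indices are dealt round-robin over `k` folds,
#' guaranteeing every fold contains both classes when counts allow.
#' @param labels factor.
#' @param k number of folds.
#' @return integer vector of fold ids (1..k) per trial.
#' @export
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(factor(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k && cl == "error")
      stop(sprintf(
        "only %d '%s' trials for %d folds; use fewer folds",
        length(idx), cl, k), call. = FALSE)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# inverse class-frequency weights of the (pre-downsampling) labels,
# normalized so the smaller class has weight >= 1
.class_weights <- function(labels) {
  tab <- table(labels)
  w <- as.numeric(max(tab) / tab)
  names(w) <- names(tab)
  w
}

.fit_svm <- function(x, y, cost, gamma, class_weights) {
  e1071::svm(x = x, y = y, kernel = "radial", cost = cost, gamma = gamma,
             class.weights = class_weights, scale = FALSE)
}

#' Exhaustive grid-search training of the class-weighted RBF SVM
#'
#' Every (cost, gamma) pair of the grid is scored by inner stratified
#' cross-validation on the training data: inside each inner training fold the
#' majority class is downsampled and the feature normalizer fit, then the
#' model is tested on the untouched (imbalanced) inner fold; the pair
#' maximizing mean balanced accuracy wins (ties: smallest cost, then smallest
#' gamma).  The final model is refit on the full downsampled training set.
#' Class weights are inverse class frequencies of the pre-downsampling
#' training labels.
#'
#' @param values trials x features matrix (unnormalized).
#' @param labels factor (`error`/`correct`), both classes present.
#' @param grid an [svm_grid()].
#' @param inner_folds number of inner folds.
#' @param class_weights optional named weights (computed from `labels` if
#'   omitted -- supply the pre-downsampling weights when `values` is already
#'   balanced).
#' @param provenance free-form list recorded in the model.
#' @return object of class `errp_model`: fields `fit`, `cost`, `gamma`,
#'   `class_weights`, `normalizer`, `grid_scores`, `train_idx` (indices used
#'   for the final fit), `provenance`.
#' @export
grid_search_train <- function(values, labels, grid = svm_grid(),
                              inner_folds = 5, class_weights = NULL,
                              provenance = list()) {
  labels <- factor(as.character(labels), levels = c("error", "correct"))
  if (min(table(labels)) < 2)
    stop("need at least 2 trials per class", call. = FALSE)
  if (is.null(class_weights)) class_weights <- .class_weights(labels)
  k <- min(inner_folds, min(table(labels)))
  fold <- stratified_folds(labels, k)
  splits <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f)
    ds <- tr[downsample_majority(labels[tr])]
    nz <- suppressWarnings(fit_normalizer(values[ds, , drop = FALSE]))
    list(test = which(fold == f), ds = ds, nz = nz)
  })
  best <- list(bacc = -Inf)
  scores <- expand.grid(cost = grid$cost_values, gamma = grid$gamma_values,
                        bacc = NA_real_)
  scores <- scores[order(scores$cost, scores$gamma), ]
  for (i in seq_len(nrow(scores))) {
    cost <- scores$cost[i]; gamma <- scores$gamma[i]
    baccs <- vapply(splits, function(sp) {
      xtr <- apply_normalizer(values[sp$ds, , drop = FALSE], sp$nz)
      fit <- .fit_svm(xtr, droplevels(labels[sp$ds]), cost, gamma,
                      class_weights[levels(droplevels(labels[sp$ds]))])
      xte <- apply_normalizer(values[sp$test, , drop = FALSE], sp$nz)
      pred <- stats::predict(fit, xte)
      balanced_accuracy(labels[sp$test], pred)$bacc
    }, numeric(1))
    scores$bacc[i] <- mean(baccs)
    if (scores$bacc[i] > best$bacc + 1e-12)
      best <- list(bacc = scores$bacc[i], cost = cost, gamma = gamma)
  }
  ds <- downsample_majority(labels)
  nz <- suppressWarnings(fit_normalizer(values[ds, , drop = FALSE]))
  xtr <- apply_normalizer(values[ds, , drop = FALSE], nz)
  fit <- .fit_svm(xtr, droplevels(labels[ds]), best$cost, best$gamma,
                  class_weights)
  structure(list(fit = fit, cost = best$cost, gamma = best$gamma,
                 class_weights = class_weights, normalizer = nz,
                 grid_scores = scores, train_idx = ds,
                 provenance = provenance), class = "errp_model")
}

#' @export
print.errp_model <- function(x, ...) {
  cat(sprintf("<errp_model> RBF SVM, cost %g, gamma %g, %d training trials\n",
              x$cost, x$gamma, length(x$train_idx)))
  invisible(x)
}

#' Predict condition labels with a trained model
#'
#' Applies the frozen normalizer and decision function; no adaptation.
#' @param object an `errp_model`.
#' @param newdata feature matrix (trials x features), unnormalized, or a
#'   `feature_matrix`.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.errp_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  z <- apply_normalizer(x, object$normalizer)
  p <- stats::predict(object$fit, z)
  factor(as.character(p), levels = c("error", "correct"))
}

.as_features <- function(x, cfg) {
  if (inherits(x, "epochs_data"))
    window_mean_features(x, cfg$channels, cfg$windows)
  else x
}

#' Subject-specific repeated stratified cross-validation
#'
#' `n_repeats` times stratified `n_folds`-fold CV: inside each outer training
#' portion the hyperparameters are grid-searched (inner CV with fold-internal
#' downsampling and normalization), the final fold model is fit on the
#' downsampled training portion, and metrics are computed on the untouched
#' imbalanced test fold.  Reported as the overall mean.
#'
#' @param subject an [epochs_data()] or `feature_matrix`.
#' @param cfg an [eval_config()].
#' @return list of class `cv_result`: `folds` (data.frame with per-repeat,
#'   per-fold TPR/TNR/bACC and chosen cost/gamma), `fold_detail` (per-fold
#'   train/test index provenance), `mean_tpr`, `mean_tnr`, `mean_bacc`,
#'   `chosen` (most frequently selected pair).
#' @export
evaluate_subject_specific <- function(subject, cfg = eval_config()) {
  fm <- .as_features(subject, cfg)
  labels <- fm$labels
  rows <- list(); detail <- list()
  for (rep_i in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(labels, cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      model <- grid_search_train(fm$values[tr, , drop = FALSE], labels[tr],
                                 grid = cfg$grid,
                                 inner_folds = cfg$inner_folds)
      pred <- predict(model, fm$values[te, , drop = FALSE])
      m <- balanced_accuracy(labels[te], pred)
      rows[[length(rows) + 1]] <- data.frame(
        repeat_i = rep_i, fold = f, tpr = m$tpr, tnr = m$tnr, bacc = m$bacc,
        cost = model$cost, gamma = model$gamma)
      detail[[length(detail) + 1]] <- list(
        repeat_i = rep_i, fold = f, test_idx = te,
        fit_idx = tr[model$train_idx],
        normalizer_mean = model$normalizer$mean)
    }
  }
  folds <- do.call(rbind, rows)
  chosen <- folds[which.max(stats::ave(seq_len(nrow(folds)),
                                       folds$cost, folds$gamma,
                                       FUN = length)), c("cost", "gamma")]
  structure(list(folds = folds, fold_detail = detail,
                 mean_tpr = mean(folds$tpr), mean_tnr = mean(folds$tnr),
                 mean_bacc = mean(folds$bacc), chosen = chosen,
                 subject_id = fm$subject_id), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> subject '%s': bACC %.3f (TPR %.3f, TNR %.3f) over %d folds\n",
    x$subject_id, x$mean_bacc, x$mean_tpr, x$mean_tnr, nrow(x$folds)))
  invisible(x)
}

# pool feature matrices of several subjects
.pool_features <- function(subjects, cfg) {
  fms <- lapply(subjects, .as_features, cfg = cfg)
  list(values = do.call(rbind, lapply(fms, `[[`, "values")),
       labels = factor(unlist(lapply(fms, function(f) as.character(f$labels))),
                       levels = c("error", "correct")),
       subject_ids = vapply(fms, `[[`, "", "subject_id"))
}

# balance by downsampling, then (optionally) subsample the balanced pool,
# preserving balance; returns indices into the pooled rows
.balanced_pool_idx <- function(labels, max_train_trials) {
  ds <- downsample_majority(labels)
  if (is.finite(max_train_trials) && length(ds) > max_train_trials) {
    per_class <- floor(max_train_trials / 2)
    ds <- unlist(lapply(levels(labels), function(cl) {
      idx <- ds[labels[ds] == cl]
      sort(sample(idx, min(per_class, length(idx))))
    }))
    ds <- sort(ds)
  }
  ds
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject the remaining subjects are pooled, the majority
#' class downsampled (optionally capped, class-balanced), the normalizer and
#' grid-searched model fit on that pool, and metrics computed on the full
#' held-out subject.
#' @param subjects list of [epochs_data()] (or `feature_matrix`) objects.
#' @param cfg an [eval_config()].
#' @return list of class `loso_result` with `per_subject` data.frame
#'   (subject, TPR, TNR, bACC, cost, gamma) and the means.
#' @export
evaluate_loso <- function(subjects, cfg = eval_config()) {
  stopifnot(length(subjects) >= 2)
  rows <- list()
  for (i in seq_along(subjects)) {
    pool <- .pool_features(subjects[-i], cfg)
    w <- .class_weights(pool$labels)
    keep <- .balanced_pool_idx(pool$labels, cfg$max_train_trials)
    model <- grid_search_train(pool$values[keep, , drop = FALSE],
                               pool$labels[keep], grid = cfg$grid,
                               inner_folds = cfg$inner_folds,
                               class_weights = w,
                               provenance = list(held_out = i))
    fm <- .as_features(subjects[[i]], cfg)
    m <- balanced_accuracy(fm$labels, predict(model, fm$values))
    rows[[i]] <- data.frame(subject = fm$subject_id, tpr = m$tpr,
                            tnr = m$tnr, bacc = m$bacc, cost = model$cost,
                            gamma = model$gamma)
  }
  per_subject <- do.call(rbind, rows)
  structure(list(per_subject = per_subject,
                 mean_tpr = mean(per_subject$tpr),
                 mean_tnr = mean(per_subject$tnr),
                 mean_bacc = mean(per_subject$bacc)), class = "loso_result")
}

#' Train the generic (simulation-pooled) classifier
#'
#' Pools all training subjects' features, downsamples the majority class
#' (optionally capped), grid-searches once and freezes model plus
#' normalizer; subsequent application performs no adaptation.
#' @param subjects list of training [epochs_data()] (or `feature_matrix`).
#' @param cfg an [eval_config()].
#' @return an `errp_model` whose provenance lists the training subject ids.
#' @export
train_generic <- function(subjects, cfg = eval_config()) {
  stopifnot(length(subjects) >= 1)
  pool <- .pool_features(subjects, cfg)
  w <- .class_weights(pool$labels)
  keep <- .balanced_pool_idx(pool$labels, cfg$max_train_trials)
  grid_search_train(pool$values[keep, , drop = FALSE], pool$labels[keep],
                    grid = cfg$grid, inner_folds = cfg$inner_folds,
                    class_weights = w,
                    provenance = list(training_subjects = pool$subject_ids))
}

#' Apply a frozen model to one subject
#'
#' @param model an `errp_model`.
#' @param subject an [epochs_data()] or `feature_matrix`.
#' @param cfg an [eval_config()] (feature settings).
#' @return list with `tpr`, `tnr`, `bacc`, `pred`.
#' @export
apply_model <- function(model, subject, cfg = eval_config()) {
  fm <- .as_features(subject, cfg)
  pred <- predict(model, fm$values)
  c(balanced_accuracy(fm$labels, pred), list(pred = pred))
}
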