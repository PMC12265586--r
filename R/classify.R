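# deterministic stratified fold assignment
make_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < folds)) {
    rlang::abort(sprintf(
      "every class needs >= %d members for %d-fold CV (smallest has %d)",
      folds, folds, min(tab)))
  }
  assignment <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

# ridge logistic regression fit + class prediction for one CV fold;
# features standardized on the training fold only (constant features -> 0);
# if nothing varies, fall back to the training majority class
fit_predict_fold <- function(x_train, y_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) < 2L) {
    # glmnet needs >= 2 columns; pad or fall back to majority vote
    if (length(keep) == 0L) {
      maj <- names(which.max(table(y_train)))
      return(factor(rep(maj, nrow(x_test)), levels = levels(y_train)))
    }
    keep <- c(keep, keep)
  }
  zs <- function(x) {
    scale(x[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  }
  family <- if (nlevels(y_train) > 2L) "multinomial" else "binomial"
  fit <- glmnet::glmnet(zs(x_train), y_train, family = family, alpha = 0,
                        lambda = 1 / nrow(x_train), standardize = FALSE)
  pred <- stats::predict(fit, newx = zs(x_test), type = "class")
  factor(as.vector(pred), levels = levels(y_train))
}

run_cv <- function(features, labels, assignment, folds, seed, feature_mode) {
  per_fold <- vapply(seq_len(folds), function(f) {
    test <- assignment == f
    pred <- fit_predict_fold(features[!test, , drop = FALSE], labels[!test],
                             features[test, , drop = FALSE])
    mean(pred != labels[test])
  }, numeric(1))
  structure(
    list(n_items = length(labels), n_classes = nlevels(labels),
         per_fold_misclassification = per_fold,
         mean_misclassification = mean(per_fold),
         feature_mode = feature_mode, folds = folds, seed = seed),
    class = "classification_report"
  )
}

#' Cross-validated structural classification from feature vectors
#'
#' Fits an L2-regularized (ridge) logistic regression — one-vs-rest for more
#' than two classes — under stratified k-fold cross-validation and reports
#' the misclassification rate: the fraction of items assigned an incorrect
#' structural class. Features are standardized to zero mean / unit variance
#' per feature, fit on the training folds only. Fold splits and fits are
#' fully deterministic given the seed.
#'
#' @param features Numeric matrix (or data frame) of equal-length feature
#'   vectors, one row per item.
#' @param labels Class labels (>= 2 classes, each with >= `folds` members).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold split.
#' @return A `classification_report`: per-fold and mean misclassification.
#' @export
run_classification <- function(features, labels, folds = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) {
    rlang::abort("labels must match feature rows")
  }
  if (nlevels(labels) < 2L) rlang::abort("need >= 2 classes")
  assignment <- make_folds(labels, folds, seed)
  run_cv(features, labels, assignment, folds, seed, NA_character_)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report>%s %d items, %d classes, %d-fold CV: mean misclassification %.3f\n",
    if (is.na(x$feature_mode)) "" else paste0(" [", x$feature_mode, "]"),
    x$n_items, x$n_classes, x$folds, x$mean_misclassification))
  invisible(x)
}

#' @rdname run_classification
#' @param x A `classification_report`.
#' @param ... Unused.
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$per_fold_misclassification),
                 misclassification = x$per_fold_misclassification,
                 feature_mode = x$feature_mode)
}

#' @rdname run_classification
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(n_items = x$n_items, n_classes = x$n_classes,
                 folds = x$folds,
                 mean_misclassification = x$mean_misclassification,
                 feature_mode = x$feature_mode, seed = x$seed)
}

#' Compare static and dynamic PSN features on the same pathways
#'
#' The head-to-head experiment behind dynamic protein structure networks:
#' every pathway is modelled both as a static PSN (its final — native —
#' snapshot, static graphlet frequencies) and as a dynamic PSN (all
#' snapshots, binned graphlet frequencies plus arrival histogram, see
#' [dynamic_features()]); both feature sets are classified with identical
#' stratified fold splits and seed, so any accuracy difference is
#' attributable to the dynamic information alone. A paired sign test across
#' folds accompanies the two reports.
#'
#' @param data Tibble with `pathway` (list-column) and `label` columns, as
#'   returned by [make_classification_dataset()]; alternatively a list of
#'   pathways passed with `labels`.
#' @param labels Class labels (when `data` is a bare list of pathways).
#' @param params A [psn_params()] contact rule.
#' @param folds,seed Cross-validation setup, shared by both feature modes.
#' @param n_bins Time bins for [dynamic_features()].
#' @return A `feature_mode_comparison`: `static` and `dynamic`
#'   classification reports plus `p_value` (paired sign test across folds).
#' @export
compare_feature_modes <- function(data, labels = NULL,
                                  params = psn_params(), folds = 5L,
                                  seed = 1L, n_bins = 10L) {
  if (is.data.frame(data)) {
    pathways <- data$pathway
    labels <- data$label
  } else {
    pathways <- data
  }
  if (is.null(labels)) rlang::abort("labels are required")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) rlang::abort("need >= 2 classes")
  dpsns <- lapply(pathways, build_dynamic_psn, params = params)
  static_x <- do.call(rbind, lapply(dpsns, function(d) {
    static_features(d$snapshots[[length(d$snapshots)]])
  }))
  dynamic_x <- do.call(rbind, lapply(dpsns, dynamic_features,
                                     n_bins = n_bins))
  assignment <- make_folds(labels, folds, seed)
  static_rep <- run_cv(static_x, labels, assignment, folds, seed, "static")
  dynamic_rep <- run_cv(dynamic_x, labels, assignment, folds, seed,
                        "dynamic")
  diff <- dynamic_rep$per_fold_misclassification -
    static_rep$per_fold_misclassification
  nz <- sum(diff != 0)
  p <- if (nz == 0) 1 else
    stats::binom.test(sum(diff < 0), nz)$p.value
  structure(list(static = static_rep, dynamic = dynamic_rep, p_value = p),
            class = "feature_mode_comparison")
}

#' @export
print.feature_mode_comparison <- function(x, ...) {
  cat(sprintf(
    "<feature_mode_comparison> static %.3f vs dynamic %.3f mean misclassification (sign test p = %.3g)\n",
    x$static$mean_misclassification, x$dynamic$mean_misclassification,
    x$p_value))
  invisible(x)
}

#' @rdname compare_feature_modes
#' @param x A `feature_mode_comparison`.
#' @param ... Unused.
#' @export
tidy.feature_mode_comparison <- function(x, ...) {
  dplyr::bind_rows(tidy(x$static), tidy(x$dynamic))
}

#' @rdname compare_feature_modes
#' @export
glance.feature_mode_comparison <- function(x, ...) {
  tibble::tibble(
    static_misclassification = x$static$mean_misclassification,
    dynamic_misclassification = x$dynamic$mean_misclassification,
    p_value = x$p_value,
    folds = x$static$folds, n_items = x$static$n_items
  )
}
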