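#' Train a per-component linear classifier
#'
#' Fits a binary classifier on one spatial component's feature vectors.
#' `kind = "svm"` fits a linear soft-margin support-vector machine at the
#' given cost and reduces it to its hyperplane form `g(x) = w.x + w0`;
#' `kind = "naive_bayes"` fits per-feature Gaussian class-conditionals with
#' pooled (class-shared) variances, which likewise reduces to a linear
#' decision rule. Either way prediction is the deterministic sign of `g`,
#' with `g = 0` mapped to +1 (the disease class).
#'
#' @param features List (or list-column) of equal-length numeric vectors,
#'   one per training subject, or an n x S numeric matrix.
#' @param labels Integer vector of class labels in `{-1, +1}` (+1 = AD).
#' @param kind `"svm"` or `"naive_bayes"`.
#' @param cost Positive soft-margin cost (SVM only).
#' @param region_id Optional region id stored on the classifier.
#' @return An object of class `sc_classifier` with elements `weights`
#'   (length S), `threshold` (`w0`), `kind`, `cost`, `region_id`.
#' @export
train_classifier <- function(features, labels, kind = c("svm", "naive_bayes"),
                             cost = 1, region_id = NA_integer_) {
  kind <- match.arg(kind)
  x <- as_feature_matrix(features)
  y <- as.integer(labels)
  check_binary_pm1(y, "training labels")
  if (nrow(x) != length(y)) abort("features and labels differ in length")
  if (length(unique(y)) < 2L) {
    abort("degenerate training set: only one class present")
  }
  if (kind == "svm") {
    if (cost <= 0) abort("cost must be positive")
    fit <- e1071::svm(x, factor(y, levels = c(-1L, 1L)), kernel = "linear",
                      cost = cost, scale = FALSE, tolerance = 1e-4)
    w <- drop(t(fit$coefs) %*% fit$SV)
    w0 <- -fit$rho
    # libsvm orients its decision values by order of label appearance;
    # re-orient so that positive g(x) means class +1.
    pred <- as.integer(as.character(predict(fit, x)))
    d <- drop(x %*% w) + w0
    off <- d != 0
    if (any(off) && mean(sign(d[off]) == pred[off]) < 0.5) {
      w <- -w
      w0 <- -w0
    }
  } else {
    mu_pos <- colMeans(x[y == 1L, , drop = FALSE])
    mu_neg <- colMeans(x[y == -1L, , drop = FALSE])
    # pooled within-class variance per feature, floored to avoid blow-up
    # on constant voxels
    ss <- colSums(sweep(x[y == 1L, , drop = FALSE], 2, mu_pos)^2) +
      colSums(sweep(x[y == -1L, , drop = FALSE], 2, mu_neg)^2)
    v <- pmax(ss / nrow(x), 1e-9)
    w <- (mu_pos - mu_neg) / v
    w0 <- sum((mu_neg^2 - mu_pos^2) / (2 * v)) + log(mean(y == 1L) / mean(y == -1L))
  }
  structure(
    list(kind = kind, weights = as.numeric(w), threshold = as.numeric(w0),
         cost = if (kind == "svm") cost else NA_real_,
         region_id = as.integer(region_id)),
    class = "sc_classifier"
  )
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  s <- unique(lengths(features))
  if (length(s) != 1L) abort("feature vectors have unequal lengths")
  do.call(rbind, lapply(features, as.numeric))
}

#' @export
print.sc_classifier <- function(x, ...) {
  cat(sprintf("<sc_classifier> %s, S = %d, region %s\n", x$kind,
              length(x$weights), x$region_id))
  invisible(x)
}

#' Predict binary component outcomes
#'
#' Applies the linear decision rule `sign(w.x + w0)` to new feature vectors,
#' mapping an exact zero to +1.
#'
#' @param object An `sc_classifier`.
#' @param features A numeric vector, a list of vectors, or an n x S matrix.
#' @param ... Unused.
#' @return Integer vector of outcomes in `{-1, +1}`.
#' @export
predict.sc_classifier <- function(object, features, ...) {
  if (is.numeric(features) && !is.matrix(features)) {
    features <- matrix(features, nrow = 1L)
  }
  x <- as_feature_matrix(features)
  if (ncol(x) != length(object$weights)) {
    abort(sprintf("feature length %d does not match classifier length %d",
                  ncol(x), length(object$weights)))
  }
  g <- drop(x %*% object$weights) + object$threshold
  ifelse(g >= 0, 1L, -1L)
}

#' Leave-one-out component outcomes
#'
#' For every subject and every component, predicts the subject's binary
#' outcome from a classifier trained on all remaining subjects (honest
#' held-out votes). These outcome vectors are what the Bayesian network is
#' learned from.
#'
#' @param features Long feature table from [decompose_cohort()]: columns
#'   `subject_id`, `region_id`, `label`, `feature` (list-column).
#' @param kind,cost Passed to [train_classifier()].
#' @return A list with `outcomes` (tibble: `subject_id`, `y`, one
#'   `z_<region_id>` column per component) and `component_accuracy`
#'   (tibble: `region_id`, `accuracy`).
#' @export
loocv_outcomes <- function(features, kind = c("svm", "naive_bayes"), cost = 1) {
  kind <- match.arg(kind)
  subjects <- unique(features$subject_id)
  n <- length(subjects)
  if (n < 3L) abort("leave-one-out requires at least 3 subjects")
  by_region <- split(features, features$region_id)
  region_ids <- as.integer(names(by_region))

  z_cols <- lapply(by_region, function(tab) {
    tab <- tab[match(subjects, tab$subject_id), ]
    x <- as_feature_matrix(tab$feature)
    y <- label_to_y(tab$label)
    if (anyNA(y)) abort("leave-one-out requires labeled (NC/AD) subjects only")
    vapply(seq_len(n), function(i) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2L) {
        abort(sprintf("fold leaving out %s has a single-class training set",
                      subjects[i]))
      }
      clf <- train_classifier(x[-i, , drop = FALSE], ytr, kind = kind,
                              cost = cost)
      predict(clf, x[i, ])
    }, integer(1))
  })

  first <- by_region[[1]][match(subjects, by_region[[1]]$subject_id), ]
  y <- label_to_y(first$label)
  outcomes <- tibble::tibble(subject_id = subjects, y = y)
  for (k in seq_along(region_ids)) outcomes[[zcol(region_ids[k])]] <- z_cols[[k]]

  acc <- tibble::tibble(
    region_id = region_ids,
    accuracy = unname(vapply(z_cols, function(z) mean(z == y), numeric(1)))
  )
  list(outcomes = outcomes, component_accuracy = acc)
}

#' Train one classifier per component on a full cohort
#'
#' @inheritParams loocv_outcomes
#' @return Named list of `sc_classifier` objects keyed by region id.
#' @export
train_component_classifiers <- function(features, kind = c("svm", "naive_bayes"),
                                        cost = 1) {
  kind <- match.arg(kind)
  by_region <- split(features, features$region_id)
  lapply(by_region, function(tab) {
    train_classifier(as_feature_matrix(tab$feature), label_to_y(tab$label),
                     kind = kind, cost = cost,
                     region_id = tab$region_id[1])
  })
}

#' Apply trained component classifiers to a cohort
#'
#' @param classifiers Named list from [train_component_classifiers()].
#' @param features Long feature table (as in [loocv_outcomes()]); labels may
#'   be missing or MCI converters.
#' @return Outcome tibble: `subject_id`, `y` (`NA` where unlabeled),
#'   `z_<region_id>` columns.
#' @export
predict_outcomes <- function(classifiers, features) {
  subjects <- unique(features$subject_id)
  by_region <- split(features, features$region_id)
  region_ids <- as.integer(names(by_region))
  stopifnot(all(as.character(region_ids) %in% names(classifiers) |
                  all(region_ids %in% vapply(classifiers, `[[`, integer(1), "region_id"))))
  first <- by_region[[1]][match(subjects, by_region[[1]]$subject_id), ]
  out <- tibble::tibble(subject_id = subjects, y = label_to_y(first$label))
  for (k in seq_along(region_ids)) {
    tab <- by_region[[k]][match(subjects, by_region[[k]]$subject_id), ]
    clf <- classifiers[[as.character(region_ids[k])]] %||%
      classifiers[[which(vapply(classifiers, `[[`, integer(1), "region_id") == region_ids[k])]]
    out[[zcol(region_ids[k])]] <- predict(clf, as_feature_matrix(tab$feature))
  }
  out
}
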