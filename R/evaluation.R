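#' Stratified hold-out split
#'
#' Randomly holds out a fraction of the labeled NC/AD cohort for validation,
#' stratified by class so the validation set preserves the class balance.
#' MCI-converter subjects never enter training: they are routed entirely to
#' validation, where they are scored against the AD-trained model.
#'
#' @param subjects Tibble with at least `subject_id` and `label`
#'   (`NC` / `AD` / `MCI_C`), e.g. a manifest.
#' @param validation_fraction Fraction of each labeled class held out
#'   (default 1/3).
#' @param seed Integer seed for reproducibility.
#' @return Object of class `sc_split`: tibbles `train` and `validation`,
#'   plus the fraction and seed.
#' @export
split_subjects <- function(subjects, validation_fraction = 1 / 3, seed = NULL) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("validation_fraction must lie in (0, 1)")
  }
  subjects <- tibble::as_tibble(subjects)
  y <- label_to_y(subjects$label)
  if (!any(y == 1L, na.rm = TRUE) || !any(y == -1L, na.rm = TRUE)) {
    abort("both NC and AD subjects are required for a split")
  }
  if (!is.null(seed)) set.seed(seed)
  val_idx <- integer(0)
  for (cls in c(-1L, 1L)) {
    idx <- which(!is.na(y) & y == cls)
    n_val <- round(length(idx) * validation_fraction)
    n_val <- min(max(n_val, 1L), length(idx) - 1L)
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- c(val_idx, which(is.na(y)))  # MCI converters: validation only
  structure(
    list(train = subjects[-sort(val_idx), , drop = FALSE],
         validation = subjects[sort(val_idx), , drop = FALSE],
         validation_fraction = validation_fraction, seed = seed),
    class = "sc_split"
  )
}

#' @export
print.sc_split <- function(x, ...) {
  cat(sprintf("<sc_split> %d train / %d validation (fraction %.3f)\n",
              nrow(x$train), nrow(x$validation), x$validation_fraction))
  invisible(x)
}

#' Classification performance from predictions and truth
#'
#' Counts true/false positives and negatives with AD (+1) as the positive
#' class and reports accuracy `(Tp + Tn) / (Tp + Tn + Fp + Fn)`, sensitivity
#' `Tp / (Tp + Fn)` and specificity `Tn / (Tn + Fp)`. If the truth contains
#' no positives (or no negatives) the undefined ratio is returned as `NA`
#' with a warning.
#'
#' @param predictions Integer vector of predicted labels in `{-1, +1}`.
#' @param truth Integer vector of true labels in `{-1, +1}`.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) != length(truth)) {
    abort("predictions and truth differ in length")
  }
  if (length(truth) == 0L) abort("nothing to evaluate")
  check_binary_pm1(predictions, "predictions")
  check_binary_pm1(truth, "truth")
  tp <- sum(predictions == 1L & truth == 1L)
  tn <- sum(predictions == -1L & truth == -1L)
  fp <- sum(predictions == 1L & truth == -1L)
  fn <- sum(predictions == -1L & truth == 1L)
  sens <- if (tp + fn == 0L) { warn("no positive subjects: sensitivity undefined"); NA_real_ } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) { warn("no negative subjects: specificity undefined"); NA_real_ } else tn / (tn + fp)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec
  )
}

#' Run the full spatial-component pipeline
#'
#' End-to-end orchestration on an in-memory dataset: stratified hold-out
#' split; per-component leave-one-out outcomes on the training cohort;
#' Bayesian-network structure search and CPT fit on those held-out outcome
#' vectors; final per-component classifiers trained on the whole training
#' cohort; validation inference with both aggregators (network posterior and
#' majority voting) on two contrasts — AD vs NC, and MCI-converters vs the
#' same NC validation subjects.
#'
#' @param dataset List with `subjects` (tibble: `subject_id`, `label`, and a
#'   list-column of 3-D arrays named by tissue, e.g. `gm`) and `atlas`
#'   (an [atlas_parcellation()]), as produced by [simulate_subjects()].
#' @param tissue Which tissue's volumes to use (default `"gm"`).
#' @param region_ids Atlas regions to use as components (default: all).
#' @param kind,cost Component classifier settings ([train_classifier()]).
#' @param smoothing CPT pseudo-count ([fit_bn()]).
#' @param n_iter,burn_in,max_parents Structure-search settings
#'   ([mh_structure_search()]).
#' @param validation_fraction,seed Split settings ([split_subjects()]). The
#'   seed also drives the structure search.
#' @return Object of class `sc_pipeline`: `reports` (tibble: contrast,
#'   aggregator, counts and the three ratios), `network` (fitted `sc_bn`),
#'   `search` (`sc_bn_search`), `train_outcomes`, `validation_outcomes`,
#'   `component_accuracy`, `split`, and the settings used.
#' @export
run_pipeline <- function(dataset, tissue = "gm",
                         region_ids = dataset$atlas$region_table$region_id,
                         kind = "svm", cost = 1, smoothing = 1,
                         n_iter = 20000L, burn_in = 2000L, max_parents = 3L,
                         validation_fraction = 1 / 3, seed = 1L) {
  subjects <- tibble::as_tibble(dataset$subjects)
  atlas <- dataset$atlas
  stopifnot(tissue %in% names(subjects))

  sp <- split_subjects(subjects, validation_fraction = validation_fraction,
                       seed = substream_seed(seed, 1L))
  leaked <- intersect(sp$train$subject_id, sp$validation$subject_id)
  if (length(leaked) > 0L) abort("split leaked subjects between train and validation")

  as_images <- function(rows) {
    purrr::pmap(list(rows[[tissue]], rows$subject_id, rows$label),
                function(arr, id, lab) {
                  tissue_image(arr, subject_id = id, tissue = toupper(tissue),
                               label = lab,
                               voxel_size_mm = atlas$voxel_size_mm)
                })
  }

  train_feats <- decompose_cohort(as_images(sp$train), atlas, region_ids)
  cv <- loocv_outcomes(train_feats, kind = kind, cost = cost)

  search <- mh_structure_search(cv$outcomes, n_iter = n_iter,
                                burn_in = burn_in,
                                seed = substream_seed(seed, 2L),
                                max_parents = max_parents)
  net <- fit_bn(search$best_structure, cv$outcomes, smoothing = smoothing)

  final_clf <- train_component_classifiers(train_feats, kind = kind, cost = cost)
  val_feats <- decompose_cohort(as_images(sp$validation), atlas, region_ids)
  val_out <- predict_outcomes(final_clf, val_feats)
  val_out <- predict(net, vote(val_out))

  is_mci <- is.na(val_out$y)
  reports <- list()
  contrasts <- list(
    ad_vs_nc = list(rows = !is_mci, truth = val_out$y[!is_mci]),
    mci_vs_nc = if (any(is_mci)) {
      rows <- is_mci | (!is_mci & val_out$y == -1L)
      list(rows = rows, truth = ifelse(is.na(val_out$y[rows]), 1L, val_out$y[rows]))
    }
  )
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (is.null(ct)) next
    for (agg in c("bayes_net", "voting")) {
      pred <- if (agg == "bayes_net") val_out$bn_label[ct$rows] else val_out$vote_label[ct$rows]
      reports[[paste(nm, agg)]] <- dplyr::mutate(
        evaluate_predictions(pred, ct$truth),
        contrast = nm, aggregator = agg, .before = 1)
    }
  }

  structure(
    list(reports = purrr::list_rbind(reports),
         network = net, search = search,
         train_outcomes = cv$outcomes, validation_outcomes = val_out,
         component_accuracy = cv$component_accuracy, split = sp,
         settings = list(tissue = tissue, region_ids = region_ids, kind = kind,
                         cost = cost, smoothing = smoothing, n_iter = n_iter,
                         burn_in = burn_in, max_parents = max_parents,
                         validation_fraction = validation_fraction,
                         seed = seed)),
    class = "sc_pipeline"
  )
}

#' @export
print.sc_pipeline <- function(x, ...) {
  cat("<sc_pipeline>\n")
  print(as.data.frame(x$reports), row.names = FALSE)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `sc_pipeline`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.sc_pipeline <- function(x, ...) x$reports

#' @rdname run_pipeline
#' @exportS3Method generics::glance
#' @export
glance.sc_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_train = nrow(x$split$train),
                   n_validation = nrow(x$split$validation)),
    glance(x$search)
  )
}

#' Plot per-component accuracies and validation performance
#'
#' @param object An `sc_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sc_pipeline <- function(object, ...) {
  long <- tidyr::pivot_longer(object$reports,
                              c("accuracy", "sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$aggregator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "rate", title = "Validation performance")
}
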