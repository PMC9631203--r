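# Step 3: evaluate a gene subset with ten classifier families under
# stratified k-fold cross-validation. Accuracy, recall, precision, and F1
# come from the pooled out-of-fold predictions (one confusion matrix per
# model); AUC is reported as the per-fold mean +/- SD, matching the common
# "0.87 +/- 0.11" presentation.

#' Binary classification metrics from predicted labels
#'
#' Positive class is 1 (ruptured). `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)` (0 when no positive predictions, with a
#' warning), F1 their harmonic mean (0 when both are 0).
#'
#' @param y_true,y_pred Equal-length 0/1 vectors; `y_true` must contain both
#'   classes.
#' @return List with `accuracy`, `recall`, `precision`, `f1`, and
#'   `confusion` — a 2x2 integer matrix, rows = true 0/1, columns =
#'   predicted 0/1, summing to `length(y_true)`.
#' @examples
#' m <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' m$confusion
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  check_two_classes(y_true, "y_true")
  cm <- matrix(0L, 2, 2, dimnames = list(true = c("0", "1"),
                                         predicted = c("0", "1")))
  for (t in 0:1) for (p in 0:1) {
    cm[t + 1, p + 1] <- sum(y_true == t & y_pred == p)
  }
  tp <- cm["1", "1"]; fp <- cm["0", "1"]
  fn <- cm["1", "0"]; tn <- cm["0", "0"]
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions; precision set to 0", call. = FALSE)
    0
  } else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (tp + tn) / length(y_true),
       recall = recall, precision = precision, f1 = f1, confusion = cm)
}

fold_auc <- function(y_true, score) {
  if (length(unique(y_true)) < 2) return(NA_real_)
  as.numeric(pROC::auc(response = y_true, predictor = score,
                       levels = c("0", "1"), direction = "<", quiet = TRUE))
}

#' Stratified cross-validation of one classifier family
#'
#' Folds are stratified on the label with shuffling from `seed`; every
#' sample is predicted exactly once. Per-fold ROC AUC is computed from the
#' held-out scores.
#'
#' @param data Expression tibble or numeric matrix.
#' @param model One of `benchmark_model_names()`:
#'   xgboost, lightgbm, random_forest, extra_trees, gaussian_nb, knn,
#'   logistic_regression, decision_tree, svm, lda.
#' @param labels Binary labels (from the `label` column when `NULL`).
#' @param genes Optional gene subset.
#' @param k Folds (default 10); every class needs at least `k` members.
#' @param seed Fold-shuffle and model-fit seed.
#' @param params Hyperparameters; defaults from [benchmark_models()].
#' @return List: `predictions` (tibble `row`, `fold`, `y_true`, `y_score`,
#'   `y_pred`, in sample order) and `fold_auc` (numeric length `k`).
#' @export
cross_validate <- function(data, model, labels = NULL, genes = NULL,
                           k = 10, seed = 1, params = NULL) {
  if (!model %in% benchmark_model_names()) {
    stop("unknown model name: ", model, call. = FALSE)
  }
  y <- expr_labels(data, labels)
  check_two_classes(y)
  x <- expr_matrix(data, genes)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  params <- params %||% benchmark_models()[[model]]
  folds <- stratified_folds(y, k, derive_seed(seed, "folds"))
  score <- numeric(length(y))
  pred <- integer(length(y))
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    out <- fit_and_score(model, x[!te, , drop = FALSE], y[!te],
                         x[te, , drop = FALSE], params,
                         seed = derive_seed(seed, paste0(model, f)))
    score[te] <- out$score
    pred[te] <- out$label
    aucs[f] <- fold_auc(y[te], out$score)
  }
  list(predictions = tibble::tibble(row = seq_along(y), fold = folds,
                                    y_true = y, y_score = score, y_pred = pred),
       fold_auc = aucs)
}

#' Benchmark a gene subset across all ten classifier families
#'
#' Runs [cross_validate()] for every family on the same stratified folds,
#' then summarizes: accuracy / recall / precision / F1 from pooled
#' out-of-fold predictions, AUC as per-fold mean and SD, plus a pooled 2x2
#' confusion matrix per model and an arithmetic mean row over models.
#'
#' @param data Expression tibble or matrix.
#' @param labels Binary labels (from the `label` column when `NULL`).
#' @param subset `"all"` or a character vector of gene ids (also accepts a
#'   `fcbf_candidates` tibble or `pso_selection`).
#' @param k Folds (default 10).
#' @param seed Master seed for folds and model fits.
#' @param models Model names to run (default all ten).
#' @return A `benchmark_report`: list with `report` (tibble `model`,
#'   `accuracy`, `recall`, `precision`, `f1`, `auc_mean`, `auc_sd`,
#'   including a final `Mean` row), `confusion` (named list of 2x2
#'   matrices), `k`, `seed`, `subset`.
#' @export
benchmark_suite <- function(data, labels = NULL, subset = "all", k = 10,
                            seed = 1, models = benchmark_model_names()) {
  if (inherits(subset, "pso_selection")) subset <- subset$selected_genes
  if (is.data.frame(subset)) subset <- subset$gene_id
  y <- expr_labels(data, labels)
  genes <- if (identical(subset, "all")) NULL else as.character(subset)
  bad <- setdiff(models, benchmark_model_names())
  if (length(bad) > 0) stop("unknown model name: ", bad[1], call. = FALSE)
  all_params <- benchmark_models()

  rows <- vector("list", length(models))
  confusion <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    cv <- cross_validate(data, m, labels = y, genes = genes, k = k,
                         seed = seed, params = all_params[[m]])
    met <- compute_metrics(cv$predictions$y_true, cv$predictions$y_pred)
    confusion[[m]] <- met$confusion
    rows[[i]] <- tibble::tibble(
      model = m, accuracy = met$accuracy, recall = met$recall,
      precision = met$precision, f1 = met$f1,
      auc_mean = mean(cv$fold_auc, na.rm = TRUE),
      auc_sd = sd(cv$fold_auc, na.rm = TRUE)
    )
  }
  report <- dplyr::bind_rows(rows)
  mean_row <- report |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
    dplyr::mutate(model = "Mean", .before = 1)
  structure(list(report = dplyr::bind_rows(report, mean_row),
                 confusion = confusion, k = k, seed = seed,
                 subset = if (is.null(genes)) "all" else genes),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  ng <- if (identical(x$subset, "all")) "all genes" else {
    paste0(length(x$subset), " genes")
  }
  cat("<benchmark_report> ", x$k, "-fold CV on ", ng, "\n", sep = "")
  print(as.data.frame(x$report |>
                        dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                                    \(v) round(v, 3)))),
        row.names = FALSE)
  invisible(x)
}

#' Tidy per-model benchmark metrics
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per model family (the `Mean` row excluded);
#'   `glance()`: the mean-over-models row.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  dplyr::filter(x$report, .data$model != "Mean")
}

#' @rdname tidy.benchmark_report
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  dplyr::filter(x$report, .data$model == "Mean") |>
    dplyr::select(-"model")
}

#' Plot benchmark metrics by model family
#'
#' @param object A `benchmark_report`.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot bar chart, models ordered by accuracy.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object,
                                      metrics = c("accuracy", "auc_mean", "f1"),
                                      ...) {
  df <- tidy(object) |>
    dplyr::mutate(model = stats::reorder(.data$model, .data$accuracy)) |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cross-validated value", fill = NULL,
                  title = "Classifier benchmark") +
    ggplot2::theme_minimal()
}

#' Write a benchmark report and its confusion matrices to TSV
#'
#' `benchmark_report.tsv` (one row per model plus the Mean row) and one
#' `confusion_<model>.tsv` per family (2x2, rows true 0/1, columns
#' predicted 0/1).
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix (e.g. `"allgenes_"`).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(report, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- report$report |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                \(v) sprintf("%.10g", v)))
  readr::write_tsv(out, file.path(dir, paste0(prefix, "benchmark_report.tsv")))
  for (m in names(report$confusion)) {
    cm <- report$confusion[[m]]
    df <- tibble::tibble(true = rownames(cm),
                         predicted_0 = cm[, "0"], predicted_1 = cm[, "1"])
    readr::write_tsv(df, file.path(dir, paste0(prefix, "confusion_", m, ".tsv")))
  }
  invisible(dir)
}
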