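# End-to-end orchestration: load data, FCBF filter, MLP-PSO wrapper, and
# the before/after classifier benchmark. A single master seed fans out to
# stage seeds via derive_seed(), so each stage is individually reproducible.

#' Load an expression matrix and label file into one dataset
#'
#' The matrix TSV/CSV has a header row of gene identifiers and a first
#' `sample_id` column (samples as rows; use `genes_as_rows = TRUE` for the
#' transposed layout). The labels file has columns `sample_id` and `label`
#' (1 = ruptured, 0 = unruptured). Samples are inner-joined on `sample_id`;
#' a partial overlap is kept with a warning, an empty overlap is an error.
#'
#' @param matrix_path Path to the expression table (TSV, or CSV by
#'   extension).
#' @param labels_path Path to the label table.
#' @param genes_as_rows Set `TRUE` when the matrix file is genes x samples.
#' @return An expression tibble: `sample_id`, `label`, gene columns, in
#'   file order.
#' @export
load_dataset <- function(matrix_path, labels_path, genes_as_rows = FALSE) {
  read_fun <- function(p) {
    if (grepl("\\.csv$", p, ignore.case = TRUE)) {
      readr::read_csv(p, show_col_types = FALSE)
    } else {
      readr::read_tsv(p, show_col_types = FALSE)
    }
  }
  mat <- read_fun(matrix_path)
  if (genes_as_rows) {
    gene_ids <- mat[[1]]
    m <- t(as.matrix(mat[, -1]))
    mat <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                            tibble::as_tibble(m, .name_repair = "minimal"))
    names(mat)[-1] <- gene_ids
  }
  names(mat)[1] <- "sample_id"
  mat$sample_id <- as.character(mat$sample_id)
  if (anyDuplicated(mat$sample_id)) {
    stop("duplicate sample ids in matrix file", call. = FALSE)
  }
  if (anyDuplicated(names(mat)[-1])) {
    stop("duplicate gene ids in matrix file", call. = FALSE)
  }
  num <- vapply(mat[-1], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric expression column: ", names(mat)[-1][!num][1], call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- names(mat)[-1][colSums(is.na(mat[-1])) > 0][1]
    stop("missing values in gene '", bad, "'", call. = FALSE)
  }

  lab <- read_fun(labels_path)
  names(lab)[1:2] <- c("sample_id", "label")
  lab$sample_id <- as.character(lab$sample_id)
  bad <- !lab$label %in% c(0, 1)
  if (any(bad)) {
    stop("non-binary label for sample '", lab$sample_id[bad][1],
         "': ", lab$label[bad][1], call. = FALSE)
  }

  shared <- intersect(mat$sample_id, lab$sample_id)
  if (length(shared) == 0) {
    stop("matrix and labels share no sample ids", call. = FALSE)
  }
  dropped <- length(unique(c(mat$sample_id, lab$sample_id))) - length(shared)
  if (dropped > 0) {
    warning(dropped, " sample(s) outside the matrix/labels intersection ",
            "were dropped; ", length(shared), " retained", call. = FALSE)
  }
  out <- mat |>
    dplyr::inner_join(lab[, c("sample_id", "label")], by = "sample_id") |>
    dplyr::relocate("label", .after = "sample_id")
  out$label <- as.integer(out$label)
  out
}

#' Pipeline run configuration
#'
#' One master `seed` fans out deterministically to the discretization-free
#' FCBF stage, the swarm, and the benchmark (see [derive_seed()]).
#'
#' @param delta FCBF relevance threshold (default 0).
#' @param discretization `"mdl"`, `"equal_frequency"`, or `"equal_width"`.
#' @param n_bins Bin count for the unsupervised discretizers.
#' @param swarm A [swarm_config()]; its seed is overridden by the master seed.
#' @param mlp An [mlp_config()].
#' @param eval An [eval_config()].
#' @param benchmark_k Folds of the final benchmark (default 10).
#' @param protocol `"paper"` (select on the full dataset, then
#'   cross-validate on the same samples — replicates the common, optimistic
#'   protocol) or `"nested"` (selection re-run inside each outer training
#'   fold; leakage-free).
#' @param seed Master seed.
#' @return A list of class `run_config`, serializable to YAML via
#'   [write_run_config()].
#' @export
run_config <- function(delta = 0, discretization = "mdl", n_bins = 10,
                       swarm = swarm_config(), mlp = mlp_config(),
                       eval = eval_config(), benchmark_k = 10,
                       protocol = c("paper", "nested"), seed = 42) {
  protocol <- match.arg(protocol)
  structure(list(delta = delta, discretization = discretization,
                 n_bins = n_bins, swarm = swarm, mlp = mlp, eval = eval,
                 benchmark_k = as.integer(benchmark_k),
                 protocol = protocol, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips all fields of [run_config()].
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- list(delta = config$delta, discretization = config$discretization,
               n_bins = config$n_bins,
               swarm = unclass(config$swarm), mlp = unclass(config$mlp),
               eval = unclass(config$eval),
               benchmark_k = config$benchmark_k,
               protocol = config$protocol, seed = config$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  f <- yaml::read_yaml(path)
  run_config(delta = f$delta, discretization = f$discretization,
             n_bins = f$n_bins,
             swarm = do.call(swarm_config, f$swarm),
             mlp = do.call(mlp_config, f$mlp),
             eval = do.call(eval_config, f$eval),
             benchmark_k = f$benchmark_k, protocol = f$protocol,
             seed = f$seed)
}

select_genes_once <- function(data, config, seed) {
  labels <- expr_labels(data, NULL)
  candidates <- fcbf(data, labels, delta = config$delta,
                     method = config$discretization, n_bins = config$n_bins)
  if (nrow(candidates) == 0) {
    stop("FCBF returned no candidates; lower delta or use a coarser ",
         "discretization", call. = FALSE)
  }
  swarm <- config$swarm
  swarm$seed <- derive_seed(seed, "pso")
  selection <- pso_search(data, candidates, labels, cfg = swarm,
                          mlp = config$mlp, eval = config$eval)
  list(candidates = candidates, selection = selection)
}

#' Run the full two-stage hybrid selection and benchmark
#'
#' Stage 1 (FCBF) ranks genes by symmetrical uncertainty with the class and
#' removes predominated (redundant) genes; Stage 2 (MLP-PSO) searches
#' subsets of the candidates by cross-validated perceptron fitness; Stage 3
#' benchmarks all genes versus the selected subset with ten classifier
#' families under stratified k-fold cross-validation.
#'
#' Under `protocol = "nested"`, selection is instead repeated inside each
#' outer training fold and metrics come from the outer test folds only,
#' removing the selection-on-test-data leakage of the `"paper"` protocol.
#'
#' @param data Expression tibble (see [load_dataset()] /
#'   [synth_expression()]).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all artifact files are
#'   written: `candidates_ranked.tsv`, `selected_genes.txt`,
#'   `fitness_history.tsv`, `benchmark_report.tsv` +
#'   `confusion_<model>.tsv` (selected subset),
#'   `allgenes_benchmark_report.tsv` (+ confusions), `run_manifest.json`.
#' @return A `hybrid_run`: `candidates`, `selection` (a `pso_selection`),
#'   `benchmark_before`, `benchmark_after`, `config`. Nested protocol adds
#'   `fold_selections` and replaces the after-report with outer-fold
#'   estimates.
#' @export
run_hybrid <- function(data, config = run_config(), out_dir = NULL) {
  labels <- expr_labels(data, NULL)
  check_two_classes(labels)
  seed <- config$seed
  bench_seed <- derive_seed(seed, "benchmark")

  if (config$protocol == "paper") {
    sel <- select_genes_once(data, config, seed)
    before <- benchmark_suite(data, labels, subset = "all",
                              k = config$benchmark_k, seed = bench_seed)
    after <- benchmark_suite(data, labels, subset = sel$selection,
                             k = config$benchmark_k, seed = bench_seed)
    run <- structure(list(candidates = sel$candidates,
                          selection = sel$selection,
                          benchmark_before = before,
                          benchmark_after = after,
                          config = config),
                     class = "hybrid_run")
  } else {
    run <- run_nested(data, labels, config, seed, bench_seed)
  }

  if (!is.null(out_dir)) write_run(run, out_dir, data)
  run
}

# Leakage-free protocol: outer stratified CV; FCBF + PSO re-run on each
# outer training fold; the ten models are fit on the fold's selected genes
# and scored on the held-out fold.
run_nested <- function(data, labels, config, seed, bench_seed) {
  k <- config$benchmark_k
  x_all <- expr_matrix(data)
  folds <- stratified_folds(labels, k, derive_seed(bench_seed, "outer"))
  models <- benchmark_model_names()
  all_params <- benchmark_models()

  fold_sel <- vector("list", k)
  score <- matrix(0, length(labels), length(models),
                  dimnames = list(NULL, models))
  pred <- matrix(0L, length(labels), length(models),
                 dimnames = list(NULL, models))
  for (f in seq_len(k)) {
    te <- folds == f
    train <- data[!te, , drop = FALSE]
    sel <- select_genes_once(train, config, derive_seed(seed, paste0("fold", f)))
    genes <- sel$selection$selected_genes
    fold_sel[[f]] <- genes
    for (m in models) {
      out <- fit_and_score(m, x_all[!te, genes, drop = FALSE], labels[!te],
                           x_all[te, genes, drop = FALSE], all_params[[m]],
                           seed = derive_seed(bench_seed, paste0(m, f)))
      score[te, m] <- out$score
      pred[te, m] <- out$label
    }
  }

  rows <- vector("list", length(models))
  confusion <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    met <- compute_metrics(labels, pred[, m])
    confusion[[m]] <- met$confusion
    aucs <- vapply(seq_len(k), function(f) {
      fold_auc(labels[folds == f], score[folds == f, m])
    }, numeric(1))
    rows[[i]] <- tibble::tibble(model = m, accuracy = met$accuracy,
                                recall = met$recall, precision = met$precision,
                                f1 = met$f1,
                                auc_mean = mean(aucs, na.rm = TRUE),
                                auc_sd = sd(aucs, na.rm = TRUE))
  }
  report <- dplyr::bind_rows(rows)
  mean_row <- report |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
    dplyr::mutate(model = "Mean", .before = 1)
  after <- structure(list(report = dplyr::bind_rows(report, mean_row),
                          confusion = confusion, k = k, seed = bench_seed,
                          subset = "nested"),
                     class = "benchmark_report")

  # consensus selection (reported, not used for metrics): selection on all data
  sel_full <- select_genes_once(data, config, seed)
  before <- benchmark_suite(data, labels, subset = "all", k = k,
                            seed = bench_seed)
  structure(list(candidates = sel_full$candidates,
                 selection = sel_full$selection,
                 benchmark_before = before,
                 benchmark_after = after,
                 fold_selections = fold_sel,
                 config = config),
            class = "hybrid_run")
}

#' @export
print.hybrid_run <- function(x, ...) {
  n_genes <- length(x$selection$candidates)
  cat("<hybrid_run> protocol = ", x$config$protocol, "\n", sep = "")
  cat("  candidates (FCBF): ", nrow(x$candidates), " genes\n", sep = "")
  cat("  selected (MLP-PSO): ", length(x$selection$selected_genes),
      " genes\n", sep = "")
  before <- glance(x$benchmark_before)
  after <- glance(x$benchmark_after)
  cat(sprintf("  mean CV accuracy: %.3f (all genes) -> %.3f (selected)\n",
              before$accuracy, after$accuracy))
  cat(sprintf("  mean CV AUC:      %.3f (all genes) -> %.3f (selected)\n",
              before$auc_mean, after$auc_mean))
  invisible(x)
}

#' Write every artifact of a pipeline run
#'
#' @param run A `hybrid_run`.
#' @param dir Output directory.
#' @param data The dataset the run was computed from (recorded in the
#'   manifest as dimensions and a numeric checksum).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, data = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_candidates(run$candidates, file.path(dir, "candidates_ranked.tsv"))
  write_selection(run$selection, dir)
  write_benchmark(run$benchmark_after, dir)
  write_benchmark(run$benchmark_before, dir, prefix = "allgenes_")
  manifest <- list(
    package_version = as.character(utils::packageVersion("genesift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    protocol = run$config$protocol,
    seed = run$config$seed,
    stage_seeds = list(pso = derive_seed(run$config$seed, "pso"),
                       benchmark = derive_seed(run$config$seed, "benchmark")),
    delta = run$config$delta,
    discretization = run$config$discretization,
    swarm = unclass(run$config$swarm),
    mlp = unclass(run$config$mlp),
    eval = unclass(run$config$eval),
    benchmark_k = run$config$benchmark_k,
    n_candidates = nrow(run$candidates),
    n_selected = length(run$selection$selected_genes)
  )
  if (!is.null(data)) {
    x <- expr_matrix(data)
    manifest$input <- list(n_samples = nrow(x), n_genes = ncol(x),
                           checksum = signif(sum(x) + sum(x^2), 12))
  }
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
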