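# Shared helpers: expression-tibble accessors, seed fan-out, stratified folds.

# An "expression tibble" is samples x genes with a `sample_id` character
# column, a `label` column over {0, 1}, and one numeric column per gene.
RESERVED_COLS <- c("sample_id", "label")

expr_gene_ids <- function(data) setdiff(names(data), RESERVED_COLS)

expr_matrix <- function(data, genes = NULL) {
  if (is.matrix(data)) {
    if (!is.null(genes)) data <- data[, genes, drop = FALSE]
    return(data)
  }
  genes <- genes %||% expr_gene_ids(data)
  missing <- setdiff(genes, names(data))
  if (length(missing) > 0) {
    stop("genes not present in data: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(data[, genes, drop = FALSE])
  if (!is.numeric(x)) stop("expression columns must be numeric", call. = FALSE)
  if ("sample_id" %in% names(data)) rownames(x) <- data$sample_id
  x
}

expr_labels <- function(data, labels = NULL) {
  if (is.null(labels)) {
    if (is.data.frame(data) && "label" %in% names(data)) {
      labels <- data$label
    } else {
      stop("no `labels` supplied and no `label` column in data", call. = FALSE)
    }
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 (1 = ruptured, 0 = unruptured)", call. = FALSE)
  }
  labels
}

check_two_classes <- function(y, what = "labels") {
  if (length(unique(y)) < 2) {
    stop(what, " contain a single class; both classes are required", call. = FALSE)
  }
  invisible(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' All stage randomness (swarm initialization, fold shuffles, model fits,
#' synthetic generation) fans out from one master seed through this hash so
#' stages are individually reproducible. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stage Character tag naming the consumer (e.g. `"pso"`, `"benchmark"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp)) * 131
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Stratified k-fold assignment: within each class, shuffle then deal
# round-robin, so fold class counts differ by at most one.
stratified_folds <- function(y, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  counts <- table(y)
  if (any(counts < k)) {
    stop("class with fewer than k = ", k,
         " members; use a smaller number of folds", call. = FALSE)
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in names(counts)) {
      idx <- which(y == as.integer(cls))
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Deterministic per-subset seed used for wrapper fitness evaluation so a
# subset's fitness is stable within a run regardless of when it is visited.
mask_seed <- function(base_seed, mask) {
  idx <- which(mask)
  h <- sum(idx * 2654435761) %% 2147483647
  as.integer((base_seed + h) %% 2147483647)
}
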