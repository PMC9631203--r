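# Synthetic expression data with planted structure. Emulates a
# differential-expression-filtered matrix on a log2-like scale: a small set
# of class-informative genes, noisy near-copies of them (redundant), and
# many label-independent noise genes. Ground-truth roles are attached so
# filter and wrapper behavior can be scored exactly.

#' Generate a labeled expression matrix with planted gene roles
#'
#' Class sizes default to 48 positive (ruptured, label 1) and 40 negative
#' (unruptured, label 0). Informative genes are Gaussian within class with
#' class means separated by `effect_size` (sign drawn at random per gene) on
#' a log2-like scale; the default 0.585 = log2(1.5) mirrors a 1.5-fold
#' differential-expression screen. Each redundant gene is a randomly chosen
#' informative gene plus N(0, `redundancy_noise_sd`) perturbation; noise
#' genes are N(0, `noise_sd`) independent of the label. Identical seeds give
#' bit-identical output.
#'
#' @param n_pos,n_neg Samples per class (labels 1 and 0).
#' @param n_informative,n_redundant,n_noise Gene counts per role.
#' @param effect_size Between-class mean difference for informative genes.
#' @param noise_sd Within-class standard deviation (all genes).
#' @param redundancy_noise_sd Perturbation SD for redundant copies.
#' @param seed Integer seed.
#' @return An expression tibble (`sample_id`, `label`, gene columns) with a
#'   `roles` attribute; see [gene_roles()]. Gene ids encode their role
#'   (`INF*`, `RED*`, `NOI*`).
#' @examples
#' d <- synth_expression(n_pos = 10, n_neg = 10, n_informative = 2,
#'                       n_redundant = 1, n_noise = 5, seed = 1)
#' dim(d)
#' gene_roles(d)
#' @export
synth_expression <- function(n_pos = 48, n_neg = 40,
                             n_informative = 5, n_redundant = 10,
                             n_noise = 600,
                             effect_size = 0.585, noise_sd = 1,
                             redundancy_noise_sd = 0.1, seed = 1) {
  stopifnot(n_pos >= 2, n_neg >= 2, n_informative >= 0, n_redundant >= 0,
            n_noise >= 0, noise_sd > 0, redundancy_noise_sd >= 0)
  if (n_informative + n_redundant + n_noise < 1) {
    stop("at least one gene must be requested", call. = FALSE)
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant genes require at least one informative gene", call. = FALSE)
  }
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))

  withr::with_seed(seed, {
    inf <- NULL
    if (n_informative > 0) {
      signs <- sample(c(-1, 1), n_informative, replace = TRUE)
      inf <- vapply(seq_len(n_informative), function(j) {
        mu <- ifelse(labels == 1, signs[j] * effect_size, 0)
        rnorm(n, mean = mu, sd = noise_sd)
      }, numeric(n))
      colnames(inf) <- sprintf("INF%02d", seq_len(n_informative))
    }
    red <- NULL
    if (n_redundant > 0) {
      parents <- sample.int(n_informative, n_redundant, replace = TRUE)
      red <- vapply(seq_len(n_redundant), function(j) {
        inf[, parents[j]] + rnorm(n, 0, redundancy_noise_sd)
      }, numeric(n))
      colnames(red) <- sprintf("RED%02d_INF%02d", seq_len(n_redundant), parents)
    }
    noi <- NULL
    if (n_noise > 0) {
      noi <- matrix(rnorm(n * n_noise, 0, noise_sd), n, n_noise)
      colnames(noi) <- sprintf("NOI%03d", seq_len(n_noise))
    }
    x <- do.call(cbind, Filter(Negate(is.null), list(inf, red, noi)))

    roles <- tibble::tibble(
      gene_id = colnames(x),
      role = rep(c("informative", "redundant", "noise"),
                 c(n_informative, n_redundant, n_noise)),
      parent = c(rep(NA_character_, n_informative),
                 if (n_redundant > 0) sprintf("INF%02d", parents) else character(0),
                 rep(NA_character_, n_noise))
    )

    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels),
      tibble::as_tibble(x)
    )
    attr(out, "roles") <- roles
    attr(out, "synth_spec") <- list(
      n_pos = n_pos, n_neg = n_neg, n_informative = n_informative,
      n_redundant = n_redundant, n_noise = n_noise,
      effect_size = effect_size, noise_sd = noise_sd,
      redundancy_noise_sd = redundancy_noise_sd, seed = seed
    )
    out
  })
}

#' Ground-truth gene roles of a synthetic dataset
#'
#' @param data A tibble from [synth_expression()].
#' @return Tibble with `gene_id`, `role` (informative / redundant / noise),
#'   and `parent` (the informative gene a redundant gene copies).
#' @export
gene_roles <- function(data) {
  roles <- attr(data, "roles")
  if (is.null(roles)) stop("data carries no ground-truth roles", call. = FALSE)
  roles
}

#' Differential-expression prefilter (t-test + fold-change screen)
#'
#' Optional pre-step emulating the usual entry point of expression-based
#' selection: keep genes with a two-sample t-test p-value below
#' `p_threshold` and an absolute between-class mean difference above
#' `log2(fc_threshold)` (inputs are assumed log2-like, so mean difference is
#' log fold change). `fc_threshold <= 1` disables the fold-change arm.
#' A constant gene is always excluded (zero fold change, undefined t-test).
#'
#' @param data Expression tibble.
#' @param labels Binary labels (from the `label` column when `NULL`).
#' @param p_threshold P-value cutoff (default 0.05).
#' @param fc_threshold Fold-change cutoff on the natural scale (default 1.5).
#' @return Tibble `gene_id`, `p_value`, `log2_fc`, `keep`; genes in input
#'   order. Filter with `dplyr::filter(keep)`.
#' @export
deg_prefilter <- function(data, labels = NULL, p_threshold = 0.05,
                          fc_threshold = 1.5) {
  y <- expr_labels(data, labels)
  check_two_classes(y)
  x <- expr_matrix(data)
  lfc_cut <- if (fc_threshold > 1) log2(fc_threshold) else -Inf
  res <- purrr::map(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    d <- mean(v[y == 1]) - mean(v[y == 0])
    p <- if (sd(v[y == 1]) == 0 && sd(v[y == 0]) == 0) {
      NA_real_
    } else {
      t.test(v[y == 1], v[y == 0])$p.value
    }
    tibble::tibble(p_value = p, log2_fc = d)
  }) |> purrr::list_rbind()
  res |>
    dplyr::mutate(gene_id = colnames(x), .before = 1) |>
    dplyr::mutate(keep = !is.na(.data$p_value) &
                    .data$p_value < p_threshold &
                    abs(.data$log2_fc) > lfc_cut)
}

#' Write a dataset to the standard TSV trio
#'
#' `matrix.tsv` (samples x genes, first column `sample_id`), `labels.tsv`
#' (`sample_id`, `label`), and — when ground-truth roles are present —
#' `truth_roles.tsv` (`gene_id`, `role`).
#'
#' @param data Expression tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(data[, c("sample_id", expr_gene_ids(data))],
                   file.path(dir, "matrix.tsv"))
  readr::write_tsv(data[, c("sample_id", "label")],
                   file.path(dir, "labels.tsv"))
  roles <- attr(data, "roles")
  if (!is.null(roles)) {
    readr::write_tsv(roles[, c("gene_id", "role")],
                     file.path(dir, "truth_roles.tsv"))
  }
  invisible(dir)
}
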