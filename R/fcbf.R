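# Stage 1: the Fast Correlation-Based Filter. Genes are ranked by
# symmetrical uncertainty with the class; genes at or below the relevance
# threshold `delta` are dropped, then the predominant-feature sweep removes
# any gene whose SU to an already-kept gene meets or exceeds its SU to the
# class. Pairwise SU is computed lazily against kept genes only, never as a
# full gene-by-gene matrix.

as_discretized <- function(data, labels = NULL, method = "mdl", n_bins = 10) {
  if (inherits(data, "discretized_matrix")) return(data)
  discretize(data, labels = labels, method = method, n_bins = n_bins)
}

#' Rank genes by symmetrical uncertainty with the class
#'
#' @param data A `discretized_matrix` (see [discretize()]) or an expression
#'   tibble, which is discretized first with `method`.
#' @param labels Binary class labels (1 = ruptured, 0 = unruptured); taken
#'   from the `label` column when `NULL`.
#' @param delta Relevance threshold: only genes with `SU(gene, class) > delta`
#'   are retained. Default 0 keeps every gene with positive SU.
#' @param method,n_bins Discretization settings used when `data` is not
#'   already discretized.
#' @return A tibble of class `su_ranking` with columns `gene_id`, `su`,
#'   `rank`, sorted by `su` descending (ties broken by gene id).
#' @export
rank_by_su <- function(data, labels = NULL, delta = 0,
                       method = "mdl", n_bins = 10) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  labels <- expr_labels(data, labels)
  if (length(unique(labels)) < 2) {
    stop("class entropy is zero; SU with class undefined as a ranking",
         call. = FALSE)
  }
  dm <- as_discretized(data, labels, method, n_bins)
  if (nrow(dm$codes) != length(labels)) {
    stop("labels length must equal sample count", call. = FALSE)
  }
  su <- vapply(seq_len(ncol(dm$codes)), function(j) {
    symmetrical_uncertainty(dm$codes[, j], labels)
  }, numeric(1))
  out <- tibble::tibble(gene_id = colnames(dm$codes), su = su) |>
    dplyr::filter(.data$su > delta) |>
    dplyr::arrange(dplyr::desc(.data$su), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(out, class = c("su_ranking", class(out)),
            delta = delta, method = dm$method, n_bins = dm$n_bins_requested)
}

#' Predominant-feature redundancy elimination
#'
#' Walks the SU ranking from the top. A gene is removed when its SU to some
#' higher-ranked kept gene is at least its SU to the class (it is
#' "predominated": redundant given that gene). The top-ranked gene is never
#' removed; output order follows the ranking.
#'
#' @param ranking A `su_ranking` from [rank_by_su()].
#' @param data The same data the ranking was computed from (a
#'   `discretized_matrix` or an expression tibble, re-discretized with the
#'   ranking's recorded settings).
#' @param labels Binary labels, needed only when `data` must be re-discretized.
#' @return A tibble of class `fcbf_candidates` (columns `gene_id`, `su`,
#'   `rank` renumbered over the survivors).
#' @export
fcbf_select <- function(ranking, data, labels = NULL) {
  stopifnot(inherits(ranking, "su_ranking"))
  dm <- as_discretized(data, labels,
                       attr(ranking, "method") %||% "mdl",
                       attr(ranking, "n_bins") %||% 10)
  missing <- setdiff(ranking$gene_id, colnames(dm$codes))
  if (length(missing) > 0) {
    stop("ranking gene(s) missing from data: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  kept <- character(0)
  for (i in seq_len(nrow(ranking))) {
    g <- ranking$gene_id[i]
    su_gc <- ranking$su[i]
    redundant <- FALSE
    for (h in kept) {
      if (symmetrical_uncertainty(dm$codes[, g], dm$codes[, h]) >= su_gc) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, g)
  }
  out <- ranking[ranking$gene_id %in% kept, c("gene_id", "su")]
  out$rank <- seq_len(nrow(out))
  structure(tibble::as_tibble(out),
            class = c("fcbf_candidates", class(tibble::tibble())),
            delta = attr(ranking, "delta"))
}

#' Run both FCBF steps: SU ranking then redundancy elimination
#'
#' @inheritParams rank_by_su
#' @return A `fcbf_candidates` tibble (`gene_id`, `su`, `rank`).
#' @examples
#' d <- synth_expression(n_pos = 20, n_neg = 20, n_informative = 2,
#'                       n_redundant = 2, n_noise = 20, effect_size = 2, seed = 1)
#' fcbf(d)
#' @export
fcbf <- function(data, labels = NULL, delta = 0, method = "mdl", n_bins = 10) {
  labels <- expr_labels(data, labels)
  dm <- as_discretized(data, labels, method, n_bins)
  ranking <- rank_by_su(dm, labels, delta = delta)
  fcbf_select(ranking, dm)
}

#' Write the ranked candidate table to TSV
#'
#' Columns `gene_id`, `su_with_class`, `rank`.
#' @param candidates A `fcbf_candidates` or `su_ranking` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- tibble::tibble(gene_id = candidates$gene_id,
                        su_with_class = sprintf("%.10g", candidates$su),
                        rank = candidates$rank)
  readr::write_tsv(out, path)
  invisible(path)
}
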