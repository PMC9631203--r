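# Discretization of continuous expression into per-gene integer bin codes.
# The filter stage computes entropies over these codes. Default is the
# supervised Fayyad-Irani minimum-description-length (MDL) criterion; a
# gene for which no cut passes the MDL test collapses to a single bin and
# therefore carries zero symmetrical uncertainty with the class.

label_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Recursive Fayyad-Irani MDL cut search on values sorted ascending.
# y must be integer class codes. Returns cut points (midpoints), ascending.
mdl_cut_points <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  classes <- sort(unique(y))
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2) return(numeric(0))
    seg_x <- xs[lo:hi]
    seg_y <- ys[lo:hi]
    counts <- tabulate(match(seg_y, classes), nbins = length(classes))
    ent_s <- label_entropy(counts)
    k <- sum(counts > 0)
    if (ent_s == 0) return(numeric(0))
    # candidate thresholds: midpoints between adjacent distinct values
    distinct <- which(diff(seg_x) > 0)
    if (length(distinct) == 0) return(numeric(0))
    best_gain <- -Inf
    best <- NULL
    # left-cumulative class counts at every split position
    left_counts <- matrix(0, nrow = length(classes), ncol = n)
    for (ci in seq_along(classes)) {
      left_counts[ci, ] <- cumsum(seg_y == classes[ci])
    }
    for (pos in distinct) {
      cl <- left_counts[, pos]
      cr <- counts - cl
      n1 <- pos
      n2 <- n - pos
      e1 <- label_entropy(cl)
      e2 <- label_entropy(cr)
      gain <- ent_s - (n1 / n) * e1 - (n2 / n) * e2
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(pos = pos, e1 = e1, e2 = e2,
                     k1 = sum(cl > 0), k2 = sum(cr > 0))
      }
    }
    # MDL acceptance: gain must exceed (log2(n-1) + delta) / n where
    # delta = log2(3^k - 2) - [k*Ent(S) - k1*Ent(S1) - k2*Ent(S2)]
    delta <- log2(3^k - 2) -
      (k * ent_s - best$k1 * best$e1 - best$k2 * best$e2)
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric(0))
    cut <- (xs[lo + best$pos - 1] + xs[lo + best$pos]) / 2
    c(recurse(lo, lo + best$pos - 1), cut, recurse(lo + best$pos, hi))
  }
  recurse(1, length(xs))
}

#' Discretize one numeric vector into bin codes
#'
#' @param x Numeric vector.
#' @param labels Binary class labels, required for `method = "mdl"`.
#' @param method `"mdl"` (supervised Fayyad-Irani MDL, the default),
#'   `"equal_frequency"`, or `"equal_width"`.
#' @param n_bins Number of bins for the unsupervised methods (>= 2).
#' @return A list with `codes` (0-based integer codes), `n_bins`, and
#'   `bin_edges` (ascending cut points; empty when the gene maps to one bin).
#' @export
discretize_vector <- function(x, labels = NULL,
                              method = c("mdl", "equal_frequency", "equal_width"),
                              n_bins = 10) {
  method <- match.arg(method)
  if (anyNA(x) || !is.numeric(x)) {
    stop("discretize_vector(): non-numeric or missing values", call. = FALSE)
  }
  edges <- if (length(unique(x)) < 2) {
    numeric(0)
  } else if (method == "mdl") {
    if (is.null(labels)) stop("method 'mdl' requires labels", call. = FALSE)
    mdl_cut_points(x, as.integer(labels))
  } else {
    if (n_bins < 2) stop("n_bins must be >= 2 for unsupervised methods", call. = FALSE)
    e <- if (method == "equal_frequency") {
      quantile(x, probs = seq_len(n_bins - 1) / n_bins, names = FALSE, type = 7)
    } else {
      seq(min(x), max(x), length.out = n_bins + 1)[-c(1, n_bins + 1)]
    }
    sort(unique(e))
  }
  codes <- findInterval(x, edges)
  list(codes = as.integer(codes), n_bins = length(edges) + 1L, bin_edges = edges)
}

#' Discretize an expression matrix gene-by-gene
#'
#' Applies [discretize_vector()] to every gene column, producing the
#' discrete variables over which entropy and symmetrical uncertainty are
#' computed. Deterministic: identical input and parameters give bit-identical
#' codes.
#'
#' @param data Expression tibble (`sample_id`, `label`, gene columns) or a
#'   numeric samples-by-genes matrix.
#' @param labels Binary labels; taken from the `label` column when `NULL`.
#' @inheritParams discretize_vector
#' @return An object of class `discretized_matrix`: list with `codes`
#'   (integer matrix, samples x genes, 0-based), `n_bins` (named integer
#'   vector), `bin_edges` (named list), `method`, `n_bins_requested`.
#' @export
discretize <- function(data, labels = NULL,
                       method = c("mdl", "equal_frequency", "equal_width"),
                       n_bins = 10) {
  method <- match.arg(method)
  x <- expr_matrix(data)
  if (nrow(x) < 2) stop("discretize(): need at least 2 samples", call. = FALSE)
  if (anyNA(x)) {
    bad <- which(colSums(is.na(x)) > 0)[1]
    stop("missing values in gene '", colnames(x)[bad], "'", call. = FALSE)
  }
  labels <- if (method == "mdl") expr_labels(data, labels) else NULL
  if (!is.null(labels) && length(labels) != nrow(x)) {
    stop("labels length must equal sample count", call. = FALSE)
  }
  per_gene <- lapply(seq_len(ncol(x)), function(j) {
    discretize_vector(x[, j], labels = labels, method = method, n_bins = n_bins)
  })
  genes <- colnames(x) %||% paste0("g", seq_len(ncol(x)))
  codes <- vapply(per_gene, `[[`, integer(nrow(x)), "codes")
  colnames(codes) <- genes
  rownames(codes) <- rownames(x)
  structure(
    list(codes = codes,
         n_bins = stats::setNames(vapply(per_gene, `[[`, integer(1), "n_bins"), genes),
         bin_edges = stats::setNames(lapply(per_gene, `[[`, "bin_edges"), genes),
         method = method, n_bins_requested = n_bins),
    class = "discretized_matrix"
  )
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat("<discretized_matrix> ", nrow(x$codes), " samples x ", ncol(x$codes),
      " genes; method = ", x$method, "\n", sep = "")
  cat("  multi-bin genes: ", sum(x$n_bins > 1), " of ", length(x$n_bins), "\n", sep = "")
  invisible(x)
}
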