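# Independent brute-force oracles used to validate the package's
# information-theoretic kernel and the FCBF sweep. Deliberately written in
# the most literal way possible (explicit joint contingency tables, nested
# loops), sharing no code with the implementation.

oracle_entropy <- function(x) {
  vals <- unique(x)
  h <- 0
  for (v in vals) {
    p <- sum(x == v) / length(x)
    h <- h - p * log2(p)
  }
  h
}

oracle_conditional_entropy <- function(x, y) {
  xv <- unique(x)
  yv <- unique(y)
  n <- length(x)
  # full joint contingency table, cell by cell
  joint <- matrix(0, length(xv), length(yv))
  for (i in seq_along(xv)) {
    for (j in seq_along(yv)) {
      joint[i, j] <- sum(x == xv[i] & y == yv[j])
    }
  }
  h <- 0
  for (j in seq_along(yv)) {
    py <- sum(joint[, j]) / n
    for (i in seq_along(xv)) {
      pxy <- joint[i, j] / n
      if (pxy > 0) h <- h - pxy * log2(pxy / py)
    }
  }
  h
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x)
  hy <- oracle_entropy(y)
  if (hx + hy == 0) return(0)
  2 * (hx - oracle_conditional_entropy(x, y)) / (hx + hy)
}

# Literal predominant-feature sweep (the original fast correlation-based
# filter definition): from the top of the SU-with-class ranking, each kept
# gene removes every lower-ranked gene whose SU to it is at least that
# gene's SU to the class.
oracle_fcbf <- function(codes, labels, delta = 0) {
  genes <- colnames(codes)
  su_c <- vapply(genes, function(g) oracle_su(codes[, g], labels), numeric(1))
  keep <- genes[su_c > delta]
  keep <- keep[order(-su_c[keep], keep)]
  i <- 1
  while (i <= length(keep)) {
    g_i <- keep[i]
    j <- i + 1
    while (j <= length(keep)) {
      g_j <- keep[j]
      if (oracle_su(codes[, g_j], codes[, g_i]) >= su_c[g_j]) {
        keep <- keep[-j]
      } else {
        j <- j + 1
      }
    }
    i <- i + 1
  }
  keep
}

# all discrete vectors of length len over alphabet 0..(a-1), as a matrix
# with one vector per row
enumerate_vectors <- function(len, a) {
  as.matrix(expand.grid(rep(list(0:(a - 1)), len)))
}

# random discrete matrix fixture for filter tests
random_codes <- function(n, g, a, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:(a - 1), n * g, replace = TRUE), n, g)
    colnames(m) <- sprintf("g%02d", seq_len(g))
    m
  })
}

# wrap integer codes as a discretized_matrix without re-binning
make_dm <- function(codes) {
  structure(list(codes = codes,
                 n_bins = apply(codes, 2, function(v) max(v) + 1L),
                 bin_edges = stats::setNames(vector("list", ncol(codes)),
                                             colnames(codes)),
                 method = "mdl", n_bins_requested = 10),
            class = "discretized_matrix")
}
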