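test_that("SU ranking keeps the class copy and drops the independent gene", {
  labels <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  codes <- cbind(g1 = labels, g2 = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L))
  r <- rank_by_su(make_dm(codes), labels, delta = 0)
  expect_equal(r$gene_id, "g1")
  expect_equal(r$su, 1.0)
  # SU never strictly exceeds 1, so delta = 1 empties any ranking
  expect_equal(nrow(rank_by_su(make_dm(codes), labels, delta = 1)), 0)
  expect_error(rank_by_su(make_dm(codes), rep(1L, 8)), "single class|zero")
})

test_that("ranking reproduces a brute-force SU-with-class recomputation", {
  for (s in 1:10) {
    codes <- random_codes(20, 6, 3, seed = 400 + s)
    labels <- withr::with_seed(500 + s, sample(0:1, 20, replace = TRUE))
    if (length(unique(labels)) < 2) next
    # delta slightly above 0 so numerically-zero SU values (which the two
    # code paths round differently at the 1e-16 level) fall on one side
    r <- rank_by_su(make_dm(codes), labels, delta = 1e-9)
    su_all <- vapply(colnames(codes),
                     function(g) oracle_su(codes[, g], labels), numeric(1))
    expected <- su_all[su_all > 1e-9]
    expected <- expected[order(-expected, names(expected))]
    expect_equal(r$gene_id, names(expected))
    expect_equal(r$su, unname(expected), tolerance = 1e-12)
  }
})

test_that("an exact duplicate of the top gene is removed, independent genes kept", {
  labels <- rep(c(0L, 1L), each = 6)
  g1 <- labels
  g2 <- g1                                  # exact copy, ranked second by id
  g3 <- c(0L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L) # ~independent
  codes <- cbind(g1 = g1, g2 = g2, g3 = g3)
  dm <- make_dm(codes)
  out <- fcbf_select(rank_by_su(dm, labels), dm)
  expect_true("g1" %in% out$gene_id)
  expect_false("g2" %in% out$gene_id)
})

test_that("mutually independent genes all survive the sweep", {
  # orthogonal binary patterns over 8 samples: pairwise SU = 0
  labels <- rep(c(0L, 1L), each = 4)
  codes <- cbind(g1 = rep(c(0L, 1L), each = 4),
                 g2 = rep(c(0L, 1L, 0L, 1L), each = 2))
  dm <- make_dm(codes)
  r <- rank_by_su(dm, labels)
  out <- fcbf_select(r, dm)
  expect_setequal(out$gene_id, r$gene_id)
})

test_that("the sweep matches the literal predominant-feature oracle", {
  mismatches <- 0
  for (s in 1:25) {
    codes <- random_codes(20, 8, 3, seed = 600 + s)
    labels <- withr::with_seed(700 + s, sample(0:1, 20, replace = TRUE))
    if (length(unique(labels)) < 2) next
    dm <- make_dm(codes)
    out <- fcbf_select(rank_by_su(dm, labels), dm)
    if (!identical(out$gene_id, oracle_fcbf(codes, labels))) {
      mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("output is a subset, keeps the top gene, and is monotone in delta", {
  codes <- random_codes(30, 8, 3, seed = 811)
  labels <- withr::with_seed(812, sample(0:1, 30, replace = TRUE))
  dm <- make_dm(codes)
  r0 <- rank_by_su(dm, labels, delta = 0)
  out0 <- fcbf_select(r0, dm)
  expect_true(all(out0$gene_id %in% r0$gene_id))
  expect_true(r0$gene_id[1] %in% out0$gene_id)
  prev <- out0$gene_id
  for (delta in c(0.02, 0.05, 0.1, 0.3)) {
    out <- fcbf_select(rank_by_su(dm, labels, delta = delta), dm)
    expect_true(all(out$gene_id %in% prev))   # raising delta never adds genes
    prev <- out$gene_id
  }
})

test_that("the sweep is idempotent on its own output", {
  for (s in 1:5) {
    codes <- random_codes(24, 8, 3, seed = 900 + s)
    labels <- withr::with_seed(950 + s, sample(0:1, 24, replace = TRUE))
    dm <- make_dm(codes)
    out1 <- fcbf_select(rank_by_su(dm, labels), dm)
    dm2 <- make_dm(codes[, out1$gene_id, drop = FALSE])
    out2 <- fcbf_select(rank_by_su(dm2, labels), dm2)
    expect_equal(out2$gene_id, out1$gene_id)
  }
})

test_that("a ranking gene missing from the data is a consistency error", {
  codes <- random_codes(20, 4, 2, seed = 990)
  labels <- rep(c(0L, 1L), 10)
  dm <- make_dm(codes)
  r <- rank_by_su(dm, labels)
  dm_small <- make_dm(codes[, 1:2, drop = FALSE])
  if (any(!r$gene_id %in% colnames(dm_small$codes))) {
    expect_error(fcbf_select(r, dm_small), "missing from data")
  } else {
    succeed()
  }
})

test_that("each planted signal group collapses to a single representative", {
  # a redundant copy and its parent are statistically interchangeable, so
  # the sweep keeps exactly one arbitrary member per correlated group and
  # removes the duplication
  for (s in 1:3) {
    d <- synth_expression(n_pos = 60, n_neg = 60, n_informative = 5,
                          n_redundant = 10, n_noise = 600, effect_size = 2,
                          redundancy_noise_sd = 0.1, seed = s)
    roles <- gene_roles(d)
    cand <- fcbf(d)
    group_of <- ifelse(is.na(roles$parent), roles$gene_id, roles$parent)
    names(group_of) <- roles$gene_id
    signal <- cand$gene_id[roles$role[match(cand$gene_id,
                                            roles$gene_id)] != "noise"]
    groups <- group_of[signal]
    expect_false(any(duplicated(groups)))        # no group kept twice
    expect_gte(length(unique(groups)), 4)        # >= 4 of 5 groups represented
  }
})
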