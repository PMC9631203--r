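test_that("entropy matches closed-form values and conventions", {
  expect_equal(entropy_bits(c(0, 0, 1, 1)), 1.0)
  expect_equal(entropy_bits(c(1, 1, 1, 1)), 0.0)
  # -(2/3)log2(2/3) - (1/3)log2(1/3)
  expect_equal(entropy_bits(c(0, 0, 1)),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)
  expect_equal(entropy_bits(c(0, 0, 1)), 0.918296, tolerance = 1e-6)
  expect_error(entropy_bits(integer(0)), "non-empty")
})

test_that("conditional entropy matches joint-table arithmetic", {
  x <- c(0, 0, 1, 1)
  expect_equal(conditional_entropy(x, x), 0.0)
  expect_equal(conditional_entropy(x, c(0, 1, 0, 1)), 1.0)
  # (3/4) * H(2/3, 1/3) + (1/4) * 0
  expect_equal(conditional_entropy(x, c(0, 0, 0, 1)),
               0.75 * entropy_bits(c(0, 0, 1)),
               tolerance = 1e-12)
  expect_equal(conditional_entropy(x, c(0, 0, 0, 1)), 0.688722,
               tolerance = 1e-6)
  expect_error(conditional_entropy(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("symmetrical uncertainty hits its endpoints and derived value", {
  x <- c(0, 0, 1, 1)
  expect_equal(symmetrical_uncertainty(x, x), 1.0)
  expect_equal(symmetrical_uncertainty(x, c(0, 1, 0, 1)), 0.0)
  y <- c(0, 0, 0, 1)
  expected <- 2 * (entropy_bits(x) - conditional_entropy(x, y)) /
    (entropy_bits(x) + entropy_bits(y))
  expect_equal(symmetrical_uncertainty(x, y), expected, tolerance = 1e-12)
  expect_equal(symmetrical_uncertainty(x, y), 0.343711, tolerance = 1e-5)
  # both-constant and one-constant conventions
  expect_equal(symmetrical_uncertainty(c(1, 1), c(2, 2)), 0)
  expect_equal(symmetrical_uncertainty(c(1, 1, 1), c(0, 1, 0)), 0)
})

test_that("entropy trio agrees with the brute-force joint-table oracle", {
  withr::with_seed(71, {
    for (rep in 1:200) {
      len <- sample(2:6, 1)
      x <- sample(0:2, len, replace = TRUE)
      y <- sample(0:2, len, replace = TRUE)
      expect_equal(entropy_bits(x), oracle_entropy(x), tolerance = 1e-12)
      expect_equal(conditional_entropy(x, y), oracle_conditional_entropy(x, y),
                   tolerance = 1e-12)
      expect_equal(symmetrical_uncertainty(x, y), oracle_su(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("SU is symmetric, bounded, and invariant to relabeling", {
  withr::with_seed(72, {
    for (rep in 1:100) {
      len <- sample(4:12, 1)
      x <- sample(0:2, len, replace = TRUE)
      y <- sample(0:2, len, replace = TRUE)
      su <- symmetrical_uncertainty(x, y)
      expect_gte(su, 0)
      expect_lte(su, 1)
      expect_equal(su, symmetrical_uncertainty(y, x), tolerance = 1e-12)
      expect_lte(conditional_entropy(x, y), entropy_bits(x) + 1e-12)
      # permute category codes: SU must not move
      perm <- sample(0:2)
      expect_equal(symmetrical_uncertainty(perm[x + 1], y), su,
                   tolerance = 1e-12)
    }
  })
})

test_that("equal-frequency and equal-width binning follow their contracts", {
  d <- discretize_vector(c(1, 2, 3, 4), method = "equal_frequency", n_bins = 2)
  expect_equal(d$codes, c(0L, 0L, 1L, 1L))
  expect_equal(d$n_bins, 2L)
  # constant gene degenerates to one bin under every method
  for (m in c("mdl", "equal_frequency", "equal_width")) {
    dc <- discretize_vector(c(5, 5, 5, 5), labels = c(0, 0, 1, 1), method = m)
    expect_equal(dc$n_bins, 1L)
    expect_equal(dc$codes, rep(0L, 4))
    expect_length(dc$bin_edges, 0)
  }
  expect_error(discretize_vector(1:4, method = "equal_width", n_bins = 1),
               "n_bins")
})

test_that("MDL accepts the perfectly separating cut on the 4-sample case", {
  # gain = 1 bit; acceptance bound = (log2(3) + log2(3^2 - 2) - 2) / 4 ~ 0.598
  d <- discretize_vector(c(1, 1, 2, 2), labels = c(0, 0, 1, 1), method = "mdl")
  expect_equal(d$n_bins, 2L)
  expect_length(d$bin_edges, 1)
  expect_equal(d$codes, c(0L, 0L, 1L, 1L))
})

test_that("matrix discretization validates input and is deterministic", {
  d <- synth_expression(n_pos = 15, n_neg = 15, n_informative = 2,
                        n_redundant = 1, n_noise = 10, effect_size = 2,
                        seed = 5)
  dm1 <- discretize(d)
  dm2 <- discretize(d)
  expect_identical(dm1$codes, dm2$codes)
  expect_true(all(dm1$codes >= 0))
  expect_true(all(dm1$codes < dm1$n_bins[col(dm1$codes)]))
  bad <- d
  bad$INF01[3] <- NA
  expect_error(discretize(bad), "INF01")
})
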