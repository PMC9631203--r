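test_that("velocity update obeys the inertia/attraction structure", {
  cfg0 <- swarm_config(omega = 1, c1 = 0, c2 = 0, v_max = 10)
  v <- c(0.1, -0.2, 0.3)
  x <- c(0.5, 0.5, 0.5)
  expect_equal(pso_update_velocity(v, x, c(0.9, 0.1, 0.4), c(0, 1, 1), cfg0), v)
  # zero displacement terms leave only inertia
  cfg <- swarm_config(omega = 0.7, v_max = 10)
  expect_equal(pso_update_velocity(v, x, x, x, cfg), 0.7 * v)
  # clamp contract under violent attraction
  cfgc <- swarm_config(omega = 1, c1 = 50, c2 = 50, v_max = 0.6)
  withr::with_seed(1, {
    vv <- pso_update_velocity(v, x, c(1, 1, 1), c(0, 0, 0), cfgc)
  })
  expect_true(all(abs(vv) <= 0.6))
  expect_error(pso_update_velocity(v, x[1:2], x, x, cfg), "length")
})

test_that("position update adds velocity and clips to the unit box", {
  expect_equal(pso_update_position(c(0.3, 0.8), c(0, 0)), c(0.3, 0.8))
  expect_equal(pso_update_position(0.9, 0.5), 1.0)
  expect_equal(pso_update_position(0.3, -0.1), 0.2)
  expect_equal(pso_update_position(0.1, -0.5), 0.0)
})

test_that("subset decoding thresholds positions and repairs empty masks", {
  expect_equal(decode_subset(c(0.9, 0.2, 0.5), 0.5), c(TRUE, FALSE, TRUE))
  expect_equal(decode_subset(c(0.1, 0.4), 0.5), c(FALSE, TRUE))
  expect_equal(decode_subset(c(0.6, 0.7, 0.5), 0.5), rep(TRUE, 3))
})

test_that("with c1 = c2 = 0 and omega < 1 velocities decay geometrically", {
  cfg <- swarm_config(omega = 0.5, c1 = 0, c2 = 0, v_max = 1)
  v <- c(0.4, -0.6)
  x <- c(0.5, 0.5)
  for (i in 1:10) v <- pso_update_velocity(v, x, x, x, cfg)
  expect_equal(v, c(0.4, -0.6) * 0.5^10, tolerance = 1e-12)
})

test_that("a label-copy gene reaches near-perfect wrapper fitness", {
  withr::with_seed(21, {
    y <- rep(c(0L, 1L), each = 20)
    X <- cbind(sig = as.numeric(y), n1 = rnorm(40), n2 = rnorm(40),
               n3 = rnorm(40))
  })
  f <- evaluate_fitness("sig", X, y, seed = 1)
  expect_equal(f$accuracy, 1.0)
  expect_lt(f$mse, 0.1)
  expect_equal(f$composite, 1 - 0.1 * f$mse - 0.05 * (1 / 4),
               tolerance = 1e-12)
})

test_that("noise-only fitness hovers at chance accuracy", {
  withr::with_seed(22, {
    y <- rep(c(0L, 1L), each = 200)
    X <- cbind(n1 = rnorm(400), n2 = rnorm(400))
  })
  f <- evaluate_fitness(c("n1", "n2"), X, y, seed = 2)
  expect_lt(abs(f$accuracy - 0.5), 0.1)
})

test_that("at fixed accuracy and MSE the smaller subset wins the composite", {
  cfg <- eval_config()
  comp <- function(size) 0.8 - cfg$lambda_mse * 0.1 - cfg$lambda_size * size / 10
  expect_gt(comp(2), comp(3))
})

test_that("injected-fitness search recovers planted optima found exhaustively", {
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 10)))
  for (s in 1:3) {
    target <- withr::with_seed(30 + s, sample(c(TRUE, FALSE), 10, replace = TRUE))
    fit <- function(mask) sum(mask == target)
    best_exhaustive <- max(apply(masks, 1, fit))
    res <- pso_search(NULL, paste0("g", 1:10),
                      cfg = swarm_config(n_particles = 20, n_iterations = 50,
                                         seed = 40 + s),
                      fitness_fn = fit)
    expect_equal(res$fitness$composite, best_exhaustive)
    expect_equal(res$mask, unname(target))
    expect_true(all(diff(res$history$composite) >= 0))
  }
})

test_that("a zero-iteration budget returns the best of the initial swarm", {
  fit <- function(mask) -sum(mask)
  res <- pso_search(NULL, paste0("g", 1:6),
                    cfg = swarm_config(n_particles = 5, n_iterations = 0,
                                       seed = 3),
                    fitness_fn = fit)
  expect_equal(nrow(res$history), 1)
  expect_equal(res$history$iteration, 0L)
})

test_that("the search is reproducible from its seed", {
  withr::with_seed(51, {
    y <- rep(c(0L, 1L), each = 15)
    X <- cbind(a = rnorm(30, y), b = rnorm(30), c = rnorm(30, -y))
  })
  cfg <- swarm_config(n_particles = 6, n_iterations = 5, seed = 99)
  mcfg <- mlp_config(epochs = 50)
  r1 <- pso_search(X, c("a", "b", "c"), y, cfg = cfg, mlp = mcfg)
  r2 <- pso_search(X, c("a", "b", "c"), y, cfg = cfg, mlp = mcfg)
  expect_identical(r1$selected_genes, r2$selected_genes)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$composite) >= 0))
})

test_that("an empty candidate set is rejected with a remediation hint", {
  expect_error(pso_search(NULL, character(0), fitness_fn = identity),
               "no candidates")
})

test_that("tidiers expose the convergence trace and final state", {
  fit <- function(mask) sum(mask)
  res <- pso_search(NULL, paste0("g", 1:4),
                    cfg = swarm_config(n_particles = 4, n_iterations = 3,
                                       seed = 7),
                    fitness_fn = fit)
  td <- tidy(res)
  expect_named(td, c("iteration", "accuracy", "mse", "subset_size", "composite"))
  expect_equal(nrow(td), 4)
  gl <- glance(res)
  expect_equal(gl$n_candidates, 4)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
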