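# Stage 2: particle-swarm search over subsets of the FCBF candidates.
# Positions are continuous in [0,1]^D, as in the canonical update equations
#   v <- omega*v + c1*rand1*(pbest - x) + c2*rand2*(gbest - x)
#   x <- x + v
# and a subset is obtained by an explicit decode step: gene j is included
# iff x_j >= decode_threshold. Fitness of a subset is the MLP's
# cross-validated accuracy, penalized by MSE and subset size.

#' Swarm configuration
#'
#' @param n_particles Swarm size (default 30).
#' @param n_iterations Iteration budget; a fixed budget is the only stopping
#'   rule (default 100).
#' @param omega Inertia weight in (0, 1\] (default 0.7).
#' @param c1,c2 Cognitive and social acceleration coefficients, the
#'   conventional value 2.
#' @param v_max Symmetric velocity clamp (default 0.6).
#' @param decode_threshold Position-to-mask cutoff in (0, 1) (default 0.5).
#' @param stall_refine Anti-stagnation refinement: when the global best has
#'   not improved for this many iterations, every single-bit flip of the
#'   global-best mask is evaluated and the best strict improvement (if any)
#'   replaces the global best. This memetic local step escapes the
#'   one-coordinate stagnation the inertia-decayed swarm cannot, at a cost
#'   of at most D fitness evaluations per stall. Default 10; 0 disables.
#' @param seed Seed for the whole search (initialization, update draws, and
#'   per-subset fitness seeds are all derived from it).
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30, n_iterations = 100, omega = 0.7,
                         c1 = 2, c2 = 2, v_max = 0.6,
                         decode_threshold = 0.5, stall_refine = 10, seed = 1) {
  stopifnot(n_particles >= 1, n_iterations >= 0,
            omega > 0, omega <= 1, v_max > 0,
            decode_threshold > 0, decode_threshold < 1, stall_refine >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 omega = omega, c1 = c1, c2 = c2, v_max = v_max,
                 decode_threshold = decode_threshold,
                 stall_refine = as.integer(stall_refine),
                 seed = as.integer(seed)),
            class = "swarm_config")
}

#' Fitness-evaluation configuration for the wrapper
#'
#' The composite score maximized by the swarm is
#' `ACC - lambda_mse * MSE - lambda_size * subset_size / D`,
#' strictly increasing in accuracy and strictly decreasing in MSE and
#' subset size. Accuracy and MSE come from stratified k-fold
#' cross-validation of the MLP on the subset's columns; MSE is the mean
#' squared difference between out-of-fold predicted probability and the
#' 0/1 label.
#'
#' @param k Cross-validation folds inside the fitness function (default 5).
#' @param lambda_mse Weight on MSE (default 0.1).
#' @param lambda_size Weight on relative subset size (default 0.05).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(k = 5, lambda_mse = 0.1, lambda_size = 0.05) {
  stopifnot(k >= 2, lambda_mse >= 0, lambda_size >= 0)
  structure(list(k = as.integer(k), lambda_mse = lambda_mse,
                 lambda_size = lambda_size),
            class = "eval_config")
}

#' One velocity update of the canonical PSO recursion
#'
#' `rand1`, `rand2` are drawn fresh per component from U\[0, 1\] using the
#' current RNG stream; the result is clamped component-wise to
#' `[-v_max, v_max]`.
#'
#' @param velocity,position,pbest,gbest Equal-length numeric vectors.
#' @param cfg A [swarm_config()].
#' @return The new velocity vector.
#' @export
pso_update_velocity <- function(velocity, position, pbest, gbest, cfg) {
  D <- length(position)
  if (length(velocity) != D || length(pbest) != D || length(gbest) != D) {
    stop("velocity/position/pbest/gbest must share one length", call. = FALSE)
  }
  v <- cfg$omega * velocity +
    cfg$c1 * runif(D) * (pbest - position) +
    cfg$c2 * runif(D) * (gbest - position)
  pmin(pmax(v, -cfg$v_max), cfg$v_max)
}

#' One position update: x + v, clipped to the unit box
#'
#' @param position,velocity Equal-length numeric vectors.
#' @return The new position in \[0, 1\]^D.
#' @export
pso_update_position <- function(position, velocity) {
  if (length(position) != length(velocity)) {
    stop("position and velocity must share one length", call. = FALSE)
  }
  pmin(pmax(position + velocity, 0), 1)
}

#' Decode a continuous position into a gene-inclusion mask
#'
#' Gene j is included iff `position[j] >= threshold`. An all-excluded mask
#' is repaired by including the single gene with the largest position
#' component (first on ties), so the classifier always has at least one
#' feature.
#'
#' @param position Numeric vector with components in \[0, 1\].
#' @param threshold Inclusion cutoff (default 0.5).
#' @return A logical mask of the same length.
#' @export
decode_subset <- function(position, threshold = 0.5) {
  mask <- position >= threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Cross-validated MLP fitness of a gene subset
#'
#' @param subset Character gene ids (non-empty).
#' @param data Expression tibble or numeric matrix.
#' @param labels Binary labels (from the `label` column when `NULL`).
#' @param D Search-space dimension used by the size penalty; defaults to the
#'   number of genes in `data`.
#' @param mlp An [mlp_config()].
#' @param eval An [eval_config()].
#' @param seed Base seed; the evaluation RNG is derived from `(seed, subset)`
#'   so a subset's fitness is stable within a run.
#' @return One-row tibble: `accuracy`, `mse`, `subset_size`, `composite`.
#' @export
evaluate_fitness <- function(subset, data, labels = NULL, D = NULL,
                             mlp = mlp_config(), eval = eval_config(),
                             seed = 1) {
  if (length(subset) == 0) stop("empty gene subset", call. = FALSE)
  y <- expr_labels(data, labels)
  check_two_classes(y)
  x <- expr_matrix(data, subset)
  D <- D %||% if (is.data.frame(data)) length(expr_gene_ids(data)) else ncol(data)

  all_genes <- if (is.data.frame(data)) expr_gene_ids(data) else colnames(data)
  mask <- all_genes %in% subset
  eseed <- mask_seed(seed, mask)

  folds <- stratified_folds(y, eval$k, eseed)
  prob <- numeric(length(y))
  for (f in seq_len(eval$k)) {
    tr <- folds != f
    model <- mlp_train(x[tr, , drop = FALSE], y[tr], config = mlp,
                       seed = derive_seed(eseed, paste0("fold", f)))
    prob[!tr] <- mlp_predict(model, x[!tr, , drop = FALSE])$prob
  }
  acc <- mean(as.integer(prob >= 0.5) == y)
  mse <- mean((prob - y)^2)
  comp <- acc - eval$lambda_mse * mse - eval$lambda_size * length(subset) / D
  tibble::tibble(accuracy = acc, mse = mse,
                 subset_size = length(subset), composite = comp)
}

#' Particle-swarm search for the optimal gene subset
#'
#' Initializes positions uniformly in \[0, 1\]^D and velocities in
#' \[-v_max/2, v_max/2\], then iterates the velocity/position updates,
#' decoding each particle to a subset and scoring it. Personal bests and the
#' global best only ever improve, so the returned fitness history is
#' non-decreasing. Fitness values are cached by decoded mask (subsets
#' revisit often). Fully reproducible from `cfg$seed`.
#'
#' @param data Expression tibble or matrix containing the candidate genes
#'   (may be `NULL` when `fitness_fn` is supplied).
#' @param candidates Character gene ids (or a `fcbf_candidates` /
#'   `su_ranking` tibble) defining the D-dimensional search space.
#' @param labels Binary labels.
#' @param cfg A [swarm_config()].
#' @param mlp,eval Configurations forwarded to [evaluate_fitness()].
#' @param fitness_fn Optional injected fitness: a function of a logical mask
#'   returning a numeric composite (or a list with `composite`). Replaces
#'   the MLP fitness; used for algorithm validation against exhaustive
#'   search.
#' @return An object of class `pso_selection`: `selected_genes`, `mask`,
#'   `fitness` (best one-row tibble), `history` (per-iteration gbest),
#'   `candidates`, and the configurations. See [tidy()][generics::tidy],
#'   [glance()][generics::glance], [autoplot()][ggplot2::autoplot].
#' @export
pso_search <- function(data, candidates, labels = NULL,
                       cfg = swarm_config(), mlp = mlp_config(),
                       eval = eval_config(), fitness_fn = NULL) {
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  candidates <- as.character(candidates)
  D <- length(candidates)
  if (D == 0) {
    stop("Stage 1 returned no candidates; lower delta", call. = FALSE)
  }
  if (is.null(fitness_fn)) {
    y <- expr_labels(data, labels)
    check_two_classes(y)
    x <- expr_matrix(data, candidates)
    fit_seed <- derive_seed(cfg$seed, "fitness")
    fitness_fn_internal <- function(mask) {
      evaluate_fitness(candidates[mask], x, y, D = D, mlp = mlp, eval = eval,
                       seed = fit_seed)
    }
  } else {
    fitness_fn_internal <- function(mask) {
      out <- fitness_fn(mask)
      if (is.list(out)) {
        tibble::tibble(accuracy = out$accuracy %||% NA_real_,
                       mse = out$mse %||% NA_real_,
                       subset_size = sum(mask),
                       composite = out$composite)
      } else {
        tibble::tibble(accuracy = NA_real_, mse = NA_real_,
                       subset_size = sum(mask), composite = out)
      }
    }
  }

  cache <- new.env(parent = emptyenv())
  score <- function(mask) {
    key <- paste0(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_fn_internal(mask)
    cache[[key]] <- val
    val
  }

  result <- withr::with_seed(cfg$seed, {
    pos <- matrix(runif(cfg$n_particles * D), cfg$n_particles, D)
    vel <- matrix(runif(cfg$n_particles * D, -cfg$v_max / 2, cfg$v_max / 2),
                  cfg$n_particles, D)
    pbest_pos <- pos
    pbest_fit <- vector("list", cfg$n_particles)
    gbest_fit <- NULL
    gbest_pos <- NULL
    gbest_mask <- NULL
    for (i in seq_len(cfg$n_particles)) {
      m <- decode_subset(pos[i, ], cfg$decode_threshold)
      f <- score(m)
      pbest_fit[[i]] <- f
      if (is.null(gbest_fit) || f$composite > gbest_fit$composite) {
        gbest_fit <- f
        gbest_pos <- pos[i, ]
        gbest_mask <- m
      }
    }
    hist <- vector("list", cfg$n_iterations + 1)
    hist[[1]] <- dplyr::bind_cols(tibble::tibble(iteration = 0L), gbest_fit)
    stall <- 0L
    for (t in seq_len(cfg$n_iterations)) {
      gbest_before <- gbest_fit$composite
      for (i in seq_len(cfg$n_particles)) {
        vel[i, ] <- pso_update_velocity(vel[i, ], pos[i, ],
                                        pbest_pos[i, ], gbest_pos, cfg)
        pos[i, ] <- pso_update_position(pos[i, ], vel[i, ])
        m <- decode_subset(pos[i, ], cfg$decode_threshold)
        f <- score(m)
        if (f$composite > pbest_fit[[i]]$composite) {
          pbest_fit[[i]] <- f
          pbest_pos[i, ] <- pos[i, ]
        }
        if (f$composite > gbest_fit$composite) {
          gbest_fit <- f
          gbest_pos <- pos[i, ]
          gbest_mask <- m
        }
      }
      stall <- if (gbest_fit$composite > gbest_before) 0L else stall + 1L
      if (cfg$stall_refine > 0 && stall >= cfg$stall_refine) {
        # memetic refinement: try every single-bit flip of the global-best
        # mask and adopt the best strict improvement
        best_flip <- NULL
        for (j in seq_len(D)) {
          m <- gbest_mask
          m[j] <- !m[j]
          if (!any(m)) next
          f <- score(m)
          if (f$composite > gbest_fit$composite &&
              (is.null(best_flip) || f$composite > best_flip$fit$composite)) {
            best_flip <- list(fit = f, mask = m)
          }
        }
        if (!is.null(best_flip)) {
          gbest_fit <- best_flip$fit
          gbest_mask <- best_flip$mask
          gbest_pos <- as.numeric(gbest_mask)
        }
        stall <- 0L
      }
      hist[[t + 1]] <- dplyr::bind_cols(tibble::tibble(iteration = t), gbest_fit)
    }
    list(gbest_fit = gbest_fit, gbest_mask = gbest_mask,
         history = dplyr::bind_rows(hist))
  })

  structure(list(selected_genes = candidates[result$gbest_mask],
                 mask = result$gbest_mask,
                 fitness = result$gbest_fit,
                 history = result$history,
                 candidates = candidates,
                 swarm = cfg, mlp = mlp, eval = eval),
            class = "pso_selection")
}

#' @export
print.pso_selection <- function(x, ...) {
  cat("<pso_selection> ", length(x$selected_genes), " of ",
      length(x$candidates), " candidate genes selected\n", sep = "")
  cat("  composite fitness ", signif(x$fitness$composite, 5),
      " (accuracy ", signif(x$fitness$accuracy, 4),
      ", mse ", signif(x$fitness$mse, 4), ")\n", sep = "")
  cat("  genes: ", paste(head(x$selected_genes, 10), collapse = ", "),
      if (length(x$selected_genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy the per-iteration global-best fitness trace
#'
#' @param x A `pso_selection`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `accuracy`, `mse`, `subset_size`,
#'   `composite` (the global best after each iteration; iteration 0 is the
#'   initial swarm).
#' @method tidy pso_selection
#' @export
tidy.pso_selection <- function(x, ...) x$history

#' @rdname tidy.pso_selection
#' @method glance pso_selection
#' @export
glance.pso_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_candidates = length(x$candidates),
                   n_selected = length(x$selected_genes),
                   n_iterations = x$swarm$n_iterations),
    x$fitness
  )
}

#' Plot the swarm's convergence trace
#'
#' @param object A `pso_selection`.
#' @param ... Unused.
#' @return A ggplot of the global-best composite fitness by iteration.
#' @method autoplot pso_selection
#' @export
autoplot.pso_selection <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$composite)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Global-best composite fitness",
                  title = "Particle-swarm convergence") +
    ggplot2::theme_minimal()
}

#' Write wrapper outputs: fitness history and selected genes
#'
#' `fitness_history.tsv` has columns iteration, gbest_composite, gbest_acc,
#' gbest_mse, gbest_size; `selected_genes.txt` has one gene id per line.
#'
#' @param selection A `pso_selection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_selection <- function(selection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hist <- tibble::tibble(
    iteration = selection$history$iteration,
    gbest_composite = sprintf("%.10g", selection$history$composite),
    gbest_acc = sprintf("%.10g", selection$history$accuracy),
    gbest_mse = sprintf("%.10g", selection$history$mse),
    gbest_size = selection$history$subset_size
  )
  readr::write_tsv(hist, file.path(dir, "fitness_history.tsv"))
  writeLines(selection$selected_genes, file.path(dir, "selected_genes.txt"))
  invisible(dir)
}
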