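# The ten benchmark classifier families. Each entry fits on a training
# matrix and returns held-out scores (probability-like, larger = more
# likely class 1) and hard 0/1 labels. Hyperparameters are the pinned
# library defaults from inst/config/benchmark_defaults.yaml; no tuning.
#
# The "lightgbm" family is leaf-wise histogram gradient boosting,
# implemented with xgboost's lossguide grower (tree_method = "hist",
# grow_policy = "lossguide", max_leaves = 31).

benchmark_model_names <- function() {
  c("xgboost", "lightgbm", "random_forest", "extra_trees", "gaussian_nb",
    "knn", "logistic_regression", "decision_tree", "svm", "lda")
}

#' Pinned hyperparameters of the benchmark model families
#'
#' Reads the versioned defaults shipped with the package
#' (`inst/config/benchmark_defaults.yaml`), so every report is reproducible
#' against a recorded configuration.
#'
#' @return Named list: one parameter list per model family.
#' @export
benchmark_models <- function() {
  path <- system.file("config", "benchmark_defaults.yaml", package = "genesift")
  yaml::read_yaml(path)
}

# Fit one family on (x_tr, y_tr) and score x_te.
# Returns list(score = numeric, label = integer). `seed` controls any
# fit-time randomness so reports are reproducible.
fit_and_score <- function(model_name, x_tr, y_tr, x_te, params, seed) {
  withr::with_seed(seed, {
    switch(
      model_name,
      xgboost = {
        fit <- xgboost::xgboost(
          x_tr, factor(y_tr, c(0, 1)),
          nrounds = params$nrounds, max_depth = params$max_depth,
          learning_rate = params$eta, nthreads = 1, verbosity = 0
        )
        s <- predict(fit, x_te, type = "response")
        list(score = s, label = as.integer(s >= 0.5))
      },
      lightgbm = {
        fit <- xgboost::xgboost(
          x_tr, factor(y_tr, c(0, 1)),
          nrounds = params$nrounds, learning_rate = params$eta,
          tree_method = "hist", grow_policy = "lossguide",
          max_depth = 0, max_leaves = params$max_leaves,
          nthreads = 1, verbosity = 0
        )
        s <- predict(fit, x_te, type = "response")
        list(score = s, label = as.integer(s >= 0.5))
      },
      random_forest = {
        fit <- randomForest::randomForest(x = x_tr, y = factor(y_tr, c(0, 1)),
                                          ntree = params$ntree)
        s <- predict(fit, x_te, type = "prob")[, "1"]
        list(score = s, label = as.integer(s >= 0.5))
      },
      extra_trees = {
        df_tr <- as.data.frame(x_tr)
        fit <- ranger::ranger(
          x = df_tr, y = factor(y_tr, c(0, 1)),
          num.trees = params$num_trees, splitrule = "extratrees",
          num.random.splits = 1, probability = TRUE,
          num.threads = 1, seed = seed
        )
        s <- predict(fit, data = as.data.frame(x_te),
                     num.threads = 1)$predictions[, "1"]
        list(score = s, label = as.integer(s >= 0.5))
      },
      gaussian_nb = {
        fit <- e1071::naiveBayes(x = as.data.frame(x_tr),
                                 y = factor(y_tr, c(0, 1)))
        s <- predict(fit, as.data.frame(x_te), type = "raw")[, "1"]
        list(score = s, label = as.integer(s >= 0.5))
      },
      knn = {
        pred <- class::knn(train = x_tr, test = x_te,
                           cl = factor(y_tr, c(0, 1)), k = params$k,
                           prob = TRUE)
        win <- attr(pred, "prob")
        s <- ifelse(pred == "1", win, 1 - win)
        list(score = s, label = as.integer(as.character(pred)))
      },
      logistic_regression = {
        # L2-regularized logistic regression (ridge penalty 1/n), the
        # standard regularized default for p >> n expression data
        fit <- glmnet::glmnet(x_tr, factor(y_tr, c(0, 1)),
                              family = "binomial", alpha = 0,
                              lambda = params$lambda_scale / nrow(x_tr))
        s <- as.vector(predict(fit, x_te, type = "response"))
        list(score = s, label = as.integer(s >= 0.5))
      },
      decision_tree = {
        df <- data.frame(x_tr, check.names = FALSE)
        df$.y <- factor(y_tr, c(0, 1))
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(cp = params$cp))
        s <- predict(fit, data.frame(x_te, check.names = FALSE))[, "1"]
        list(score = s, label = as.integer(s >= 0.5))
      },
      svm = {
        fit <- e1071::svm(x = x_tr, y = factor(y_tr, c(0, 1)),
                          kernel = params$kernel, cost = params$cost,
                          scale = apply(x_tr, 2, sd) > 0)
        pred <- predict(fit, x_te, decision.values = TRUE)
        dv <- as.vector(attr(pred, "decision.values"))
        # orient the decision value toward class 1
        if (!startsWith(colnames(attr(pred, "decision.values"))[1], "1")) dv <- -dv
        list(score = dv, label = as.integer(as.character(pred)))
      },
      lda = {
        fit <- suppressWarnings(MASS::lda(x_tr, grouping = factor(y_tr, c(0, 1))))
        pr <- predict(fit, x_te)
        s <- pr$posterior[, "1"]
        list(score = s, label = as.integer(s >= 0.5))
      },
      stop("unknown model name: ", model_name, call. = FALSE)
    )
  })
}
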