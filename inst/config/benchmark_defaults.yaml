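# Pinned hyperparameters for the ten benchmark classifier families.
# Values are the widely used library defaults; edits here change every
# benchmark report, so treat this file as versioned configuration.
xgboost:
  nrounds: 100
  max_depth: 6
  eta: 0.3
lightgbm:            # leaf-wise histogram gradient boosting (lossguide)
  nrounds: 100
  eta: 0.1
  max_leaves: 31
random_forest:
  ntree: 500
extra_trees:
  num_trees: 500
gaussian_nb: {}
knn:
  k: 5
logistic_regression: # ridge-penalized; lambda = lambda_scale / n_train
  lambda_scale: 1.0
decision_tree:
  cp: 0.01
svm:
  kernel: radial
  cost: 1.0
lda: {}
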