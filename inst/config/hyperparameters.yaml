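# Randomized-search spaces per architecture. Types:
#   int        - uniform integer in [min, max]
#   uniform    - uniform real in [min, max]
#   loguniform - exp(uniform(log(min), log(max)))
#   choice     - uniform over 'values'
rf:
  num.trees: {type: int, min: 100, max: 500}
  mtry_frac: {type: uniform, min: 0.15, max: 0.9}
  min.node.size: {type: int, min: 1, max: 20}
gbt:
  nrounds: {type: int, min: 30, max: 250}
  eta: {type: loguniform, min: 0.02, max: 0.4}
  max_depth: {type: int, min: 2, max: 8}
  subsample: {type: uniform, min: 0.5, max: 1.0}
  colsample_bytree: {type: uniform, min: 0.5, max: 1.0}
cart:
  cp: {type: loguniform, min: 0.0001, max: 0.05}
  minsplit: {type: int, min: 5, max: 40}
  maxdepth: {type: int, min: 2, max: 30}
multinom:
  decay: {type: loguniform, min: 0.00001, max: 1.0}
glmnet:
  alpha: {type: uniform, min: 0.0, max: 1.0}
  lambda: {type: loguniform, min: 0.00001, max: 0.5}
svm_rbf:
  cost: {type: loguniform, min: 0.1, max: 100}
  gamma: {type: loguniform, min: 0.001, max: 1.0}
naive_bayes:
  laplace: {type: uniform, min: 0.0, max: 2.0}
lda: {}
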