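Package: txensemble
Title: Ensemble Meta-Classification of Differential Isoform Expression Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the heterogeneous per-transcript significance outputs of
    multiple differential isoform expression analysis (DIEA) tools -- p-values
    and q-values, posterior probabilities of differential expression (PPDE),
    and probabilities of positive log ratio (PPLR) -- into a single
    machine-learning meta-prediction of differential expression. Provides
    score harmonization into a common feature matrix, a from-scratch rotation
    forest alongside unified wrappers for support vector machines, random
    forest and gradient-boosted trees, random hyperparameter grid search with
    stratified cross-validation, a score-level simulator of six heterogeneous
    DIEA pipelines with known ground truth, a full evaluation suite (accuracy,
    sensitivity, specificity, NPV, PPV, AUC, directional true-positive rates)
    and rank aggregation for comparing methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
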