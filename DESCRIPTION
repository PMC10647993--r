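Package: prmct
Title: Parametric Response Mapping of Paired Inspiratory-Expiratory CT with
    Machine-Learning Spirometry Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies functional small-airways disease (fSAD) and emphysema
    from paired inspiratory/expiratory chest CT by parametric response mapping
    (PRM): deformable alignment of the expiratory scan onto the inspiratory
    grid, voxel-wise classification against the -950/-856 HU thresholds, and
    aggregation of 72 regional volume and volume-percentage parameters over
    whole lung, left and right lung, and the five lobes. Random-forest and
    multilayer-perceptron regressors map the 72 PRM parameters plus four
    clinical covariates to FEV1/FVC and FEV1 percent predicted; rule-based
    staging assigns normal, high-risk, and COPD (GOLD I-IV) labels from
    measured or predicted spirometry. Includes a paired-breath phantom and
    cohort simulator with voxel-level ground truth, and an evaluation suite
    (R-squared, MAE, MSE, RMSE, Spearman correlation, confusion matrices with
    sensitivity, specificity, PPV, NPV and accuracy).
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    nnet,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
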