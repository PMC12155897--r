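Package: desopt
Title: Design-of-Experiments Optimization of Extraction Processes with
    Response Surfaces and Neural-Network Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing natural-product extraction conditions from
    small designed experiments. Builds three-factor Box-Behnken designs,
    fits full second-order response-surface models in coded units with a
    Type-III ANOVA including the lack-of-fit/pure-error partition, and
    locates surface optima both as stationary points and as box-constrained
    maxima. In parallel it trains a small feed-forward neural-network
    surrogate (tansig hidden layer, linear output) by Levenberg-Marquardt
    with validation-based early stopping, and maximizes the surrogate with
    a real-coded genetic algorithm. Includes model-comparison metrics
    (R-squared, MSE, RMSE, absolute average deviation), calculators for
    Folin-Ciocalteu total-phenolics yield and ORAC Trolox equivalence from
    fluorescence-decay kinetics, and synthetic-data generators with known
    ground truth for end-to-end validation. Ships a 17-run ultrasound/
    deep-eutectic-solvent polyphenol-extraction dataset used throughout the
    documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
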