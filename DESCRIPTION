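Package: tinnitraj
Title: Latent-Class Trajectory Analysis of Daily Tinnitus Symptom Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for uncovering latent trajectory classes in daily
    ecological momentary assessment (EMA) diaries collected during tinnitus
    treatment. Simulates realistic EMA panels with known latent-class
    structure, preprocesses long-format diaries (compliance filtering,
    seven-day moving averages, robust outlier screening, missingness
    accounting), fits latent-class linear mixed models with natural cubic
    spline mean trajectories and a shared random intercept by multi-start
    EM, enumerates and triangulates the number of classes (AIC, BIC,
    relative entropy, posterior probability of membership), contrasts
    classes on baseline and outcome variables with Holm-adjusted tests and
    minimal clinically important differences, and computes symptom-dynamics
    summaries such as weekly within-class correlations and the
    intra-individually standardized loudness-distress difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
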