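Package: choicetrace
Title: Choice Traces from Repetition-Suppression MEG Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering millisecond-resolved "choice traces" from
    trial-locked source-space MEG signals in a context-dependent random-dot
    decision task that uses repetition suppression to isolate feature-tuned
    subpopulations. Provides balanced task schedules and regressor codings,
    a synthetic epoch and behaviour generator with known ground truth,
    sliding-window ridge regression with inner cross-validation and trial
    subsampling, permutation inference on shuffled design matrices,
    leave-one-subject-out peak-latency estimation, repeated-measures ANOVA
    with partial eta squared and Hedges' g effect sizes, behavioural log-RT,
    accuracy and psychometric regressions, and residualized nested
    cross-validated decoding of relevant and irrelevant input strength.
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
    grid,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
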