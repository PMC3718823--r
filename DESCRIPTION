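Package: coged
Title: Cognitive Effort Discounting: Task Generation, Titration, and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the cognitive effort discounting (COG-ED) paradigm, in
    which participants trade a low-effort task for less money against a
    high-effort N-back task for more money. Provides constrained N-back
    stimulus-list generation with target and lure placement, signal-detection
    scoring (d-prime), the adjusting-amount staircase that titrates offers to
    indifference points, subjective-value and area-under-the-curve discounting
    metrics for effort and delay, synthetic choice agents for closed-loop
    simulation and parameter recovery, random-intercept multilevel models of
    subjective value (with an optional anchored reference level and
    age-heterogeneous residual variance), and an end-to-end simulation
    pipeline with reproducible CSV/JSON artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
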