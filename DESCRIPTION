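Package: reachopt
Title: Optimal Control of a Two-Muscle Elbow Model for Muscle-Ageing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates rapid point-to-point elbow movements driven by an
    antagonistic pair of Hill-type muscles and finds excitation schedules
    that minimise cumulative squared positional error by direct shooting
    with exact adjoint gradients. Provides factorial sweeps over
    ageing-related muscle parameters (peak force, maximum strain rate,
    activation and deactivation time constants, parallel passive
    stiffness), performance and coactivation metrics per solution,
    min-range-normalised importance regression with pairwise interactions,
    and a bisection locator for the stiffness-neutral deactivation time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
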