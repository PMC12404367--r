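Package: narhmm
Title: Behavioural-State Analysis of Duty-Cycled Marine Mammal Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring behavioural states from duty-cycled Argos
    satellite telemetry and binned dive (time-at-depth) data of deep-diving
    cetaceans. Provides a continuous-time correlated random walk (integrated
    Ornstein-Uhlenbeck) Kalman filter/smoother for regularizing error-prone,
    temporally-irregular locations; construction of six movement and dive data
    streams on 6-hour analysis steps; a 3-state hidden Markov model with
    covariate-dependent gamma and Weibull emission distributions (including a
    zero-mass component for time-at-depth) and multinomial-logit transition
    probabilities; Viterbi decoding and covariate-dependent stationary state
    probabilities; and gridded spatial summaries including the
    disproportionate-state statistic. A synthetic-data generator emulating the
    duty-cycled telemetry structure supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
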