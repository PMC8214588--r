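Package: markovboot
Title: Markov Cohort Cost-Utility Analysis with Bootstrap Probabilistic
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cost-utility analysis of add-on nabiximols (Sativex) oromucosal
    spray versus standard spasticity care in multiple sclerosis, using a
    seven-state Markov cohort model run over 65 cycles of 28 days. Transition
    probabilities and state utilities are estimated from patient-level trial
    data (numerical rating scale severity trajectories and concurrent
    utility observations); standard-of-care resource use is costed from a
    Delphi expert panel and a unit-cost tariff table. Parameter uncertainty
    is propagated by a stratified bootstrap of the patient-level and panel
    data, which preserves the correlation structure of the source data, and
    a conventional independent-parameter Monte Carlo engine is provided as a
    comparator. Includes a synthetic trial-data generator with known ground
    truth, the three published analysis scenarios, and cost-effectiveness
    plane summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
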