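Package: psmsr
Title: Phenotypic Switching and Stress-Response Dynamics of Drug-Sensitive
    and Drug-Tolerant Cancer Cell Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits an ordinary-differential-equation model of
    co-cultured cisplatin-sensitive and cisplatin-tolerant non-small-cell
    lung cancer cell populations in which a hidden stress variable, generated
    by sensitive-cell growth and removed by tolerant cells, suppresses growth
    and drives reversible phenotypic switching between the two states
    (the phenotype switch model with stress response, PSMSR). Provides
    lineage-resolved simulation of fluorescence-labelled co-culture
    experiments at arbitrary seeding ratios and cisplatin dosing schedules
    with an exposure (AUC) dependent sigmoidal kill term, a native real-valued
    genetic algorithm with profile-likelihood confidence intervals for
    parameter estimation from growth curves, extraction of time-varying
    game-theoretic payoff coefficients by moving-window competitive
    Lotka-Volterra fits, a synthetic live-imaging data generator, and
    continuous versus intermittent therapy regimen simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
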