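Package: circadeg
Title: Rhythmic Degradation of Circadian Proteins from Steady Proteolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulates and analyses the spontaneous emergence of rhythmic
    degradation rates in circadian proteins under constant (non-rhythmic)
    proteolytic machinery. Provides mass-action ordinary differential equation
    models of ubiquitination-mediated degradation with and without prior
    phosphorylation (mono- and multisite), multi-route and realistic PER2
    variants, a profile-constrained simulation technique that holds the protein
    abundance waveform fixed while screening biological feasibility,
    quasi-steady-state closed-form approximations of the degradation rate with
    validity-condition checking, proteosynthetic cost accounting and its
    waveform lower bounds, an empirical fitting pipeline (splines, empirical
    degradation-rate profiles, uniform parameter scans, Nelder-Mead
    optimization of profile similarity or cost), proteome-scale cost analysis
    under truncated power-law abundance distributions, four randomization-based
    significance tests, and synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
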