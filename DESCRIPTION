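Package: kvclamp
Title: Voltage-Clamp Simulation and Biophysical Characterization of
    Voltage-Gated Potassium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates episodic voltage-clamp recordings (step families,
    steady-state inactivation pre-pulse protocols, isochronal tail and
    deactivation protocols, P/N leak subtraction) from parametric
    Hodgkin-Huxley-style gating models of Shaker-family potassium channels,
    and implements the standard electrophysiology analysis pipeline on top of
    them: Boltzmann conductance-voltage and steady-state-inactivation fits,
    single- and double-exponential kinetics, the sigmoidal activation-delay
    statistic, isochronal tail-current conductance measurement, deactivation
    time-constant/voltage curves, heteromer pre-pulse subtraction and
    phenotype classification, plus a Class I PDZ-binding-motif scanner for
    channel C-termini. Ships a fixtures registry of six sea-anemone Shaker
    channel parameter sets and regulatory-subunit heteromer presets, and a
    one-command harness that recovers the configured gating parameters
    end-to-end from simulated recordings.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
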