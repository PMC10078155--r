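Package: mepdsim
Title: Amygdala Modulation of the GnRH Pulse Generator: Models and LH Pulse Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field model of the arcuate KNDy (kisspeptin/neurokinin
    B/dynorphin) population acting as the GnRH pulse generator, coupled to a
    firing-rate model of the posterodorsal medial amygdala (MePD) circuit in
    which kisspeptin drives a GABA-GABA disinhibitory chain and glutamatergic
    pathways. Includes receptor-antagonist conditions (GABA-A, GABA-B,
    ionotropic glutamate blockade), optogenetic stimulation protocols, an
    input-scan utility exposing the bifurcation structure that terminates
    pulsatility above an upper input threshold, a synthetic luteinising
    hormone (LH) blood-sampling generator (gamma-renewal pulse trains,
    exponential clearance, multiplicative assay noise), and a pulse-detection
    and interpulse-interval analysis pipeline with censoring and per-arm
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
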