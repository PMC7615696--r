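Package: nvcgaba
Title: Neurovascular Coupling Model of GABAergic Interneuron Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic kinetic model of neurovascular coupling driven by
    GABAergic interneurons. Couples GABA, neuropeptide Y (NPY) and glutamate
    state equations -- with nitric-oxide-inhibited GABA transaminase and
    GABA-gated chloride channels -- to a reduced electro-vascular stage
    (potassium relay, smooth-muscle membrane potential, NPY-modulated
    voltage-operated calcium channel, arteriolar radius) and a Buxton balloon
    hemodynamics stage. Simulates whisker and optogenetic stimulation
    protocols with and without NOS blockade (L-NAME) and returns fractional
    oxy-, deoxy- and total-haemoglobin time series, plus synthetic reference
    traces and trace-comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
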