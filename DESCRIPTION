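Package: tumorca
Title: Multiscale Cellular-Automaton Model of Avascular Tumor Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic two-dimensional cellular-automaton simulator of avascular
    tumor growth coupled to five diffusing metabolic fields (oxygen, glucose,
    hydrogen ions, growth factor, inhibitory factor). Cells occupy one of four
    states (normal/empty, proliferating, quiescent, necrotic) and respond to
    microenvironmental oxygen, glucose and pH thresholds; metabolite transport
    uses a shifting block-cellular-automata averaging scheme; stochastic mitosis
    distinguishes mutant and nonmutant phenotypes through the switching
    probability Nmm. Provides tumor geometry and population metrics (growth and
    necrotic fractions, critical point, radius, normalized volume, pH and oxygen
    layer stratification), replicate experiments, and Nmm parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
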