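Package: serosim
Title: Kinetic Modelling of Serotonin Varicosity Dynamics and Virtual Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic kinetic model of a serotonin varicosity:
    tryptophan uptake and serotonin synthesis, vesicular storage, stimulated
    release shaped by a serotonin-binding-protein kernel, SERT reuptake,
    thresholded glial Uptake 2, and G-protein/RGS dynamics of the 5HT1B
    autoreceptor and the histamine H3 receptor.  Provides stiff ODE
    simulation, self-consistent steady-state solving with closed-form
    receptor equilibria, stimulation-response presets, in-silico tryptophan
    and meal experiments, and a systems population layer that samples
    virtual individuals by varying expression-level parameters and
    summarizes the resulting distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
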