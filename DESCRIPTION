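Package: stemkinetics
Title: Compartmental Kinetic Modeling of Radiotracer Transport in Plant Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing dynamic PET time-activity curves of a
    radiotracer bolus (such as [18F]fluoride) administered at a cut petiole
    and advected up a plant stem. Implements a single-parameter free/trapped
    compartment model with irreversible trapping, solves the trapping rate
    per unit time (sv) from a late-time final condition, estimates transport
    velocity from truncated mean arrival times of the free tracer at several
    stem positions, derives the trapping probability per unit stem length
    (s = sv/V), and aggregates results across plants. Includes a forward
    simulator of bolus transport with irreversible trapping observed through
    a PET frame schedule with counting noise, used for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
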