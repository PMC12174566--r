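Package: amtsim
Title: Colored Petri Net Simulation of Acupuncture and Moxibustion
    Treatment Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of organ-network dynamics under
    acupuncture and moxibustion treatment (AMT). Provides a minimal colored
    Petri net engine with typed tokens, guards, inhibitor arcs and seeded
    execution; a token-guided transition control (TGTC) layer that compiles
    series-parallel schedules into control places and arcs so transitions
    fire in exactly the admissible orders; the Five-Elements organ model
    (generation and restriction among the five viscera, exterior-interior
    viscera-bowel coupling, acupoint stimulation, and qi-blood-fluid
    generation, transport and absorption); a WHO-notation meridian and
    acupoint registry; a multicriteria treatment score (in-range time ratio,
    windowed RMSD indicator, reference-envelope similarity); and a
    randomized protocol explorer with batch screening. Ships the Meniere's
    disease case study as a worked fixture set and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
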