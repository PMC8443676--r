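Package: plasmidecology
Title: Ecological and Metapopulation Models of Parasitic Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic models of costly, infectiously
    transferred ("parasitic") plasmids. Provides chemostat-style ODE models of
    conjugative and transformative plasmid spread with analytic invasion
    thresholds, copy-number optimization, equilibrium and stability analysis,
    and phase diagrams; co-infection dynamics for multiple compatible plasmid
    types with binomial and Poisson-binomial reference distributions; a
    Wright-Fisher metapopulation model of plasmid acquisition under
    configurable plasmid-plasmid epistasis, with analytic stationary
    distributions of unique plasmid types per genome; least-squares fitting of
    those stationary distributions to observed plasmid-count histograms; and
    utilities to derive such histograms from assembly-summary-like replicon
    tables, including a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    lhs
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
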