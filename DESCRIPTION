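Package: lulcsim
Title: Markov-Cellular Automata Modeling of Land Use and Land Cover Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit analysis and simulation of land use/land
    cover change (LULCC) on categorical raster landscapes. Estimates Markov
    transition matrices from classified maps, annualizes them by
    eigendecomposition, screens continuous change drivers with Cramer's V,
    fits Weights-of-Evidence transition-probability surfaces, allocates the
    demanded change with a stochastic cellular automaton (patcher/expander
    patch dynamics and per-step dynamic driver updates), projects
    stationary, optimistic and pessimistic scenarios to a target year, and
    validates simulated maps against references with the kappa coefficient
    and a multi-window fuzzy similarity index. A synthetic-landscape
    generator with known transition and driver-effect parameters supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
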