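Package: regenscan
Title: Detecting Historic Limb Loss and Regeneration Trade-Offs from
    Crab Morphometrics
Version: 0.1.0
Authors@R:
    person("Regenscan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting historic, partially regenerated limb loss
    in crabs from cross-sectional morphometric data, and for quantifying
    the energetic trade-offs that regeneration imposes on reproduction,
    energy storage and growth. Per-limb power-law allometries (mass =
    a * CW^b) are fitted by nonlinear least squares; limbs whose residual
    mass falls below a negative cutoff are classified as regenerating and
    their summed dry mass forms a per-crab regeneration index. Trade-offs
    are inferred with generalized additive models (mgcv) using the counts
    of missing limbs, Poisson-decorrelated limb-bud counts and the
    regeneration index as parametric terms alongside smooths of carapace
    width and Julian sampling day. A synthetic-population generator with a
    ground-truth table makes every stage testable without field data, and
    a command-line pipeline ties the stages into a reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
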