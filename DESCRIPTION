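Package: mesobuffer
Title: Buffer-Specific Analysis of Ionizable Lipid Mesophases and
    Transfection Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how preparation buffers shift the pH-dependent
    phase behaviour of ionizable lipid mesophases and the expression kinetics
    of lipid nanoparticle (LNP) transfection. Implements closed-form polyprotic
    buffer speciation, mean valency and ionic strength (Henderson-Hasselbalch,
    sodium counterions by electroneutrality); identification of lyotropic
    liquid-crystalline phases (inverse hexagonal, Fd3m and P63/mmc micellar,
    disordered micellar, bicontinuous cubics) from 1D small-angle X-ray
    scattering profiles by relative Bragg peak positions, with lattice-constant
    fits, coexisting-phase decomposition and nearest-neighbor distances; a
    Helfrich bending-energy model of the inverse micellar to inverse hexagonal
    competition with pH-dependent headgroup charging; single-cell GFP
    expression summaries (onset time, area under the curve, relative
    efficiency); seeded synthetic-data generators for SAXS profiles and
    expression trajectories; and phase-diagram assembly with transition-pH
    extraction.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
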