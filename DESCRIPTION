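Package: helisteps
Title: Single-Molecule Stepping Analysis for Hairpin-Unwinding Helicases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule optical-tweezers traces of helicases
    processing a DNA hairpin at constant force. Provides a kinetic Monte-Carlo
    generator for unwinding and re-zipping traces under a delayed
    strand-release (looping) mechanism, chi-square iterative step detection
    with per-dwell position and uncertainty estimation, error-weighted kernel
    density estimation of step-size distributions with bootstrap significance
    bands, dwell-time kinetics including the n_min (inverse randomness)
    statistic and Michaelis-Menten fits, worm-like-chain DNA mechanics with
    nearest-neighbor hairpin thermodynamics, and the convolution model that
    predicts step sizes from independent 3' and 5' strand-release
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
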