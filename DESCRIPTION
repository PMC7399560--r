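Package: origamiLC
Title: Cholesteric Order from Conformational Fluctuations of DNA Origami Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to trace macroscopic cholesteric liquid-crystal observables of
    DNA-origami-like filaments back to their conformational statistics. The package
    generates or imports ensembles of fluctuating six-helix-bundle conformations
    (wormlike-chain backbone fluctuations, prescribed axial twist, optional solenoidal
    bias), measures backbone helicity spectra from transverse Fourier cross-correlations,
    duplex twist densities and the local polar writhe of the filament centerline, and
    feeds conformationally averaged pair interactions into an extended Onsager
    second-virial density functional to obtain the equilibrium orientation distribution,
    the Frank twist modulus, the chiral strength, the cholesteric pitch, and
    isotropic-cholesteric coexistence concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
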