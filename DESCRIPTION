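Package: rafttrace
Title: Imaging FCS Diffusion-Law Analysis and Acyl-Chain Conformer Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for camera-based (TIRF) imaging fluorescence correlation
    spectroscopy: temporal autocorrelation of pixel intensity traces at
    multiple software binnings, nonlinear fitting of the imaging-FCS
    autocorrelation model to obtain diffusion coefficients and particle
    numbers, and the FCS diffusion law (diffusion time versus effective
    observation area) whose intercept classifies membrane diffusion as free,
    domain-confined or hop diffusion. Includes a Brownian-dynamics simulator
    of free, domain-confined and meshwork-hop diffusion rendered through a
    Gaussian point-spread function onto an EMCCD camera model, and a
    conformer toolkit that parses fatty-acid ligands from PDB files,
    superposes them on a reference by least-squares rigid-body fitting over
    carbon atoms, and summarises conformational closeness as a binned,
    dataset-size-normalised RMSD distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    tiff,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
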