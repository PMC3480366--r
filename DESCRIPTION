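Package: texdiv
Title: Multiresolution Texture Signatures for Species Richness and Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical multiresolution texture analysis of single-band
    satellite image windows for monitoring plant biodiversity. Detail
    subbands of an orthogonal wavelet decomposition are modelled as
    generalized Gaussian samples; windows are compared through the
    closed-form symmetrized Kullback-Leibler divergence between their
    per-subband models (a proxy of species turnover, beta diversity),
    while pixel-intensity Shannon entropy serves as a proxy of local
    species richness (alpha diversity). Includes occurrence-table
    gridding with Jaccard turnover, calibration of image statistics
    against measured diversity, and seeded synthetic generators
    (textures with known subband laws, blob cloud masks, multi-period
    landscapes with controlled turnover) so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
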