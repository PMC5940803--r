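Package: mechanoquant
Title: Quantification of Cell and Tissue Mechanics from Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how substrate stiffness shapes cell
    behaviour: Hertz-model fitting of atomic force microscopy (AFM)
    force-indentation curves and force-map assembly, traction force
    microscopy by multi-pass particle image velocimetry (PIV) and
    Tikhonov-regularized Fourier-transform traction cytometry (FTTC),
    cell-track motility metrics and durotactic turn angles, spheroid
    disaggregation quantification, and fluorescence-image morphometry
    (focal adhesions, Manders and Pearson colocalization, nuclear to
    cytoplasmic ratios). Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes, so the whole
    analysis chain can be validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pracma,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
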