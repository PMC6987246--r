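Package: dmriqc
Title: Slice-Wise Artifact Detection and Quality Control for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated quality control for 4D diffusion MRI volumes.
    Extracts axial and sagittal slice sets with peripheral-slice exclusion
    rules, trains independent per-view slice classifiers (a compact
    convolutional network trained with RMSprop, or a transfer-learning head
    over a frozen backbone), and produces slice-wise and volume-wise QC
    reports with slice-count threshold sweeps and an inspection-workload
    reduction estimator. Includes classical texture baselines (Gabor filter
    bank, Zernike moments, uniform local binary patterns with random
    forests; Gabor features into a fully connected network; CNN features
    into PCA and an SVM) and a physics-based synthetic artifact simulator
    (Nyquist ghosting, herringbone spikes, chemical shift, susceptibility
    distortion, motion dropout, multiband interleave banding) over
    ellipsoid head phantoms with Rician noise, so that every stage is
    trainable and testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
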