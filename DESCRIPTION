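Package: fetalT2star
Title: Real-Time Style T2* Relaxometry for the Fetal Brain and Placenta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxelwise monoexponential T2* mapping of multi-echo gradient-echo
    volumes with organ-masked quantification for fetal brain and placenta,
    gestational-age normative curves with quantile-regression centiles and
    low/normal/high classification, and a robustness battery (repeat
    agreement, Bland-Altman, Dice). Includes a synthetic uterine phantom
    generator with ground-truth masks, noise, contraction and motion
    confounds, and a command-line interface over the full flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    quantreg,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
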