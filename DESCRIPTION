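Package: meniscusqmri
Title: Response-to-Loading Analysis of Meniscus Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ex-vivo stress-MRI analysis pipeline for human meniscus
    samples. Simulates degeneration-graded, load-deformed meniscus cross
    sections with multi-contrast magnitude MRI signal stacks and
    unconfined-compression stress-strain curves; fits voxelwise T1
    (inversion recovery), T1rho (spin lock) and T2 (multi-echo) relaxation
    maps; partitions segmentation masks into apex, intermediate and base
    zones by mediolateral thirds; computes region-of-interest medians and
    relative response-to-loading changes (Delta1/Delta2); fits the
    two-parameter exponential hyperelastic model and evaluates the tangent
    Elastic Modulus; scores histological degeneration on the Pauli scale;
    and runs the grade-wise, load-wise and correlation statistics plan.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
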