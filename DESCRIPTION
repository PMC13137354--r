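Package: hemofuse
Title: Desk-Scale Multimodal Image-Text Fusion for Intracranial Hemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Synthetic brain phantoms with subtype-specific hemorrhage lesions
    and simulated temporal progression, entropy-adaptive contrast enhancement
    (modified CLAHE with entropy-derived clip limits, gamma correction and
    unsharp sharpening), templated clinical narratives with sentiment lexicons,
    toy vision-transformer and WordPiece text embeddings, cross-attention
    multimodal fusion with early/late/joint strategies, a pufferfish-style
    metaheuristic for patch-size selection, image-quality and classification
    metric suites, and structured prognosis/therapeutic sentiment reports.
    Everything runs on synthetic data on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
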