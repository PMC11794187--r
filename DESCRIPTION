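Package: longandet
Title: Lightweight Single-Stage Detector Construction Kit for Fruit-Cluster Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Building blocks and a full assembly of a lightweight anchor-free
    single-stage object detector for clustered fruit in orchard imagery. Provides
    pooling-fusion channel attention (AMA), a densely connected backbone stage
    (DenseAMA), partial-convolution cross-stage blocks (C2f-Faster-AMA), a
    slim-neck cross-stage block (VOVGSCSPC), the Inner-SIoU bounding-box
    regression loss with analytic gradients, exact parameter and FLOP
    accounting, seeded training on a built-in synthetic orchard-image
    generator, YOLO-format label input/output, augmentation and split
    protocols, and mean-average-precision evaluation. All network primitives
    run on a small reverse-mode automatic-differentiation tape over base-R
    arrays, so the package is self-contained and CPU-only.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: png, yaml, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
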