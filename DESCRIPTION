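Package: trapscan
Title: Tiled Detection, Duplicate Suppression and Counting for Sticky-Trap Insect Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting thrips on yellow sticky traps photographed as a
    lattice of overlapping smartphone captures. Models the 6 x 4 capture grid and
    its coordinate frames, resizes and splits captures into detector-sized tiles,
    reads and writes YOLO-format bounding-box annotations, transfers labels
    between superposable lighting datasets, and augments tiles. A synthetic
    scene generator draws traps with negative-binomially dispersed insect loads
    and a configurable noisy stub detector stands in for a trained network, so
    the whole pipeline can be exercised end to end: per-tile detections are
    mapped to the trap frame, duplicates arising from overlapping captures are
    suppressed by confidence-keeping connected-component clustering, per-class
    counts and a four-level intensity map are produced, and detector output is
    scored with IoU-matched precision, recall, average precision, mAP at 0.5,
    and actual-versus-predicted confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
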