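Package: flockwatch
Title: Video-Stream Detection of Aggressive Behavior in Group-Housed Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects aggressive behavior in group-housed sheep from
    surveillance-video object-detection streams. Per-frame bounding-box
    detections are stabilised by a quadrant/distance ordering heuristic and
    packed into fixed-length 600-dimensional vectors, assembled into
    frame-skipped one-second clip tensors, and classified by a long
    short-term memory (LSTM) network with a fully connected fusion head and
    sigmoid output trained with binary cross-entropy. Includes readers and
    writers for YOLO-style per-frame detection files and long-format CSV,
    precision/recall/F1 and ROC/AUC evaluation, and a synthetic flock
    simulator (calm random-walk motion versus pairwise charge-recoil
    aggression bouts with camera-like detection noise) so the full pipeline
    can be trained and tested without access to farm video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
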