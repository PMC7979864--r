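Package: beetrackr
Title: Markerless Detection and Tracking of Honey Bee Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and markerless tracking of honey bees on a natural
    honeycomb background. Point annotations are rendered into small
    segmentation targets encoding position, class (fully visible bee versus
    bee inside a comb cell) and body orientation; a compact recurrent
    encoder-decoder segmentation network (trained with a weighted 3-class
    cross-entropy and a circular orientation loss) converts images into dense
    detections; triplet-loss appearance embeddings and a greedy cost-based
    matching procedure link detections into individual trajectories through
    occlusions; colony-level sociometric statistics (circadian count
    periodicity, Rayleigh circular uniformity tests, bee-brood correlation,
    brood proximity) and per-trajectory motion metrics (speed, angular speed,
    motion span, diffusion coefficient, comb-cell visits, entrance
    enrichment) summarise the results. A synthetic-colony simulator with
    full ground truth makes every stage testable end to end.
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
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
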