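Package: ruminate
Title: Non-Contact Rumination Monitoring from Facial Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts per-frame nose/mouth keypoint trajectories of ruminating
    cattle into a chewing motion curve (the nose-mouth Euclidean distance),
    denoises it with a zero-phase low-pass (or median) filter, and counts
    chews by multi-condition threshold peak detection with a dynamic median
    threshold and a minimum inter-chew spacing. Reports the three session
    indicators used in welfare monitoring (chew count, rumination duration
    with rest bouts over three seconds excluded, and chewing frequency),
    implements keypoint-evaluation metrics (object keypoint similarity,
    average precision, mean average precision, precision, recall) and
    chew-count error statistics, and ships a synthetic trajectory generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
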