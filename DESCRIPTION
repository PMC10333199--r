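Package: rufatrack
Title: Automated-Telemetry Analysis of Red Knot Spring Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based analysis pipeline for coded VHF tag (Motus-style)
    detection data from migrating rufa red knots (Calidris canutus rufa).
    Filters false-positive detections using pulse-count, frequency-offset
    and burst-interval consistency rules; estimates departure dates as
    known dates or uncertainty-weighted day windows; classifies Delaware
    Bay use along the stopped/skipped spectrum; detects stopovers from
    detection spans at single stations or station clusters; extracts
    migratory flights with great-circle trajectory kinematics; and
    computes tailwind support from gridded surface winds. Includes a
    synthetic-data generator that produces complete study inputs with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
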