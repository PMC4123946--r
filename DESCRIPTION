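Package: lcctraj
Title: Land-Cover Trajectory Analysis for Tropical Deforestation and
    Regrowth Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing dated stacks of classified land-cover maps
    (mature forest, non-forest, secondary forest) from tropical deforestation
    frontiers. Implements temporal-consistency correction of disallowed
    transitions, per-pixel trajectory metrics (age of secondary forest,
    period of active land use, frequency of clearance), annualised
    deforestation and regrowth rates with period typologies, accuracy
    assessment with error matrices, and inverse (Tenenbein) calibration of
    class-area estimates. Includes a semi-Markov landscape simulator with
    known ground truth and confusion-matrix classification noise for
    end-to-end validation, plus bundled published accuracy and land-cover
    proportion tables from three Brazilian Amazon Landsat time-series sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
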