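Package: cuffwss
Title: Wall Shear Stress Metrics of Atherogenic Flow in Cuffed Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes six wall shear stress (WSS) metrics of atherogenic
    blood flow - time-averaged WSS (TAWSS), oscillatory shear index (OSI),
    relative residence time (RRT), transverse WSS (transWSS), shear stress
    angle deviation (SAD), and continuous low/high shear indices (LSI/HSI)
    with thresholds calibrated from a contralateral control vessel - over
    time-resolved WSS vector fields on triangulated lumen surfaces. Includes
    a quasi-steady pulsatile tube-flow simulator emulating the flow
    disturbances of the tapered-cuff mouse carotid model, four-region vessel
    segmentation, control-scaled cohort statistics, en-face map generation,
    and STL/CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
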