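Package: bulbflow
Title: Carotid Bulb Hemodynamic Biomarkers from Pulsatile Flow Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes hemodynamic biomarkers of pro-thrombotic flow in the
    carotid bifurcation bulb from time-resolved velocity fields on tetrahedral
    meshes: wall shear stress and shear rate, time-averaged WSS, oscillatory
    shear index (OSI), relative residence time, low-velocity volume fractions
    and flow stasis over the cardiac cycle. Includes RCR Windkessel outlet
    boundary-condition estimation with Murray's-law outflow splitting, a
    centerline/ROI geometry toolkit, ROC threshold-sensitivity analysis and
    Kruskal-Wallis group comparison, plus a synthetic pulsatile-flow generator
    (idealized tubes and bifurcations, parabolic profiles, programmable
    recirculation pockets) that provides analytic ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
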