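Package: domfuse
Title: Multi-Technique Characterization of Dissolved Organic Matter in River Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing dissolved organic matter (DOM) in natural
    waters by combining excitation-emission matrix (EEM) fluorescence,
    UV-Vis absorption, electrochemical impedance spectroscopy (EIS) and in-situ
    physicochemical parameters. Implements EEM conditioning (blank subtraction,
    Rayleigh/Raman scatter excision, dilution handling, quinine-sulfate-unit
    normalization), the classical fluorescence indices (FI, HIX, BIX,
    Peak C/Peak T), multivariate curve resolution by alternating least squares
    (MCR-ALS) with non-negativity and trilinearity constraints for multi-sample
    EEM stacks, principal component analysis of Bode-phase EIS spectra with
    Savitzky-Golay smoothing, and multi-block data fusion with a global
    autoscaled PCA. A synthetic campaign generator with stored ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
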