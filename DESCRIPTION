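Package: emgsyn
Title: Muscle Synergy Extraction and Comparison from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts synchronous muscle synergies from multichannel surface
    electromyography (EMG) recorded during discrete and discrete-rhythmic arm
    movements. Provides a forward simulator (coupled-oscillator figure-eight
    and minimum-jerk point-to-point kinematics driving a three-module synergy
    model of seven shoulder muscles), EMG envelope preprocessing
    (rectification, cascaded averaging filter, decimation, per-movement
    min/max normalization, polynomial differentiation), per-trial component
    analysis (correlation-matrix PCA and varimax rotation with component time
    courses and EMG reconstruction), cross-trial component matching by
    sign-aware k-means clustering with a conflict-reassignment rule, and the
    inferential layer used to compare conditions (Wilks' lambda MANOVA with
    Rao's F approximation, per-muscle ANOVAs, cluster-dispersion ANOVA with a
    planned PCA-versus-varimax contrast, and Kolmogorov-Smirnov/Lilliefors
    normality screening).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
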