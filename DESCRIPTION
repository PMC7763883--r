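Package: ecgfuse
Title: Time-Frequency Fusion Normalization of Post-Exercise ECG for Biometric Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches tachycardic post-exercise electrocardiogram (ECG) cycles to
    resting-state cycle morphology so that heartbeat-based user identification
    keeps working after exercise. Provides a seeded generator of paired
    rest/exercise single-lead ECG with subject-specific P-QRS-T morphology;
    Butterworth bandpass preprocessing with Pan-Tompkins R-peak detection,
    QRS-sparing median smoothing and piecewise-linear baseline removal;
    fiducial cycle segmentation and P/QRS/T wave splitting; time normalization
    of the P and T sections by neighbor-average linear data interpolation,
    frequency normalization by an optimized 10-80 Hz bandpass, and the fusion
    of the two; Euclidean cycle-similarity evaluation; and a closed-set 1:N
    identification harness (discriminant reduction, k-NN, SVM and neural
    classifiers) with precision/recall/F1/accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    class,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
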