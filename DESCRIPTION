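Package: pcgwcnn
Title: Heart Valve Disease Detection from Phonocardiograms with a Weighted CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for detecting heart valve disease in
    phonocardiogram (PCG) audio. Reads and standardizes PCM WAV recordings,
    extracts mel-frequency cepstral coefficient (MFCC) feature maps (17
    static coefficients by 13 frames by default), and classifies them with a
    lightweight weighted convolutional neural network whose parameter-free
    key-weighting (KWC) layer rescales each channel by its global average
    activation. Includes analytic parameter and FLOP accounting for the
    architecture, Grad-CAM explanations over the MFCC input plane, a
    band-energy-ratio (BER) signal-quality metric, a cross-validated
    evaluation suite (accuracy, precision, recall, F1, Cohen's kappa,
    trapezoidal AUC-ROC, average precision), and a synthetic PCG generator
    with controllable murmur classes and noise-band energy so the entire
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
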