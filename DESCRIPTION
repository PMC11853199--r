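Package: respscreen
Title: Lung-Sound Screening with Wavelet and Entropy Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for screening chest auscultation
    recordings into four respiratory classes (healthy, pneumonia, COPD,
    other). Recordings are bandpass filtered (80-1000 Hz, 5th-order
    Butterworth realized as cascaded high-pass and low-pass sections),
    amplitude normalized and cut into 6-second segments; each segment is
    decomposed with a 10-level Daubechies db7 discrete wavelet transform
    and summarized by 13 features (Shannon entropy, spectral entropy, and
    the root mean square of each coefficient set). Features are ranked by
    the Kruskal-Wallis H statistic against a chi-squared critical value
    and fed to a single-hidden-layer feed-forward network (ReLU hidden
    units, softmax output, categorical cross-entropy, dropout, L2 weight
    penalty and early stopping). The package also provides a seeded
    synthetic auscultation corpus generator, one-vs-rest evaluation
    metrics, per-recording probability screening reports, and a
    command-line interface for the staged workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
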