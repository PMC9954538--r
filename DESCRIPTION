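Package: eegtrm
Title: Topographic Representation Module for EEG Classification Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a size-preserving topographic representation module
    (TRM) for multichannel EEG classification. Raw epochs of shape channels x
    time points are mapped onto a 2-D scalp grid (one cell per electrode,
    empty cells zero-filled), passed through a stack of valid 2-D convolutions
    whose kernel sizes are derived automatically from the grid size, and
    reshaped back to channels x time points, so the module can be prepended to
    any EEG classification network without altering that network. Also
    provides minimal reimplementations of three standard EEG decoding
    networks (shallow, deep and compact convolutional nets), epoching and
    band-pass preprocessing for continuous recordings, a class-conditioned
    synthetic EEG generator, and a training/evaluation protocol with
    minimum-validation-loss checkpointing and paired significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
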