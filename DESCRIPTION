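Package: eegattr
Title: Attribution Methods and Faithfulness Tests for EEG Deep-Learning
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets convolutional neural networks trained on
    multichannel EEG. Implements seven backpropagation-based attribution
    methods (saliency, deconvolution, guided backpropagation,
    gradient x input, integrated gradients, epsilon-rule layer-wise
    relevance propagation, rescale-rule DeepLIFT) in one modified-gradient
    engine, two quantitative faithfulness tests (local-patch sensitivity
    and deletion curves), a sample-wise visualization and trust-report
    pipeline, a seeded synthetic EEG generator with ground-truth feature
    masks, and compact reference CNN architectures with a demo trainer so
    that the whole stack is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
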