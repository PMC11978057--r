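Package: monkeyid
Title: Facial Recognition for Individual Identification of Laboratory Macaques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual identification of cynomolgus monkeys (Macaca
    fascicularis) from face images, built from classical computer-vision
    components: eigenface principal-component features, local binary
    pattern histograms, keypoint descriptors quantized against a
    bag-of-visual-words codebook, and a tuned classifier suite (support
    vector machines with four kernels, linear discriminant analysis,
    k-nearest neighbors) with Gaussian-process Bayesian hyperparameter
    search.  Includes stratified 10-fold cross-validation benchmarking,
    a near-real-time video identification layer with 0.5 s frame pooling
    and temporal majority voting, a pluggable face-detection contract,
    and a deterministic synthetic face-image generator for desk-scale
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    quadprog,
    jsonlite,
    png,
    jpeg,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
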