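Package: hybridSeg
Title: Hybrid Handcrafted-Feature/CNN Brain Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-modal MRI brain tumor segmentation combining handcrafted
    image descriptors (dense SURF, histograms of oriented gradients, and
    intensity/texture channel maps) with a U-Net-style convolutional
    encoder-decoder. Provides three handcrafted/CNN fusion strategies (input
    channel, feature map, and decision level), a combined cross-entropy plus
    soft-Dice training objective optimized by stochastic gradient descent
    with momentum and early stopping, stochastic training-time augmentation
    applied jointly to image and mask, BraTS-style region metrics (whole
    tumor, tumor core, enhancing tumor), and a multi-modal phantom generator
    so the entire pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io_preprocess.R'
    'augment.R'
    'features_texture.R'
    'features_hog.R'
    'features_dsurf.R'
    'feature_stack.R'
    'losses_metrics.R'
    'nn_ops.R'
    'model.R'
    'phantom.R'
    'train.R'
    'pipeline.R'
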