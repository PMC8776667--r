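Package: cystct
Title: Multi-Channel CT Radiomics and Stacked Classification of Pancreatic
    Cystic Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing serous from mucinous pancreatic cystic
    neoplasms on axial CT slices. Implements ROI-to-patch preprocessing
    (tight bounding box with a 2-pixel margin), conversion of Hounsfield-unit
    patches into three-channel images (windowed grayscale, Canny edge map,
    Sobel gradient magnitude), handcrafted texture descriptors (GLCM, LBP,
    HOG, Gabor, Haar wavelet), a seeded convolutional feature extractor, and
    probability fusion of KNN, softmax and naive-Bayes classifiers through a
    random-forest stacking model with out-of-fold meta-training. A synthetic
    phantom generator produces CT-like slices with honeycomb (multi-locule)
    and unilocular cystic lesions so the full pipeline can be exercised and
    evaluated offline with the standard six indicators (precision,
    sensitivity, specificity, accuracy, F1, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    e1071,
    glmnet,
    graphics,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
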