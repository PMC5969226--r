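Package: morphsurp
Title: Morphological Surprisal Predictors and Simulated Lexical-Decision
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how information-theoretic word properties
    relate to evoked brain responses and reaction times in visual word
    recognition. Implements a minimum-description-length (MDL) morph
    segmentation model with Viterbi decoding and character-level fallback,
    seven item-level surprisal predictors (word length, rendered image
    complexity via a GIF compression index, open-bigram surprisal, MDL
    morph surprisal, lemma and surface-frequency surprisal, and lemma
    transition probability), a synthetic-corpus and stimulus generator
    with gold morph boundaries, a simulator of lexical-decision responses
    (component window amplitudes and reaction times with planted linear
    effects), and the item-level analysis stage: within-participant
    z-scoring, cross-participant item averaging, simple correlations with
    F-tests, forward stepwise regression with standardized coefficients,
    and tertile-binned grand-average curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
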