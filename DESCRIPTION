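Package: condlm
Title: Conditional Transformer Language Modeling for Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for keyword- and year-conditioned language
    modeling of biomedical citation records. Provides a self-contained unigram
    subword tokenizer with Viterbi and sampled segmentation, a MEDLINE-style
    corpus pipeline (filtering, splitting, condition indexing, annotation
    alignment, training-window sampling), a transformer with a shallow
    condition-encoder stack and a deep causally masked decoder trained with a
    four-task objective (next token, part of speech, dependency tag, entity
    label), hand-derived gradients with Adam and LAMB optimizers, conditional
    ancestral text generation, an n-gram evaluation suite (per-order BLEU,
    ROUGE-L, CIDEr, a title-masked CIDEr variant and a stem-matching METEOR
    score), and a synthetic condition-dependent corpus generator with known
    closed-form statistics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
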