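Package: distagger
Title: Disease Named-Entity Recognition with Bi-LSTM-CRF Sequence Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for recognizing disease names in
    biomedical text. Implements skip-gram word embeddings trained with
    negative sampling, a bidirectional LSTM encoder with coupled
    input/forget gates and peephole connections, a linear-chain
    conditional random field with exact forward-algorithm normalization
    and Viterbi decoding, BIO span encoding with character-accurate
    offsets, a short-form/long-form abbreviation detector whose output
    takes precedence over the sequence model in a label merge, and
    mention-level evaluation with a put-back bootstrap confidence
    interval. Includes readers and writers for PubTator-style annotated
    corpora, CoNLL-style token files and word2vec text vectors, plus a
    deterministic synthetic corpus generator so the whole pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
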