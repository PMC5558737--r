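Package: nermtl
Title: Multi-Task Convolutional Window Taggers for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-task and multi-task convolutional window-based sequence
    taggers for biomedical named entity recognition with BIOES tags. Provides
    CoNLL-style corpus input/output, frozen word-embedding tables with
    unknown-word handling, hard-parameter-sharing multi-output models, a
    dependent (auxiliary-task) model, binary transition-matrix Viterbi repair
    of predicted tag sequences, mention-level exact-match evaluation, a
    seed-deterministic synthetic multi-corpus generator, and drivers for
    pairwise, grouped, all-dataset and dataset-size-reduction experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
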