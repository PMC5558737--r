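# nermtl

Multi-task convolutional window taggers for biomedical named entity
recognition (NER), in pure R.

Biomedical NER corpora are small, expensive, and annotate related but
different entity inventories (genes, chemicals, diseases, species, anatomy).
This package implements and tests the hypothesis that training one
convolutional tagger on several corpora jointly — multi-task learning with
hard parameter sharing — improves performance over single-task training,
especially when the target corpus is small. It is aimed at text-mining
researchers who want a compact, fully reproducible implementation of the
approach whose every component (including backpropagation) is inspectable R
code.

## What is implemented

Tokens are tagged with the BIOES scheme (`S-T` single-token entity of type
`T`, `B-T`/`I-T`/`E-T` multi-token spans, `O` outside) and each token is
classified from a seven word context window (focus word ± 3, sentence-break
padding) of frozen word embeddings. Four architectures:

* **baseline** — window concat → ReLU(300) → softmax (SGD, batch 50);
* **STM** (single-task CNN) — 100 filters of widths 3/4/5 slid along the
  token axis only, ReLU, *no pooling*, flatten → fully connected (300) →
  dropout (keep 0.75) → softmax (Adam 1e-4, batch 200);
* **MO-MTM** (multi-output multi-task) — the STM trunk shared by all corpora
  with one private softmax head per corpus; at each step one corpus is drawn
  uniformly at random and only its path is updated;
* **D-MTM** (dependent multi-task) — an STM for the main task whose output
  layer consumes the concatenation of its own fully connected layer and that
  of a separately pre-trained, frozen auxiliary network (e.g. a POS-like
  token classifier).

Predicted tag sequences are repaired by constrained Viterbi over a **binary
transition matrix** learned from training labels (a transition scores 1 iff
it occurs in the training tags). Evaluation is mention-level exact-match
precision/recall/F1 pooled over entity types; run comparisons use a
two-tailed Welch t-test at α = 0.05.

A seed-deterministic synthetic corpus generator produces multi-corpus
collections with partially shared entity lexicons — including surface forms
present in one corpus's test split but only in *another* corpus's training
split — plus auxiliary token-classification tasks with a tunable
informativeness dial. Experiment drivers reproduce the study designs:
pairwise (main, auxiliary) effects grid, grouped same-entity training,
all-dataset comparison (baseline/STM/MO-MTM/D-MTM) and the 50/25/10%
dataset-size reduction study.

See `vignettes/nermtl-methods.Rmd` for the model details, design choices and
the generator's scope.

## Worked example

```r
library(nermtl)

cfg <- synthetic_config(n_corpora = 2, seed = 42)
collection <- generate_collection(cfg)
collection[[1]]
#> <ner_corpus 'corpus1': types {CHEM, GENE}; train/dev/test = 500/100/100 sentences>

table <- make_random_table(collection_vocabulary(collection), 50, seed = 43)
arch  <- architecture_spec("single_task", embedding_dimension = 50,
                           filters_per_width = 25, fully_connected_size = 100)
sched <- training_schedule(max_steps = 1000, batch_size = 50,
                           learning_rate = 3e-3, eval_every = 500,
                           patience = 10, seed = 44)
fit <- train_single_task(collection[[1]], arch, sched, table)
fit
#> <ner_fit 'single_task' on {corpus1}: best dev f1 0.8996 at step 1000>

evaluate_fit(fit, collection[[1]], "test")
#> Mention-level exact match: P = 0.9638  R = 0.8471  F1 = 0.9017 (tp 133, fp 5, fn 24)
#>   CHEM         P = 0.9672  R = 0.8551  F1 = 0.9077
#>   GENE         P = 0.9610  R = 0.8409  F1 = 0.8970

predict(fit, collection[[1]]$test)[[1]][1:6]
#> [1] "B-CHEM" "E-CHEM" "O"      "B-GENE" "I-GENE" "E-GENE"
```

The fit object is a classed model with `print`, `summary`, `predict` (tags
new sentences with Viterbi repair) and `plot` (development-F1 history)
methods. `fit_ner()` is the umbrella fitting function dispatching on model
kind; `train_multi_output()` and `train_dependent()` fit the multi-task
variants; `run_pairwise_grid()`, `run_grouped()`, `run_all_multi()` and
`run_size_reduction()` drive whole experiment suites and write TSV tables. A
thin command-line wrapper lives at `inst/cli/nermtl.R`
(`Rscript inst/cli/nermtl.R generate --out data ...`).

Real corpora in CoNLL column format are read with `read_conll_split()`
(IOB/IOB2 input is converted to BIOES behind an explicit flag), and
pre-trained embeddings in word2vec text format with `load_embedding_table()`.

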