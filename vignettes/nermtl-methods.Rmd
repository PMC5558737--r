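---
title: "Multi-task convolutional window taggers for biomedical NER: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task convolutional window taggers for biomedical NER: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical named entity recognition (NER) locates and types mentions of
genes, chemicals, diseases and similar entities in text. Annotated corpora
are expensive, so each one is small, and different corpora annotate related
but not identical entity inventories. Multi-task learning (MTL) asks whether
training one model on several such corpora jointly improves performance on
each of them — in particular in the low-resource regime where a target corpus
has little training data but a related corpus is plentiful. A concrete
motivation: an entity surface form can appear in the *evaluation* section of
one corpus while occurring in the *training* section of another; only a model
that shares parameters across corpora can exploit that.

`nermtl` implements this programme as a self-contained R package: the window
CNN taggers, their multi-task variants, binary-transition Viterbi repair,
mention-level exact-match evaluation, a synthetic multi-corpus generator that
reproduces the structural features the method relies on, and drivers for the
experiment families (pairwise effects grid, grouped same-entity training,
all-dataset MTL, dataset-size reduction).

## Sequence tagging setup

Sentences are tagged with the BIOES scheme: `S-T` marks a single-token entity
of type `T`, multi-token entities are `B-T`, `I-T`..., `E-T`, and `O` marks
non-entity tokens. Tagging is cast as independent classification of each
token from a *context window*: the focus token plus `n` words on each side
(`2n + 1` tokens, default `n = 3`, a seven word window), with a reserved
sentence-break token padding positions beyond the sentence boundary. Word
representations are frozen pre-trained embeddings (word2vec text format);
out-of-vocabulary handling cascades exact match → lowercased match → a
dedicated unknown-word vector. The cascade is our choice: the original
setting trains a single unknown-word vector and states no case-folding
policy; lowercasing reduces avoidable OOV while preserving single-UNK
behaviour.

## Models

* **Baseline**: the concatenated window vectors feed one ReLU hidden layer
  (size 300) and a softmax output layer; trained with plain SGD, mini-batch
  50. Its learning rate is unstated in the original setting; we default to
  0.01.
* **Single-task CNN (STM)**: 100 filters for each width in {3, 4, 5} slide
  along the token axis only (filter width in the embedding axis always equals
  the embedding dimension), ReLU, **no pooling** (position information is
  kept), flattening, a fully connected layer, dropout, and a softmax output.
  The flat feature length for `n = 3` is (5 + 4 + 3) x 100 = 1200. We flatten
  in (width, position, filter) order; any fixed order is equivalent up to a
  permutation of the learned weights of the next layer.
* **Multi-output multi-task model (MO-MTM)**: identical trunk (convolutions +
  fully connected layer) shared by all corpora; each corpus owns a private
  softmax head. At every training step one corpus is chosen uniformly at
  random and only its head plus the shared trunk receive gradients (hard
  parameter sharing). Uniform rather than size-proportional sampling is our
  reading of "randomly selected" with no weighting stated.
* **Dependent multi-task model (D-MTM)**: a single-task network is first
  trained on an auxiliary token-classification task (POS-like); a second,
  main-task network is then trained whose output layer consumes the
  concatenation of its own fully connected activation and the auxiliary
  network's (e.g. 300 + 300 = 600 inputs). The auxiliary network is frozen
  during main training and always runs with dropout off. Freezing is a
  design choice: the source text is ambiguous about fine-tuning, and freezing
  matches the description of using the *trained* auxiliary model in the
  second phase.

The loss is categorical cross-entropy; CNN kinds use Adam (reference learning
rate 1e-4, mini-batch 200; 190,000 steps is the documented full-scale run
length). Dropout keep probability is 0.75 at the fully connected layer only.
We read "dropout with a probability of 0.75" as the *keep* probability (the
convention of the original dropout paper) and implement inverted scaling so
inference needs no rescaling. Biases are included in all affine maps.
Gradients and optimiser updates are written in closed form with base R matrix
algebra — no deep-learning framework is used — which keeps runs exactly
reproducible: fixed seed and data imply a bit-identical parameter trajectory
on a single-threaded BLAS.

## Decoding

Window classification is per-token, so raw argmax tag sequences can violate
the BIOES grammar. A **binary transition matrix** is computed from the
training labels: a transition scores 1 if it occurs in the training tags and
0 otherwise (we also record observed sentence-initial and sentence-final
tags; the source describes only pair transitions, but without boundary
constraints an invalid sentence-initial `E-T` could survive). Decoding is
global constrained Viterbi over per-token log-probabilities: the argmax over
tag sequences whose every transition is allowed. Probabilities are floored
at 1e-12 before the log; forbidden transitions score −Inf; ties break toward
the lowest label index at the latest differing position; if no allowed path
exists (possible with very small training sets) the per-token argmax is
returned with a warning. Because training tags are BIOES-valid, every
repaired sequence is too. The implementation is verified against exhaustive
enumeration over all tag sequences on randomized small instances.

## Evaluation

Scores are mention-level exact-match F1 pooled over entity types: a predicted
mention counts only if an identical (sentence, start, end, type) span is in
the gold standard, and precision/recall are computed from the joint counts of
all types (the source calls this "macro F1" while describing the pooled
computation — "a single precision and recall calculated for all types" — so
we implement the pooled definition, which standard terminology calls micro
F1). Zero-denominator conventions follow conlleval (undefined precision or
recall scores 0). Auxiliary tasks are scored by token accuracy. Run-level
comparisons use a two-tailed Welch t-test at alpha = 0.05 (the equal-variance
and paired variants are exposed; the original text does not say whether its
tests were paired).

## Synthetic data: what it emulates and what it does not

The generator builds collections of corpora that reproduce the structural
properties the method depends on, at desk scale:

* **Context vocabulary** (default 300 words) and **type-specific trigger
  tokens** that precede an entity with probability 0.7 — context is
  informative but unreliable, as in real text.
* **Entity lexicons** of composite surface forms (1–3 tokens, probabilities
  0.5/0.3/0.2) over **piece alphabets disjoint from the context vocabulary**.
  Pieces are specific to an entity type and to a positional role (single /
  begin / mid / end, a synthetic analogue of the positional morphology of
  real biomedical names such as "-ase" suffixes), so entity status and type
  are recoverable from surfaces — the role pre-trained embeddings play for
  real corpora. Each type's alphabet has 15 pieces, of which few (a quarter)
  serve the single role: single-token mentions are the hardest unigram
  decisions, so each single piece recurs often in training.
* **Partial lexicon sharing**: a configurable fraction (default 0.5) of each
  type's 20 surface forms comes from a pool shared across corpora annotating
  that type. Each corpus withholds a quarter of its shared forms from its own
  training split — they still occur in its dev/test splits and in other
  corpora's training splits, reproducing the cross-corpus transfer premise.
  Held-out forms are chosen so their pieces all occur in retained forms;
  they are new combinations of attested pieces, recoverable in principle and
  directly trainable from the other corpora.
* **Sentences** of 6–12 tokens with on average 1.5 entities, at least one
  context token between entities (adjacent same-type mentions would make the
  boundary unrecoverable from surfaces, an ambiguity no tagger could
  resolve).
* **Label noise** (off by default) flips whole training mentions to `O` — an
  annotation-miss model mirroring the incompatibility mode of merged corpora;
  flipping whole mentions keeps tags BIOES-valid.
* The default collection has 3 corpora, each annotating a shared GENE type
  plus one private type, with 500/100/100 train/dev/test sentences.

What it does **not** emulate: realistic morphology or word frequencies,
embedding geometry (tests use seeded uniform random vectors on
[−0.5/d, 0.5/d]), discourse structure, nested or overlapping mentions
(unsupported by design), and the scale of real corpora. Passing tests
therefore demonstrate that the machinery is correct and that the MTL
mechanisms behave as described under controlled conditions — not that any
particular F1 carries over to real biomedical corpora.

## Scale profiles and numerical choices

Experiment drivers accept a scale profile:

* `full` — the reference configuration: 190,000 steps, batch 200, Adam 1e-4,
  100 filters per width, fully connected size 300.
* `default` — same architecture, shorter schedules (5,000/8,000 steps).
* `tiny` — for complete suites on one CPU: 1,000 single-task / 2,000
  multi-task steps (so per-task exposure is balanced when two tasks are
  sampled uniformly), batch 50, 25 filters per width, fully connected size
  100, 50-dimensional embeddings, and learning rate 3e-3 — a sensible
  optimisation regime for runs two orders of magnitude shorter than full
  scale. The package's own test suite and the bundled acceptance script run
  at this profile.

Other numerical choices: Glorot-uniform initialisation with zero biases
(seed-deterministic); Adam with beta 0.9/0.999, eps 1e-8; early stopping
evaluates the development split every `eval_every` steps and keeps the best
checkpoint (ties resolved to the earliest step); multi-task checkpoint
selection uses the unweighted mean of per-task development F1 — the source
reports a single score per run and states no rule, and one model needs one
stopping point. Label vocabularies are sorted with C-locale collation, `O`
first, so label indices are identical across platforms.

## Known limitations

* Overlapping or nested annotations are rejected, matching the stated
  limitation of the original implementation.
* The window tagger sees at most `n` tokens of context; entities longer than
  the window cannot be fully represented (synthetic entities are capped at 3
  tokens).
* The per-corpus overlap audit reports the fraction of test sentences whose
  token sequence appears verbatim in a training split; the original report
  does not define its denominator, so those printed percentages are not
  reproduced.
* Transition matrices learned from very small training splits can forbid all
  paths for an unusual sentence; the decoder then falls back to per-token
  argmax with a warning.
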