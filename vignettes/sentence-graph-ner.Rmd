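---
title: "Sentence-graph NER: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentence-graph NER: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatner)
```

## The model

`gatner` casts biomedical named entity recognition (BioNER) as node
classification on a sentence graph.  A sentence is tokenized (spaces
split words; every non-alphanumeric symbol is its own token; periods end
sentences), parsed into a dependency tree, and turned into an
undirected graph: one node per sub-word piece plus `[CLS]`/`[SEP]`
terminals, with an edge for every dependency triple and a `next` edge
between consecutive pieces of the same word.  The adjacency matrix is
binary and symmetric, with self-loops so every node attends to itself.

Each node carries the concatenation of two feature blocks:

* **Cont** — a contextual embedding of dimension $d$ (768 for a
  transformer adapter; 16 for the built-in deterministic stub), and
* **Synt** — a 54-dimensional one-hot syntactic vector:
  14 POS slots (10 retained tags + `OTHERS`, `CLS`, `SEP`, `X`) and
  two 20-slot dependency blocks (18 retained relations + `others` +
  `next`), one for in-degree and one for out-degree.  The retained tags
  are those whose corpus frequency among entity mentions reaches 1%.

A stack of $L$ graph attention layers fuses the features.  Per head,
$\mathrm{coef}_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$
for $j \in N_i$, normalized by a masked softmax to $\alpha_{ij}$, and
$h_i' = \mathrm{ELU}\big(\sum_{j \in N_i} \alpha_{ij} W h_j\big)$;
the $M$ head outputs are concatenated, so a layer maps width $F$ to
$M F'$.  A linear-softmax decoder assigns each node a BIO label
probability; words take the label of their first piece, and
`repair_bio()` rewrites orphan `I-` tags so output is grammar-valid.
Scoring is strict and entity-level: a predicted span counts only when
start, end and type all match a gold span; precision, recall and F1 are
micro-averaged.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `layers` | 2 | GAT depth; influence propagates at most `layers` hops |
| `heads`, `units` | 12, 64 | heads per layer and units per head (output width = heads x units) |
| `leaky_slope` | 0.2 | LeakyReLU slope in the attention logits (canonical value for this layer family; unstated in the reference configuration) |
| `self_loops` | TRUE | without them a node's own features would be discarded by the neighbor sum |
| `msl` | 256 | max nodes per graph; longer sentences are split at the last word boundary before the limit and re-rooted deterministically |
| `bs`, `lr`, `epochs` | 32, 5e-5, 50 | reference-scale optimizer settings; desk-scale runs use bs 8, lr 0.01, 40-100 epochs |
| `dropout`, `weight_decay`, `word_dropout` | 0 | optional regularizers; measured to not help on the synthetic task and left off |
| `threshold` (inventory) | 0.01 | frequency cutoff that defines the retained POS/dependency lists |

`preset_config()` ships the per-dataset reference configurations
(e.g. `preset_config("bc5cdr_chem")` gives msl 256, bs 32, lr 3e-5,
4 layers, 12 heads, 64 units).

The optimizer is Adam with global gradient-norm clipping at 1.0 and mean
cross-entropy over supervised nodes.  The reference description names no
optimizer or loss; these are reconstructions, flagged as such.  CLS/SEP
nodes are never supervised; continuation pieces are supervised with the
`I-` form of their word's label; evaluation is word-level only.

## Open design points and the choices made

* **CLS/SEP connectivity** is unstated upstream; here they carry
  self-loops only, because no dependency triple involves them and
  wiring them to the root would add structure the parse does not
  assert.
* **Wordpiece inheritance**: all pieces inherit their word's dependency
  bits and (by default) its adjacency; the first piece keeps the word's
  POS while continuation pieces take `X`.  Flags
  (`inherit_adjacency`, `continuation_pos_inherit`) expose the
  alternatives.
* **Root in-degree**: the parse root has no incoming triple, so the
  `root` relation sets the root word's in-degree slot — otherwise the
  root would be the only word with no in-degree signal although `root`
  is in the retained relation list.
* **Span convention**: entity spans use 1-based inclusive start/end
  (the natural R interval convention, as in IRanges); subtract 1 from
  `start` for 0-based half-open coordinates.
* **Numerics**: masked softmax uses row-max subtraction; masked pairs
  are `-Inf` before exponentiation; prediction ties break toward the
  lowest label index; parameters are Glorot-uniform from a private
  seeded stream, and every stochastic step (init, shuffling, dropout)
  derives from the run seed, so identical seeds give byte-identical
  predictions.

## The synthetic generator

Real benchmark corpora require external downloads and a pre-trained
transformer plus parser, so training-level tests run on generated
corpora that emulate parsed, BIO-labeled biomedical sentences.
`generate_tree()` grows a single-root dependency tree (word 1 is the
root; later words attach to the root with probability `root_attach` =
0.5, else to a uniform earlier word — verb-rooted clauses hang most
arguments off the main verb).  Relations are drawn from weights over
the 18 retained labels plus `others`; POS is drawn conditional on the
relation; surfaces come from a fixed POS-keyed lexicon of letter/digit/
symbol word shapes, so the tokenizer and wordpiece paths see realistic
material.

Entity placement follows a syntactic motif: a NOUN/PROPN attached to a
VERB head by `nsubj`/`dobj`/`nmod` is a trigger, selected with
probability $\rho$; a compound NOUN/PROPN child of a selected trigger
joins the entity (one level, deterministic); any other word becomes a
singleton entity with noise probability $\varepsilon$; adjacent entity
words merge into one multiword span.  With probability
`multiword_prob` a selected trigger acquires an adjacent compound
modifier (guarded so the rewired parse stays a tree and labels remain a
deterministic function of the final parse at $\rho = 1,
\varepsilon = 0$).  Defaults — sentence length 4-14, $\rho = 1$,
$\varepsilon = 0$, `multiword_prob` 0.3 — give about 0.85 entities per
sentence with a third of spans multiword, similar to the benchmark
corpora's densities.

What the generator does **not** emulate: real lexical semantics,
long-range discourse, parser errors on real text, nested or
discontinuous entities, and genuinely contextual word meaning.  Passing
the synthetic tests therefore shows that the architecture can exploit
syntax and topology under controlled conditions — not that it matches
reference-scale benchmark accuracy, which requires a fine-tuned
pre-trained encoder.

## The contextual stub

The built-in encoder maps each surface to a fixed unit-norm hashed
Gaussian vector and overwrites the trailing `min(8, d/2)` channels with
a word-position code (a linear position channel plus dyadic sine/cosine
pairs).  Both properties imitate what a real contextual encoder
provides: distinct surfaces embed apart, and the same surface at
different positions embeds differently.  The position channels matter:
IOB2 boundary tags (`B-` vs `I-`) are a function of linear word order,
which dependency topology alone does not carry; without them no decoder
on top of this graph could separate a two-word span from two adjacent
singleton spans.

## Problem sizes and known limitations

Training-level checks use desk-scale sizes chosen to keep the whole
suite fast on a single CPU: 500 train / 100 test sentences for
parameter recovery (2 layers, 8 heads x 16 units, stub d = 16, Adam lr
0.01, batch 8, dev-based model selection), and 3 seeds x 250 train
sentences for the feature-ablation contrast.

Two limitations are worth stating plainly.  First, the softmax decoder
classifies nodes independently and cannot use label-transition
structure; its characteristic failure is span-boundary confusion on
multiword entities (predicting `B B` where `B I` is gold, or absorbing
an adjacent modifier).  In the parameter-recovery check entity
*detection* is essentially perfect while boundary confusions dominate
the residual strict-matching errors — the same error class the
reference analysis attributes to its decoder.  A
transition-aware decoder (e.g. a CRF) is deliberately out of scope.
Second, the frozen stub cannot do sequence reasoning the way a
fine-tuned transformer does; its additive attention logits
$a^\top[Wh_i \| Wh_j]$ contain no bilinear term, so comparing a
neighbor's position against one's own is representable only through
stacked nonlinearities, which costs sample efficiency.  Both effects
disappear when a real contextual encoder adapter supplies `Cont`.

## Reproducing the pipeline

```{r, eval = FALSE}
dir <- tempfile()
run_pipeline("simulate",
             overrides = list(n_sentences = 200, seed = 7, out = dir))
run_pipeline("train",
             overrides = list(data = dir, out = file.path(dir, "model"),
                              seed = 7, epochs = 40, bs = 8, lr = 0.01,
                              layers = 2, heads = 8, units = 16,
                              encoder_d = 16))
run_pipeline("predict",
             overrides = list(model = file.path(dir, "model"),
                              data = file.path(dir, "test.conllu"),
                              out = file.path(dir, "pred.bio")))
run_pipeline("evaluate",
             overrides = list(gold = file.path(dir, "test.bio"),
                              pred = file.path(dir, "pred.bio")))
```

Every stage writes a `manifest.json` (config hash, seed, package
version, input digests, timing); reruns with identical seeds produce
byte-identical prediction files.
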