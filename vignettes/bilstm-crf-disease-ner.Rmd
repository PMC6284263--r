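---
title: "Disease NER with Bi-LSTM-CRF: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease NER with Bi-LSTM-CRF: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distagger)
```

## The problem and the architecture

Disease names in biomedical abstracts are hard to recognize: they are
built from Greco-Latin roots and affixes ("hemo-chromatosis"), carry
descriptive modifiers ("recurrent cat-eye syndrome"), span several
words, and are frequently abbreviated with short forms that collide
with non-disease abbreviations ("CT" may be Copper Toxicosis or
Computed Tomography). `distagger` implements a three-layer sequence
labeler for this task plus a definition-based abbreviation resolver:

1. **Word embeddings.** Skip-gram vectors trained with negative
   sampling (NEG). The score of a center/context pair is
   $s(w, c) = v_w^\top v'_c$, and each observed pair is contrasted
   against $k$ noise words drawn from $Q(w) \propto \text{count}(w)^{0.75}$
   by maximizing
   $\log\sigma(s(w,c)) + \sum_{i=1}^{k}\log\sigma(-s(\tilde w_i, c))$
   with stochastic gradient ascent.
2. **Bidirectional LSTM.** A coupled-gate peephole cell: the input gate
   $i_t = \sigma(W_{xi}x_t + W_{hi}h_{t-1} + W_{ci}c_{t-1} + b_i)$ also
   controls forgetting through the coefficient $(1-i_t)$, the cell
   update is $c_t = (1-i_t)\odot c_{t-1} + i_t\odot\tanh(W_{xc}x_t +
   W_{hc}h_{t-1} + b_c)$, and the output gate peeks at the fresh cell
   state, $o_t = \sigma(W_{xo}x_t + W_{ho}h_{t-1} + W_{co}c_t + b_o)$,
   $h_t = o_t \odot \tanh(c_t)$. Two independent cells read the
   sentence left-to-right and right-to-left; their states are
   concatenated per token.
3. **Linear-chain CRF.** An affine projection of the encoder states
   yields an $n \times 3$ emission matrix $P$ over the BIO labels, and
   a learned transition matrix $A$ (augmented with START and STOP
   states) scores label paths: $s(X,y) = \sum_i P_{i,y_i} +
   A_{\text{START},y_1} + \sum_i A_{y_i,y_{i+1}} + A_{y_n,\text{STOP}}$.
   Training maximizes $\log p(y|X) = s(X,y) - \log Z$ with the exact
   forward algorithm in log space; decoding is Viterbi.

Mentions are carried as 0-based, half-open character spans and
converted to/from per-token BIO tags; the abbreviation detector scans
for "Long Form (SF)" definition sites, validates them with the FC /
FCG / FCS matching strategies, and propagates disease short forms
document-wide, taking precedence over the sequence model in the final
label merge.

## Gradients

No automatic differentiation is used: all gradients are derived by
hand. The CRF NLL gradient is the difference between expected
(forward-backward marginals) and observed sufficient statistics;
backpropagation through the coupled cell accounts for both peephole
paths (the input-gate peephole feeds $c_{t-1}$, the output-gate
peephole feeds the *current* $c_t$) and the coupled forget coefficient
$(g_t - c_{t-1})$ term in $\partial c_t/\partial i_t$. The test suite
checks every parameter of the full stack — embedding rows, both LSTM
cells, the emission projection and the transition matrix — against
central finite differences on random small instances, and the CRF
against exhaustive enumeration over all $3^n$ paths.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `word_dim` | 200 | token embedding dimension |
| `hidden` | 100 | LSTM units per direction |
| `dropout` | 0.5 | input dropout rate on embedded tokens (training only) |
| `word_dropout_alpha` | 0.25 | token replaced by `<unk>` with probability $\alpha/(\alpha+\text{count})$, so the UNK embedding is trained |
| `learning_rate` | 0.1 | SGD step size (sentence-level updates) |
| `clip` | 5 | global gradient-norm clip |
| `window` | 5 | skip-gram context half-width |
| `k_negatives` | 5 | noise words per positive pair (small-corpus setting) |
| `power` | 0.75 | noise-distribution exponent |

The 200/100 embedding/hidden defaults are the tuned settings for this
architecture; the optimizer is plain SGD. The dropout *switch* is part
of the architecture, its rate of 0.5 a conventional choice (a rate of
1.0 would zero every input and cannot be meant). The embedding
training schedule (window 5, 5 epochs, linear learning-rate decay from
0.025) follows standard NEG practice; these values are conventions,
not tuned quantities.

## Numerical and design choices

* **Boundary handling.** The path score's transition sum runs over
  $n+1$ edges, which requires boundary states: `A` is 5×5 with START
  used only as a source and STOP only as a target.
* **Viterbi ties** break toward the lower label index (B < I < O),
  making decoding deterministic; on an all-zero instance the decoded
  path is all-B by construction.
* **Transition legality.** `A` is fully learned; O→I is *not* forbidden
  by default. A `constrain_bio` flag sets that transition to $-\infty$
  at decode time. Illegal `I` prefixes from the no-CRF ablation are
  repaired to `B`.
* **Zero denominators** in precision/recall yield 0 (and F1 then 0).
* **Exact-span matching**: a predicted mention counts only if its
  `(start, end)` pair matches a gold mention exactly — the stricter,
  deterministic choice.
* **Percentile bootstrap**: documents are resampled with replacement
  ("put-back"), 100 rounds, 95% interval, seeded.
* **Tokenization** splits on whitespace and detaches sentence
  punctuation, but keeps intra-word hyphens, so compounds like
  "insulin-dependent" stay one token; a token partially overlapping a
  mention boundary counts as inside (span snapped outward).
* **Initialization**: Glorot-uniform weights, zero biases; embedding
  rows uniform $\pm\sqrt{3/D}$; skip-gram input vectors uniform
  $\pm 0.5/D$ with zero output vectors, which keeps early
  $\sigma(s) \approx 0.5$.
* **Ablations**: `use_bilstm = FALSE` replaces the encoder with a
  per-token affine classifier over the embedding (the CRF still
  receives an $n\times 3$ emission matrix); `use_crf = FALSE` trains
  per-token softmax cross-entropy and decodes by argmax plus BIO
  repair.
* **Peephole weights** are full $H\times H$ matrices (the cell
  equations are general linear maps); diagonal peepholes are a special case.

## Abbreviation strategies

The module implements the two classical matching strategies plus one
documented fallback, in fixed reliability order:

* **FC** — each SF character matches the first character of
  consecutive long-form words, ending at the word before the
  parenthesis ("Copper Toxicosis (CT)").
* **FCG** — an SF character may additionally match the character
  following a non-alphanumeric, non-space character inside a word, so
  "IDDM" validates against "insulin-dependent diabetes mellitus"
  (I, D-after-hyphen, D, M). Every word of the span must contribute at
  least one character and the match must start at the span's first
  character.
* **FCS** (fallback) — FC allowing exactly one skipped interior word.

The candidate long-form window is the relaxed length restriction
$\min(2|SF|+2, |SF|+5)$ words. Strategy matching is case-insensitive;
propagation of a validated disease short form through the document is
case-sensitive and token-bounded, and it applies document-wide (a
declared design choice; sentence-local propagation would be the
conservative alternative). The merge never deletes a sequence-
model mention merely because the abbreviation layer is silent about
it; it replaces only on span conflict.

## The synthetic corpus generator

Real annotated corpora and billion-word embedding corpora cannot ship
with a package, so every claim is exercised on generated data whose
shape mirrors a typical annotated abstract collection: ~10 sentences
per document, ~21 words per sentence. The generator emulates the hard
cases the task is known for:

* disease names built by affix concatenation — fused
  ("hemochromatosis"), hyphenated ("hemo-chromatosis") and multi-word
  with descriptive modifiers ("chronic hepatic syndrome");
* parenthesized definitions "Long Form (SF)" with the short form
  reused later in the document, all character-exact gold spans;
* **ambiguous abbreviations**: documents may also define non-disease
  long forms (procedures such as "computed tomography (CT)") whose
  short forms collide with disease short forms elsewhere in the
  corpus. Token identity alone therefore cannot resolve standalone
  short-form occurrences — exactly the situation that motivates
  definition-based abbreviation resolution and its precedence in the
  merge.

What the generator does *not* emulate: real PubMed language (fillers
are drawn i.i.d. from a fixed vocabulary, so sentence context carries
far less signal than in real text), concept-identifier distributions,
nested or discontinuous mentions, and corpus scale. Passing the
synthetic checks therefore demonstrates the correctness of the
machinery — exact inference, exact gradients, learnability, codec and
merge semantics — not state-of-the-art accuracy on real corpora.

The embedding fixture plants word clusters: each sentence draws all
tokens from one cluster, so co-occurrence exists only within clusters
and a correct NEG implementation must separate them (intra-cluster
minus inter-cluster mean cosine well above 0.2).

## Evaluation protocol on synthetic data

The package's end-to-end checks use one generated corpus split into
training and held-out test documents (500/100), matching the usual
single-corpus split protocol. Model-quality runs use a 25-unit hidden
layer and 50-dimensional embeddings — deliberately below the 100/200
defaults — with sentence-level SGD at learning rate 0.1: 30 epochs for
the 50-sentence memorization check and 3 epochs for the 500-document
generalization run, after which training loss has plateaued on this
fixture. The bootstrap experiment evaluates test subsets of increasing
size: the 95% percentile
interval from 100 put-back rounds must be degenerate for a single
document and strictly narrower at 100 documents than at 10.

## Known limitations

* Pure-R inner loops: training scales to the desk-sized corpora used
  here (minutes on one core), not to real corpora; there is no GPU or
  multi-thread path (single-threaded execution is also what makes runs
  bit-reproducible).
* Part-of-speech features are not implemented: the path-scoring
  function contains no POS term, so none are extracted.
* Character-level encoders and classical feature-function CRFs
  (L-BFGS-trained) are out of scope — they belong to baseline systems,
  not this architecture.
* Concept normalization is out of scope; concept identifiers are
  carried as opaque strings.
* The seventeen-strategy reliability estimation of the reference
  abbreviation tool is not reproduced; the strategy list is
  extensible, with FC/FCG/FCS implemented.
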