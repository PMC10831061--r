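---
title: "A cerebellar circuit model of next-word prediction and emergent syntax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cerebellar circuit model of next-word prediction and emergent syntax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cann)
```

## The model

`cann` simulates a biologically constrained model of the cerebellar cortex as
a next-word prediction circuit. The circuit has three layers wired in a
feedforward pathway — an input layer standing for granule cells, a middle
layer of Purkinje cells, and an output layer of cerebellar nucleus neurons —
closed by a recurrent pathway that relays the Purkinje signal back to a
*distinct* population of recurrent input cells (the nucleocortical
projection). Words arrive one at a time as one-hot activity over `V + 1`
input cells: each of the `V` most frequent corpus words drives its own cell
and every rarer word drives a shared unknown-word (UNK) cell. One-hot codes
are pairwise orthogonal, so the input carries no information about a word
beyond its identity — any syntactic structure found downstream must be
constructed by the circuit itself.

Every connection computes `F(W x + b)`, where `b` stands for the spontaneous
activity of the postsynaptic cells and `F` is the leaky rectified linear
function `y = x` for `x >= 0`, `y = alpha x` otherwise. The leak slopes
follow the assumption of near-linear cerebellar transmission: `alpha = 0.14`
into the Purkinje cells and along both recurrent relay hops, and
`alpha = 1.0` (exactly linear) from the Purkinje cells to the output cells.
In the reference variant the two relay connections (Purkinje cells to
recurrent output cells, recurrent output cells to recurrent input cells) are
fixed identity matrices with zero bias: they relay rather than transform.
Because the relay biases are zero, the reset state at a sentence start is
the zero vector, and the "spontaneous" Purkinje activity used as the origin
of trajectory plots is `F(b_p)`.

The Purkinje prediction signal is persistent between words: the recurrent
input cells hold their activity until the next word arrives, when the
Purkinje cells integrate the new word's feedforward drive with that stored
context,

```
purkinje = F( W_ff · onehot(word) + W_rec · recurrent_activity + b_p ).
```

This discrete-step persistence is the model's only temporal mechanism; there
are no spiking dynamics or membrane time constants.

One deliberately exposed switch: the nonlinearity is applied at *every*
connection arrow, including both relay hops. Setting `alpha_relay = 1` in
`build_circuit()` makes the relays exactly linear, recovering the
conventional simple-recurrent-network formulation in which the nonlinearity
acts once per time step; the default keeps the per-connection rule.

## Learning

Prediction errors reach the circuit through the climbing-fiber pathway. The
output activity `O` is normalized by a softmax into a distribution `P` over
the next word, and the error for the actual next word `j` is the cross
entropy `E = -log P_j`. (Written with the opposite sign the same quantity
would be maximized by a confident wrong answer; the negative-log-likelihood
convention is the one under which "reducing the prediction error" produces
the observed decreasing cross-entropy curves.) Gradients `dE/dW` are taken
only for the synapses on the dendrites of the Purkinje cells (both the
feedforward and the recurrent input blocks, plus `b_p`) and of the output
cells (`W_out`, `b_out`) — the two plastic sites of the cerebellar circuit —
and weights move by plain gradient descent `W <- W - eps * dE/dW`.

Defaults, chosen once on the synthetic corpus and logged with every run:
learning rate `eps = 0.1` on the per-position mean gradient of a batch of 32
sentences, 8 laps over the training sentences (the point where validation
performance plateaus), full backpropagation through the recurrent pathway
within a sentence (at most 16 words). A `bptt = "one-step"` mode treats the
incoming recurrent activity at each word as a constant, for studying
stricter biologically local credit assignment, and an `optimizer =
"adaptive"` (Adam) mode exists for speed; the plain-SGD default is bitwise
reproducible from `(seed, config, corpus)`. UNK is a training target like
any other cell but is excluded from evaluation: a correct "unknown" never
counts as a correct prediction, and such positions leave both numerator and
denominator of the correct rate.

Gradient correctness is enforced by tests that compare every
backpropagated derivative with central finite differences on toy circuits
(relative error below `1e-5`) for all four structural variants.

## Structural variants

* `rec-compress` — the identity relays are replaced by trainable
  compression/decompression connections (192 Purkinje cells to 48 recurrent
  output cells to 192 recurrent input cells at full scale; `n/4` and `n`
  generally), mirroring the convergent Purkinje-to-nucleus and divergent
  nucleocortical anatomy.
* `inhib-purkinje-output` — Purkinje output weights constrained nonpositive
  (Purkinje cells are GABAergic); the constraint is imposed at
  initialization and re-imposed by clipping after every update.
* `ei-split-input` — the input-to-Purkinje projection is split into a
  nonnegative block (direct parallel-fibre excitation) and a nonpositive
  block (inhibition via molecular-layer interneurons), each full width.
  After a full-length training run the excitatory block develops a distinct
  peak of near-zero "silent" synapses, which the unconstrained circuit's
  positive weights do not show — the physiological signature that motivates
  this variant. The population sizes are a design default (two full-width
  blocks scaled by `1/sqrt(2)`), since only the sign rule, not the split
  width, is anatomically fixed.

Weights initialize from a symmetric uniform distribution with Glorot
fan-in/fan-out scaling; sign-constrained blocks take absolute values times
their sign, so every circuit starts inside its constraint cone.

## The convergent (modular) model

The convergent model replaces the wide one-cell-per-word output with 16
output cells per module, reflecting the anatomical convergence from many
Purkinje cells onto few nucleus neurons. The correct-answer signal is then a
fixed 16-dimensional embedding row per word — `build_embedding()` offers a
truncated SVD of the corpus log co-occurrence matrix (self-contained
default), seeded random rows, or externally supplied pretrained vectors
reduced by PCA. A module's prediction is decoded as the word whose embedding
row is nearest (Euclidean) to its output pattern; ties go to the lowest
index, and the same metric gates learning: at every prediction position all
10 modules run forward (each advancing its own recurrent state — they must
run to compete), and only the module whose output lies closest to the
correct answer receives a mean-squared-error gradient step. Updates are per
position with one-step credit assignment, because the winner changes from
word to word and a within-sentence error chain through a gated mixture is
not well defined. The winner's update touches no other module's parameters —
an audit mode records, after every step, how many modules' weight digests
changed, and the test suite verifies exactly one across more than 10,000
steps. Module learning rate defaults to 0.05 on the per-position MSE.

Modules are ranked by exact-decoding accuracy over the final eighth of the
last lap, and the bank's top-5 candidate set at a position is the decoded
words of the five best modules ("prediction accuracy during training" is
measured on the training stream, and ranking is stable between training and
validation).

## The synthetic grammar

`grammar_spec()` defines the corpus generator that stands in for large text
corpora, so every analysis runs without downloads. It emulates the corpus
features the analyses depend on:

* S-V-O sentences of 3–16 words with determiner/adjective noun phrases,
  pronoun arguments, and prepositional phrases attached to the subject, the
  verb, or the sentence end. Role labels are phrase-wise (every token of a
  subject phrase is `S`), verbs and be-verbs are `V`, object-phrase tokens
  `O`, prepositional phrases and predicate adjectives `other`.
* Zipf-skewed word frequencies (weight `rank^-skew` within each category,
  default skew 1).
* A role-sharing fraction (default 0.8) of nouns usable as both subject and
  object heads, so word identity alone cannot separate S from O.
* Verb/noun homographs ("fish", "ship", "boat", ...) occupying about 30% of
  verb tokens, so word identity alone cannot tag every V token either — the
  desk-scale counterpart of the pervasive category ambiguity of real text.
* Verb–object affinity: with probability 0.5 a transitive verb draws its
  object head from a small preferred set ("sail the boat"), giving context
  genuine predictive value for object nouns.

What it does **not** emulate: semantics, agreement or long-range
dependencies, vocabulary scale (about 103 distinct words against a
3000-word inventory), and — importantly for interpreting probe results —
the *word sparsity* of a realistic evaluation set. In a 190-sentence natural
evaluation set most content words occur once, so a classifier reading
one-hot codes cannot generalize across the train/test split and input-layer
role separation sits at chance. In a small closed grammar every word recurs,
identity memorization partially succeeds, and input-layer separation is
above chance at desk scale (mid-90s for V, ~70% for S and O). Passing tests
therefore establish the *ordering* of layers (Purkinje above both input and
output) and the blocking dissociation, not an input layer at exactly 50%.

## Probing

* **Top-k scoring.** Candidates are the `k` strongest output cells (ties to
  the lower index, `k = 5` by convention). Word-type-conditional rates
  (noun-after-verb, etc.) restrict positions by the current and next token's
  type and role tags; "noun after a verb" is scored as predicting the object
  head noun of a transitive verb.
* **Role separability.** For a contrast such as S vs V/O, sentences are
  split 90/10 at the *sentence* level (so correlated positions never
  straddle the split), an RBF-kernel SVM is trained on the 90% and scored on
  the 10%, and the mean accuracy over 256 redrawn splits is reported.
  Hyperparameters are the kernel library defaults: unit cost and the
  variance-scaled kernel width `gamma = 1/(d * var(x))`; the flat `1/d`
  width makes dense-layer kernels nearly constant at this scale and
  degenerates to majority voting. Splits that leave a training class empty
  are redrawn and counted. A null calibration (balanced random labels on
  Gaussian vectors) must and does return 50% within noise.
* **PCA and separating directions.** Purkinje trajectories are visualized in
  the 2–3 components that maximally preserve the variance of the labelled
  word positions. The plotting axes of the role views are unit normals of
  linear maximum-margin hyperplanes, oriented so the contrast's class sits
  on the positive side. The similarity index between a separating direction
  and a PCA dimension is their squared dot product; over the complete
  orthonormal basis the entries sum to 1.
* **Weight statistics.** The silent-synapse threshold is `tau = 2%` of the
  weight standard deviation (configurable); for the `ei-split-input` variant
  statistics are reported per sub-population.

## Problem sizes and reproducibility

The package's reference experiment — the one its tests run — uses corpora of
2000 sentences over the default grammar (V = 100 plus UNK), 96 Purkinje
cells, 8 training laps, and three independent seeds, with probe batteries of
64-repeat SVM separations on a 150-sentence labelled evaluation corpus; the
convergent study uses 1200 sentences, 10 modules of 64 Purkinje cells and 4
laps. These sizes reproduce the qualitative pattern portfolio (frequency
baseline exceeded, Purkinje-peaked layer profile, blocking dissociation with
preserved V separation, silent-synapse peak) in a few minutes of CPU time.
Every stochastic step — corpus sampling, splits, initialization, shuffling,
SVM repeats — derives from explicit seeds, and all run artifacts embed their
configuration hash.

## Known limitations

* The headline full-scale numbers (38.3% top-5 on mixed novel corpora,
  96% role separations over 1328 positions, medians over 20 replicas)
  require external corpora and hours of training; the package reproduces the
  phenomena at reduced scale, not those exact values.
* Under the strongly skewed default grammar the unigram top-5 baseline is
  unusually high (~29% of targets are among five word types). The full
  10-module convergent candidate set beats it (~33%), but the 5 selected
  modules alone (~24%) do not: winner-take-error specialization makes the
  individually best modules redundant, so their union loses coverage
  relative to the full bank. At full scale, where the frequency baseline is
  far lower, the selected-module rate clears it comfortably.
* Very early in training the model predicts by word frequency; at this
  output width the signature is a frequency-dominated candidate set with the
  most frequent word ranked first in every context, rather than an exactly
  identical top-5 set.
* Significance tests across 20 trained replicas are not run by default; the
  replica count is configurable and desk-scale defaults use 3.
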