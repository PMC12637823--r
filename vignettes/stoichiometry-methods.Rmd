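---
title: "Predicting protein complex stoichiometry from subunit embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein complex stoichiometry from subunit embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
```

## The problem

Most proteins act as oligomers: assemblies of several polypeptide chains,
either copies of one entity (homomers) or of several distinct entities
(heteromers).  The *stoichiometry* of a complex — how many copies of each
unique entity the assembly contains, written `AxBy...` — is a prerequisite
for structure prediction tools and is hard to obtain experimentally.
`oligostate` predicts a ranked list of candidate stoichiometries for a
complex given one fixed-length embedding vector per unique entity (for real
proteins, typically a mean-pooled protein language model representation;
the package itself is agnostic about where the vectors come from).

## The model

Given a complex with $C$ unique subunits and embeddings
$X \in \mathbb{R}^{C \times d}$, each row is first transformed by a
two-layer MLP into $h_c^{(0)}$.  The encoder then applies `n_layers`
masked multi-head **additive graph attention** layers over the complete
graph on subunits.  For head $h$ with projection $z_c^h = W^h h_c$, the
attention logit between subunits $c$ and $c'$ is

$$e_{cc'}^h = \mathrm{LeakyReLU}\!\left(a_{src}^{h\top} z_c^h +
a_{dst}^{h\top} z_{c'}^h\right),$$

masked to $-\infty$ on the diagonal and at padded positions, normalized by
a softmax over the valid neighbors, and used to aggregate
$\sum_{c' \neq c} \alpha_{cc'}^h z_{c'}^h$.  Head outputs are
concatenated, linearly projected, passed through ELU and dropout, and
added back through a residual connection.  Two conventions are worth
stating because the architecture does not force them:

* **Single-subunit complexes.**  A homomer's only subunit has no
  neighbors; its softmax row is defined as exactly zero, so the
  aggregated message is the zero vector and the representation flows
  through the residual path.  This lets homomers and heteromers share one
  set of weights.
* **Padding.**  Padded rows are masked out of every softmax and pass
  through each layer unchanged, so valid outputs are bit-for-bit
  independent of padded content (tested exactly, not to tolerance).

Two prediction branches read the encoded representations.  The **local
head** is a linear-softmax classifier giving each subunit a distribution
over copy numbers $1..K_{max}$.  The **global head** predicts the
complex's *composition* — the entity-agnostic multiset of copy numbers,
e.g. $(3,2)$ for either `A2B3` or `A3B2` — with a conditional
mixture-of-experts: the subunit representations are mean-pooled over valid
rows (the minimal symmetric pooling, which guarantees the distribution is
invariant to subunit order) and routed to the expert dedicated to the
complex's subunit count.  The expert's logits over the compositions seen
at least `min_count` times in training are joined with a shared expert's
single logit for the trailing `"other"` class in one softmax.  Counts
without a dedicated expert fall back to the shared expert alone, whose
distribution is then the degenerate point mass on `"other"`; such
complexes are excluded from the global loss term.

Training minimizes the mean per-chain cross-entropy of the local head plus
`lambda_g` (default 1) times the mean global cross-entropy over
heteromers with a dedicated expert.  Because no automatic differentiation
engine is used, all gradients are derived analytically (reverse mode
through the softmax-over-valid-neighbors, the additive logits, ELU,
dropout, residual, pooling, and both heads) and are checked against
central finite differences to a relative error below $10^{-4}$
(`gradient_check()`).  Optimization is minibatch Adam (learning rate
$10^{-3}$ by default) with early stopping on validation top-1 accuracy;
every source of randomness — initialization, shuffling, dropout — derives
from one explicit seed, so runs are bit-reproducible.

## From distributions to ranked stoichiometries

For a homomer the ranking is simply the local distribution.  For a
heteromer, `beam_candidates()` searches over the product of the per-chain
distributions, keeping the `beam_width` best partial assignments per
chain; with the default width `max(50, 10 * n_out)` the search is exact
for realistic $C$ and $K_{max}$ (verified against exhaustive enumeration
in the tests, including tie-breaks).  Each candidate state's final score
is the weighted combination

$$\mathrm{score} = \alpha \cdot p_{\mathrm{global}} +
(1-\alpha) \cdot p_{\mathrm{chain}},$$

where $p_{\mathrm{chain}}$ is the product of its per-chain probabilities
and $p_{\mathrm{global}}$ the global head's probability of its
composition.  Candidates whose composition is not in the vocabulary share
the `"other"` probability equally, so that mass is never counted twice.
Ties are always broken by the lexicographically smaller notation string,
making rankings deterministic across platforms.  The default
$\alpha = 0.5$ can be replaced by `select_alpha()`, a grid search over
$\{0, 0.1, \ldots, 1\}$ maximizing validation top-5 accuracy.  We apply
the combination to the beam's candidate pool rather than enumerating the
whole global vocabulary: the global branch is most useful as a re-ranker
of locally plausible states, and this keeps prediction cost independent
of vocabulary size.

Two config switches ablate the architecture: `use_gat = FALSE` removes
the attention layers (each chain is then classified from its own
embedding alone) and `use_global = FALSE` forces $\alpha = 0$.

## Baselines

The **template predictor** scores candidate copy numbers for each chain
by weighted voting over its template-search hits: copy number $y$ gets
$\sum_k \mathrm{bits}_k \cdot \mathrm{sim}_k \cdot
\mathbf{1}[T_k = y] \,/\, \sum_k \mathrm{bits}_k \cdot \mathrm{sim}_k$
over the top `top_k` (default 30) hits, where $\mathrm{bits}_k$ is the
bitscore, $\mathrm{sim}_k$ the sequence identity (or TM-score in structure
mode, both normalized by the larger chain length upstream), and $T_k$ the
template's copy number.  The scores form a distribution and are invariant
to uniform bitscore rescaling.  Chains with no usable hits fall back to
one copy.  Per-chain distributions are combined into complex rankings with
the same product + beam scheme as the deep model's local branch.  The
package does not run the alignment search itself; it parses the standard
12-column tabular output of sequence/structure search tools.

The **frequency baseline** ranks compositions by their training frequency
within each subunit count ($\mathrm{freq}(S) = N_S / N_C$), instantiates
non-homomeric compositions by assigning copy numbers to chains uniformly
at random, and averages accuracy over 1000 shuffle runs (homomer-only
test sets therefore have exactly zero variance).  Unseen subunit counts
yield one copy per chain.

## Evaluation and curation

`top_n_accuracy()` is the fraction of targets whose true state appears
among the first $N$ ranked candidates.  `micro_macro_f1()` treats top-1
composition labels as a single-label multiclass problem: micro-F1 is
computed over raw labels (and provably equals plain accuracy in this
setting — the package asserts it rather than reporting two numbers that
could silently diverge), while for macro-F1 classes with fewer than
`min_class_count` (default 10) true instances are first aggregated into
`"Other"`; a threshold of 0 disables aggregation for small benchmark
sets.

The curation utilities operate on pre-extracted per-entity metadata
tables, not on mmCIF (parsing coordinates is out of scope and would tie
the package to an archive snapshot): keep all-polypeptide assemblies,
deduplicate identical (sequence multiset, stoichiometry) pairs keeping
the earliest deposition (ties by id), split by deposition date (defaults:
training before 2023-10-01, validation through 2024-05-01, test after,
with experimental support required for test), and remove test complexes
whose chains can all be mapped to one reference complex at identity
strictly above 0.8.  The mapping is a maximum-total-identity bipartite
assignment solved with a Hungarian algorithm ("optimally mapped" means
global, not greedy, matching — the tests include the 2×2 matrix where
greedy fails) and is verified against brute-force enumeration up to 5×5.
Pairwise identities are supplied by a pluggable function, because
identity computation belongs to the external search tool that produced
them.  Size filters for structure-prediction subsets use strict bounds on
total (< 4200) and single-chain (< 500) length and at most 8 copies per
subunit.

## The synthetic generator

Real training data for this problem (embeddings of curated assemblies)
cannot ship with a package, so `generate_dataset()` plants a controllable
copy-number signal.  In standard mode each copy number $k$ owns a fixed
random centroid $\mu_k \in \mathbb{R}^{d_{in}}$ (drawn once per seed and
stored with the dataset) and an entity with $k$ copies gets
$\mu_k + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$.  Compositions
are drawn from a prior; the default prior weights entity counts by
$2^{-(C-1)}$ and copy numbers by $2^{-k}$, so monomers, dimers and small
copy numbers dominate, qualitatively mimicking the imbalance of
structural databases without claiming their exact frequencies.  The
default noise ($\sigma = 1$) leaves the signal learnable but not
trivially separable at $d_{in} = 32$.

Two benchmark tasks probe the two architectural components:

* **Dependency task** (`dependency_mode = TRUE`, $\sigma = 0.5$):
  complexes are entity pairs; each entity's embedding encodes only its own
  latent key while its true copy number equals the *partner's* key.  A
  per-chain classifier is at chance on this task by construction — the
  tests verify that decoding a chain's own embedding recovers its key,
  not its copy number — so any accuracy above chance must come from
  message passing.
* **Rare-composition task** (`rare_composition_prior()`, $\sigma = 3.5$):
  only the symmetric compositions `1-1 ... 4-4` occur, but per-chain
  marginals are broad and the noise makes local predictions genuinely
  uncertain.  Ranking by the product of chain distributions proposes many
  asymmetric states that never occur; the global head learns to veto
  them.  The noise level was chosen so the local signal is weak but
  present — at low noise the local branch alone saturates the task and
  the global head has nothing to add.

What passing these tests shows — and does not show.  The synthetic
embeddings are isotropic Gaussian clusters; real protein language model
embeddings have anisotropic geometry, correlated entities, and label
noise.  The desk-scale checks demonstrate that the architecture can
extract a cross-chain signal when one exists and that the global branch
helps exactly when the composition prior is informative; they say nothing
about absolute accuracy on real assemblies.

## Numerical choices and problem sizes

Default hyperparameters follow common practice for this architecture
(`d_model = 256`, 3 layers, 4 heads, dropout 0.1, `K_max = 12`,
dedicated global experts for subunit counts 2–5).  The package's own
benchmarks and tests run a reduced encoder (`d_model = 32`, 2 layers, 2
heads, `K_max = 6`) on 2000 training complexes — sizes at which the
planted signals are comfortably learnable and a full ablation (two models
× three seeds × two tasks) trains in a few minutes on one CPU core.
Dropout is applied before the residual addition.  Softmax rows with no
valid entry are defined as exact zeros rather than NaN.  Copy numbers
above `K_max` are representable in the notation but outside the class
space; such instances are excluded from training with a warning.
Products of chain probabilities are accumulated left-to-right in double
precision everywhere (including `chain_probability()`), so the beam, the
oracle enumeration, and reported scores agree bit-for-bit.

## Known limitations

Protein-only complexes; at least one copy of every input entity is
assumed (the package does not predict absence of interaction).  The
global vocabulary is frozen at training time; novel compositions can only
be ranked through the `"other"` class.  The encoder treats the complex as
a complete graph, which is appropriate for the small $C$ of biological
assemblies but would not scale to hundreds of distinct entities.
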