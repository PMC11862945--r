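---
title: "Ancestral-like protein design with a sequence VAE: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral-like protein design with a sequence VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein engineers often want variants of a query enzyme that keep its
function but gain stability or solubility. Phylogenetically reconstructed
ancestors tend to have these properties, but full ancestral sequence
reconstruction is heavy and tied to one tree. SeqVAE follows a lighter,
generative route: learn a two-dimensional latent representation of the
query's family from its multiple sequence alignment (MSA), verify that the
latent space is organized phylogenetically (ancestor-like sequences sit
nearer the origin), and then decode candidate designs along the straight
line from the query's embedding to the latent-space origin. The output is
not a single "best" sequence but a profiled series of 100 increasingly
divergent, ancestor-like candidates from which a scientist selects designs
for synthesis.

## The model

Sequences live in fixed MSA coordinates over a 21-symbol alphabet (20 amino
acids plus the gap, which the model treats as an ordinary symbol). A
sequence of width $N$ is one-hot encoded into a vector of length $21N$.

The variational autoencoder is deliberately small:

* **Encoder**: one dense hidden layer of $N$ tanh units mapping the one-hot
  input to a diagonal Gaussian $q(z \mid x) = \mathcal{N}(\mu(x),
  \sigma^2(x))$ over a latent space of dimension 2.
* **Decoder**: one dense hidden layer of $N$ tanh units mapping a latent
  point $z$ to $N$ independent categorical distributions over the 21
  symbols (per-column softmax).
* **Loss**: categorical negative log-likelihood of the true symbols under
  one reparameterized sample, plus the closed-form KL divergence
  $\tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - \log \sigma_d^2 - 1)$
  to the standard-normal prior, with equal weighting of the two terms.
* **Training**: minibatch Adam, learning rate $10^{-3}$, early stopping
  once the mean epoch training loss has failed to improve on the best seen
  for more than 3 consecutive epochs (absolute tolerance $10^{-6}$),
  optionally with an exponentially decreasing weight decay
  $w_t = w_0\gamma^t$.

There is no deep-learning framework behind this: the forward pass, the
reverse-mode gradients and Adam are implemented directly in R matrix
algebra. At these sizes (hundreds of sequences, one hidden layer) that is
both fast enough and fully deterministic under a seed, which the pipeline
exploits heavily — every stage is bit-reproducible from its run report on a
fixed platform with single-threaded BLAS.

The conditional variant (CVAE) appends a one-hot solubility tag
(LOW/MEDIUM/HIGH) to both the encoder input and the decoder input. Tags
come from quantile-binning an external per-sequence solubility score table
into three equal-mass bins; the package never predicts solubility itself.

## Why early stopping monitors the training loss

Only "the loss" is monitored, on the training set: the 5% held-out split
is reserved as a *positive control* for the reconstruction-accuracy
separation analysis, and using it for early stopping would leak it into
model selection. With a patience of 3 epochs and a noisy minibatch
objective the rule mostly acts as a divergence guard; the epoch cap is the
practical budget. For the synthetic benchmark we cap at 800 epochs
(the unconditional model) and 300 epochs (the conditional models), sizes at
which the generative statistics below are well converged.

## Preprocessing

Preprocessing is query-anchored throughout: the query is exempt from
sequence filtering and clustering, and column filtering drops any column
where the query has a gap, plus columns whose gap fraction exceeds a
threshold (0.5 by default; the `strict` mode applies a lower default of
0.2, removing frequent-gap columns even where the query holds a residue).
Defaults — maximum per-sequence gap fraction 0.25, greedy clustering at 90%
identity, 5% hold-out — are conventional MSA-hygiene values and are all
exposed as configuration. The surviving columns are recorded in a 0-based
column map, the single source of coordinate truth; external (unaligned)
sequences are projected into these coordinates by dynamic programming
against the per-column frequency profile (log-frequency match scores with a
1/21 pseudocount, linear gap penalty of −2). Ambiguity codes are mapped to
the gap symbol with a warning so the alphabet arity stays at 21.

Order of operations is fixed: filter sequences, filter columns, cluster,
split. Binning of solubility scores happens on the full preprocessed set
before the hold-out split, so tag boundaries do not depend on the split
seed.

## The three audits of a trained model

**Generative capacity.** 3,000 sequences are decoded from prior draws and
compared with the input MSA via first-order statistics (per-column symbol
frequencies) and second-order statistics (pairwise covariances
$f_{ij}(a,b) - f_i(a)f_j(b)$ over all column pairs $i<j$ and all symbol
pairs, gap included, zero-frequency entries retained). Agreement is the
Pearson correlation over the flattened tables. Generated sequences are
drawn *categorically* from the decoder distributions — argmax decoding
would collapse diversity and make the first-order comparison degenerate.
The profile-sampled negative control (each column sampled independently
from its empirical frequencies) has by construction the right first-order
statistics and no second-order structure, which is exactly what makes it
the right baseline for the covariance comparison.

**Reconstruction-accuracy controls.** Each sequence's average
reconstruction accuracy is the mean identity between the sequence and the
argmax decodes of latent samples drawn from its posterior (5,000 samples by
default; 200 in the scaled-down benchmark, where the accuracy estimate's
binomial noise is already far below the negative/positive separation).
Identity counts gap–gap matches as matches, since all sequences live in
fixed MSA coordinates. Four control sets are scored: profile-sampled
negatives, a training subset, the 5% held-out positives, and optionally the
trajectory designs; negative and positive sets are sized at 5% of the
training set. A trained model separates negatives from family sequences at
an accuracy cutoff of about 50%.

**Phylogeny-to-latent geometry.** Given a rooted tree whose every node
carries an aligned sequence (true ancestors from the simulator, or external
reconstructions — the package infers neither trees nor ancestors), every
node is embedded at its posterior mean. Per root-to-leaf lineage we report
(i) the Pearson correlation between node depth (cumulative branch length;
unit lengths when the tree has none) and distance of the embedding from the
origin, and (ii) the signed cosine between the lineage's first principal
axis — oriented from the leaf end toward the root end by projection order —
and the unit vector from the leaf embedding toward the origin. Lineages
with fewer than 3 nodes, or degenerate (constant) geometry, are flagged
undefined and excluded. Both metrics only involve distances and angles to
the origin, so they are invariant under rotations of the latent space.
We read "branches" as root-to-leaf lineages; per-segment alternatives exist
but lineages match the per-branch histogram semantics and are stable for
short segments. Ancestor-closed random subsampling (about 100 nodes,
root always kept, parent pointers contracted) checks that the majority
signs are not artifacts of tree size.

## The straight-line trajectory

The query is encoded, and the segment from its mean embedding to the origin
is divided into 100 equal intervals. All 101 boundary points (index 0 = the
query's own reconstruction, index 100 = the exact origin) are argmax-decoded
with ties broken toward the lowest symbol index, making designs
deterministic, platform-stable artifacts. Each design is profiled with:

* **average reconstruction probability** — the mean over columns of the
  probability the decoder assigns to the decoded symbol at that design's
  own latent point (the mean point, not an average over latent samples:
  designs are points, not distributions);
* identity to the query, and identity to (plus identifier of) the closest
  training sequence, ties broken by alignment order;
* insertion and deletion counts relative to the query in shared MSA
  coordinates (design residue where the query has a gap = insertion, and
  vice versa).

The package deliberately makes no automatic candidate selection — choosing
which indices to synthesize is scientific judgment — but offers indel and
identity filters on the FASTA outputs.

## The synthetic benchmark

All quantitative claims the test suite makes are demonstrated on a
simulated family with known truth, emulating the structure the metrics
assume:

* a star phylogeny of 4 clades radiating from the root at branch length 1
  (mirroring a family with several subfamilies), random bifurcating clades
  of 100 leaves each with exponential branch lengths (mean 0.2);
* per-site substitutions at rate 0.3 per unit branch length, uniform over
  the 19 alternative residues — a Jukes–Cantor-style model, adequate for
  metric testing though far from a realistic substitution matrix;
* three planted coupled column pairs (strength 0.95): whenever either
  member changes on a branch, the dependent column re-syncs to a paired
  symbol with that probability, creating heritable pairwise covariation
  that profile sampling destroys;
* a low indel rate (0.002 events/site/unit length): deletions become gaps
  inherited down the lineage, insertions add new global columns (gap
  everywhere else) so the coordinate system stays strict;
* a planted solubility score per leaf: indicator weights on six columns
  (the column's majority residue scores 1) plus Gaussian noise (sd 0.1),
  giving the conditional model a learnable, clade-correlated target.

What the simulator does *not* emulate: site-rate heterogeneity, realistic
exchange matrices (WAG/LG), selection, alignment error, or database biases
of real homolog mining. Passing the benchmark therefore shows the
*machinery* recovers planted structure under its own assumptions — it does
not certify performance on any real family.

Benchmark problem sizes were chosen once: 400 leaves × ~140 columns trains
in minutes on one CPU while leaving all recovery margins wide (first-order
agreement ≈ 0.95 against a 0.9 gate; control separation ≈ 19 pooled
standard errors against a 2-SE gate; ≈ 86% of lineages with positive
depth–origin correlation against a 50% gate — the values
`scripts/acceptance.R` recomputes).

## Numerical choices and degenerate inputs

* Softmax is computed with per-column max subtraction; categorical NLL
  clips probabilities at $10^{-12}$.
* Argmax ties (exactly equal probabilities) resolve to the lowest symbol
  index everywhere.
* `statsAgreement` refuses zero-variance (degenerate) statistics rather
  than returning NaN; per-path geometry flags degenerate paths as NA and
  summaries exclude them.
* Quantile binning breaks score ties by identifier, and the remainder rule
  puts extra members in the lowest bins first; bin composition is invariant
  to input row order.
* Empty alignments, ragged inputs, missing tags, width mismatches and
  untrained models all fail fast with contract errors.
* Checkpoints are versioned JSON carrying the config, flat parameter
  vectors, the fixed symbol order and the column map, so a decode is
  portable across sessions.

## Known limitations

* A 2-D latent space is a strong bottleneck; the package exposes
  `latentDim` but the pipeline's geometric metrics are designed for 2-D.
* One reparameterization sample per sequence per step makes the epoch loss
  stochastic; with patience 3 the stop is occasionally noise-triggered on
  small data (the epoch cap is the effective budget there).
* The profile aligner assumes the external sequence is no longer than the
  MSA width (no residue skipping), which is the correct contract for
  projecting close homologs into fixed coordinates, not a general aligner.
* Training is single-threaded by design for bit-reproducibility; wall-clock
  scales roughly with sequences × width² per epoch.
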