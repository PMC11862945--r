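# SeqVAE

Ancestral-like protein sequence design with a small variational autoencoder
(VAE) trained on a query-anchored family multiple sequence alignment (MSA).

Reconstructed ancestors of modern enzymes are often more stable and more
soluble than their descendants, but classical ancestral sequence
reconstruction is tied to one tree and one set of assumptions. SeqVAE takes
a generative shortcut aimed at protein engineers: learn a 2-dimensional
latent representation of the query's family, check that the latent space is
organized phylogenetically (lineages run outward from the origin), and then
decode candidate *ancestor-like* designs along the straight line from the
query's embedding to the latent-space origin — the **straight-line
evolutionary strategy**.

## The model in brief

For an MSA of width $N$ over the 21-symbol alphabet (20 amino acids + gap):

* encoder: one-hot input ($21N$) → one tanh hidden layer of $N$ units →
  latent Gaussian $\mathcal N(\mu, \sigma^2)$, $\dim z = 2$;
* decoder: $z$ → one tanh hidden layer of $N$ units → $N$ per-column
  categorical distributions (softmax over 21 symbols);
* loss: categorical reconstruction NLL + closed-form KL to the standard
  normal prior, equally weighted; Adam (lr $10^{-3}$), early stop after
  more than 3 non-improving epochs;
* optional conditioning: a LOW/MEDIUM/HIGH solubility tag (quantile-binned
  from an external score table) appended to encoder and decoder inputs.

Designs decoded along $z_k = (1 - k/100)\,\mu_{\text{query}}$,
$k = 0..100$, are profiled with their average reconstruction probability,
identity to the query, identity to the closest training sequence, and
insertion/deletion counts — the statistical profile from which candidates
are picked for synthesis.

The networks, gradients and Adam are implemented directly in R matrix
algebra: at these sizes that is fast, dependency-free and bit-reproducible
under a seed.

## Worked example

Everything below runs offline on a simulated benchmark family (400 leaves,
4 clades, ~140 columns, known true ancestors, planted pairwise covariation
and planted solubility):

```r
library(SeqVAE)

sim   <- fixture("bench")                       # simulated family + true tree
split <- holdoutSplit(sim$alignment, 0.05, seed = 12L)

cfg   <- modelConfig(msaWidth = alnWidth(split$train), seed = 4L)
model <- trainVAE(initModel(cfg), sequences(split$train),
                  config = trainConfig(maxEpochs = 800L))

# generative capacity: input vs 3,000 generated sequences
gen <- sampleGenerated(model, n = 3000L, seed = 5L)
statsAgreement(siteStats(sequences(split$train)), siteStats(gen))
#>  firstOrderR secondOrderR
#>    0.9579814    0.6469009

# latent-space phylogeny: depth vs distance from origin, per lineage
emb <- embedTree(model, sim$tree)
geometrySummary(depthOriginCorrelation(sim$tree, emb)$r)$fractionPositive
#> [1] 0.855

# the straight-line trajectory, profiled
traj <- profileDesigns(generateTrajectory(model, querySeq(split$train)),
                       split$train, model)
head(traj$profile[, 1:4], 3)
#>   index reconstruction_probability identity_to_query identity_to_closest_training
#> 1     0                  0.8392905         0.9432624                    0.9432624
#> 2     1                  0.8378705         0.9503546                    0.9503546
#> 3     2                  0.8368884         0.9361702                    0.9361702
writeDesigns(traj, "designs")                  # FASTA + TSV/JSON profile
```

Read: the model reproduces per-column residue frequencies of the family
almost perfectly (first-order r ≈ 0.96) and much of the pairwise covariance
structure (r ≈ 0.65) that profile sampling destroys entirely; 86% of
root-to-leaf lineages of the *true* simulated tree run outward from the
latent origin; and the design series starts at a 94%-identity
reconstruction of the query and drifts monotonically toward more divergent,
ancestor-like sequences (identity to the query falls to ~35% at the
origin).

A command-line wrapper over the same stages
(`simulate`, `preprocess`, `train`, `evaluate`, `phylo`, `generate`) is in
`inst/scripts/seqvae-cli.R`; every stage writes a JSON run report echoing
its full configuration and seeds, from which the run can be reproduced
bit-for-bit.

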