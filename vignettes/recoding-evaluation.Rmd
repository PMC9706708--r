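---
title: "Evaluating amino-acid recoding: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating amino-acid recoding: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Six-state recoding replaces each amino acid by a label for its bin in a
reduced alphabet — Dayhoff-6 uses the bins {AGPST}, {DENQ}, {HKR}, {ILMV},
{FWY}, {C}, grouping residues that exchange frequently — and thereby masks
within-bin substitutions. Its proponents argue that masking the most
exchange-prone substitutions reduces saturation and compositional
heterogeneity, improving the fit of tractable models and hence the accuracy
of inferred topologies; its critics argue that it merely discards
information. `aarecode` implements a simulation pipeline that makes this
dispute quantitative: it simulates alignments whose across-site
compositional heterogeneity a deliberately restricted model cannot describe,
and measures whether recoding changes (i) model adequacy, via posterior
predictive Z-scores, and (ii) topological accuracy, via support for the true
tree on Farris-zone and Felsenstein-zone trees.

## The generative model

Data are simulated under a finite profile-mixture model in the CAT family.
Each site draws a frequency profile $\pi_c$ (a point on the 20-simplex) with
weight $w_c$, a relative rate $r$ from a discrete Gamma($\alpha$, mean 1)
with $G$ categories, and evolves along the tree by the reversible generator
$Q_c = \rho \,\mathrm{diag}(\pi_c)$, row-normalised to one expected
substitution per unit branch length at stationarity. The exchangeabilities
$\rho$ are the empirical LG matrix for simulation; inference uses the
Poisson (F81) special case with all $\rho_{ij}$ equal, for which the
transition kernel has the closed form
$P_{ij}(t) = e^{-\beta t}\delta_{ij} + (1 - e^{-\beta t})\pi_j$ with
$\beta = 1/(1 - \sum_i \pi_i^2)$. All likelihoods are computed by
Felsenstein pruning over compressed site patterns with per-node scaling;
the F81 structure collapses the per-branch matrix-vector product to $O(k)$
per pattern, which is what makes desk-scale Markov chain Monte Carlo
affordable at $k = 20$.

### Profiles: why raw Dirichlet draws are not enough

`default_study_model()` draws `n_categories = 50` profiles from a symmetric
Dirichlet with concentration 0.15. Raw sparse Dirichlet draws, however,
scatter their mass over arbitrary amino acids, whereas empirically estimated
site profiles concentrate mass on biochemically similar, frequently
exchanging residues — the very regularity that motivates the Dayhoff bins.
A generator without that structure produces data in which Dayhoff-6 is no
better than a random six-state scheme, which contradicts the premise being
tested. Each raw profile is therefore diffused for a short time
$\tau = 0.4$ under the normalised LG process
($\pi \leftarrow \pi P_{\mathrm{LG}}(\tau)$), which spreads every state's
mass onto its high-exchangeability neighbours while preserving sparsity at
the level of exchangeability groups. Concentration, $\tau$, $\alpha = 0.5$
and the category count are exposed as arguments; the defaults are the
package's study conditions.

## Zone trees and study conditions

`zone_tree()` builds the four-clade problem: outgroup (long stem),
Ctenophora (long stem), Porifera (short stem) and the remaining animals
(short stem). Under Ctenophora-sister the two long stems are adjacent across
the internal branch (Farris zone, where attraction reinforces the true
tree); under Porifera-sister they are separated (Felsenstein zone, where
long-branch attraction pulls inference toward the wrong tree). The default
branch lengths — long 0.9, short 0.1, internal 0.1 substitutions/site for
quartets; long 1.1 for the 10-taxon ladder stage — were chosen once, by
locating the Felsenstein zone for this generator: long enough that the
homogeneous model is attracted on amino-acid data, short enough that
better-fitting analyses are not. The ladder stage sits deliberately at the
crossover depth, where the richest model in the ladder recovers the true
tree from the amino-acid data — the accuracy-vs-adequacy regression needs
that adequate anchor, exactly as the published version of the relationship
is anchored by its best-fitting models. They are study conditions, not
constants of nature, and are arguments everywhere.

The package's canonical experiment (`experiment_config()` defaults plus the
`analysis/` drivers) uses quartets with 10,000 sites and 8-10 replicates
per arm for the accuracy stage, and 10-taxon trees with 5,000 sites and 2-3
replicates per arm for the adequacy ladder. These sizes are the package's
desk-scale design: large enough that every directional effect it claims is
visible, small enough to run on one CPU in minutes. They reproduce
directions, not published magnitudes, which came from cluster-scale runs on
hundredfold larger data.

## Inference

### Maximum likelihood

`ml_fit()` performs coordinate ascent on a fixed topology: one-dimensional
optimisation per branch (on the log scale — the likelihood is flat in a
branch length once the branch saturates, and probing on the linear scale can
strand the optimiser on that plateau), then the Gamma shape, then
family-specific parameters. Mixture profiles are initialised by k-means on
site frequency vectors and updated by a guarded expectation-maximisation
step: weights have the usual closed-form update; a profile moment-update is
accepted only if the observed-data log-likelihood does not decrease, which
enforces monotonicity without a closed-form M-step (none exists for F81
mixtures, where the profile enters both the transition kernel and the root
density). Convergence is declared at a sweep improvement below `1e-4` log
units; non-convergence is flagged, not raised.

### Markov chain Monte Carlo

`sample_posterior()` runs Metropolis-Hastings over an explicit candidate
topology list (the three quartet-of-clades resolutions), branch lengths, the
Gamma shape, and mixture parameters, with categories marginalised in the
likelihood. One cycle sweeps every move class: multiplier proposals on
branch lengths (optionally a random subset per cycle) and on $\alpha$,
Dirichlet proposals centred on the current value for weights and for one
profile, and a uniform topology proposal that carries branch lengths across
topologies by matching edge bipartitions (unmatched edges — the
rearranged ones — are paired in sorted order; the map is a permutation, so
the proposal stays symmetric). Priors: exponential(mean 0.1) branch lengths,
exponential(mean 1) shape, symmetric Dirichlet(1) elsewhere. Chains default
to warm starts (a branch sweep under a cheap single-profile surrogate, then
guarded EM for mixtures): short chains started at k-means profiles otherwise
spend their whole budget fitting, and over-sparse start profiles inflate
posterior-predictive Z-scores. Topology posterior probability is the
fraction of retained post-burnin cycles at each candidate;
`convergence_check()` compares two chains and flags PP differences above
0.1.

The ladder of inference models is nCAT-style: F81 mixtures with 1, 4 and 8
categories (`poisson_g`, `mix_n_g`). Ladders continued to 16 categories
overparameterise data of this size and destabilise short chains (profiles
pinned near a sparse k-means start make the predictive under-disperse,
pushing Z artificially positive), so the canonical ladder stops at 8.

## Model adequacy

`div_stat()` is the mean number of distinct non-missing states per column;
`mean_comp_stat()` the mean over taxa of summed absolute deviations between
taxon and global frequencies. `ppa()` simulates one alignment of the
observed dimensions from each of `n_sims` posterior draws and reports the
signed Z-score $(\mathrm{obs} - \overline{\mathrm{pred}})/
\mathrm{sd}(\mathrm{pred})$; observed missing cells are masked at the same
positions in every predictive replicate so both sides of the comparison use
identical cell sets. Under this sign convention, profile-heterogeneous data
analysed under a too-homogeneous model give large *negative* diversity
Z-scores (the data are less diverse per column than the model's predictive);
comparisons across models and data types use $|Z|$, and
$\delta$PPA-Div $= |Z_{aa}| - |Z_{rec}|$. The interpretation bands
(`fit_band()`): adequate to $|Z|\le2$, acceptable to 3, acceptable-to-fairly-
poor to 5, poor to 10, very poor beyond. Note that with only four taxa the
diversity statistic has little power (columns take at most four states),
which is why the adequacy stage uses ten taxa.

## Parsimony, information loss and saturation

`fitch_length()` counts minimal state changes (missing symbols are the full
state set; the basal trifurcation of an unrooted tree is combined pairwise,
which is exact for three subtrees). `parsimony_search()` runs random
stepwise addition with nearest-neighbour-interchange refinement and keeps a
single best tree. Information loss is the percent reduction in tree length
after recoding; because recoding merges states, the recoded length can never
exceed the source length, and the loss lies in [0, 100]. The per-branch loss
map uses one deterministic minimal reconstruction (root takes the state
present in most root-child state sets, every other node keeps its parent's
state when possible, lowest state index on ties), whose per-branch steps sum
exactly to the Fitch length. Saturation follows the NJ-based recipe:
observed P-distances, an NJ tree, tip-to-tip distances from it regressed
through the origin against the reference-tree distances
($M = \sum xy / \sum x^2$), and $\mathrm{Sat} = 1 - M$. Saturation values
are comparable only within a state space: six-state distances are compressed
relative to the amino-acid branch lengths, so amino-acid and recoded
saturation should each be read against their own baselines.

## The experiment pipeline

`run_experiment()` composes the stages: simulate per arm and replicate,
recode into the requested data types (Dayhoff-6, and random schemes at 0%
and 90% similarity found by rejection sampling with re-scored constructive
shortcuts at 90%), sample topology support per inference model, classify
each replicate (`accurate` / `incorrect` / `unresolved` at threshold 0.5 by
default, 0.95 as the stringent variant), pool Total Accuracy over both arms,
attach PPA Z-scores, and regress $\delta$TA on $\delta$PPA-Div across
models. Per-stage wall times are recorded (`with_stage()`), echoing the
computational-efficiency accounting that motivates recoding in practice;
no timing number is load-bearing.

## Scheme similarity

Random schemes follow the Dayhoff-6 size template (5, 4, 4, 3, 3, 1).
Similarity between two schemes with equal size multisets is
size-constrained optimal bin matching: bins may be paired only with bins of
the same size, the total intersection over the $2! \times 2!$ admissible
pairings is maximised, and the result is expressed as a percentage of the
20 amino acids. This metric is 5%-quantised, symmetric, reaches 100 only for
identical partitions, and can reach 0 (equal-size bins of two partitions can
be pairwise disjoint) — properties an unconstrained optimal assignment would
not have, since two partitions of the same set always intersect somewhere.
The test suite validates it against brute-force enumeration over all
size-respecting pairings.

## What the tests do and do not establish

The simulations are across-site compositionally heterogeneous only; they
contain no across-lineage heterogeneity, no indels, no alignment error, and
their profiles come from a diffused Dirichlet rather than a fitted
posterior. Passing tests therefore establish that the pipeline's statistics
behave as designed and that, under these controlled conditions, recoding
improves adequacy and accuracy exactly when the inference model fails to
describe the amino-acid data — the directional claims. They do not
establish the published magnitudes (which came from 30,000-site,
97-taxon simulations and empirical superalignments), nor anything about
across-lineage effects, nor that six states is the optimal bin count
(schemes with other than six states are out of scope).

## Numerical choices collected

* Branch-length optimisation on the log scale; interval $[10^{-8}, 20]$.
* Coordinate-ascent convergence at $10^{-4}$ log units; EM steps guarded.
* Discrete Gamma uses category means with equal probabilities; simulation
  can use continuous Gamma behind a flag.
* Reversible generators are diagonalised through the symmetric similarity
  transform; transition probabilities are clipped at 0 and renormalised.
* Pruning scales per node when partials leave $[10^{-120}, 10^{120}]$.
* k-means mixture initialisation is seeded by the caller's RNG state; ties
  in the deterministic Fitch traceback resolve to the lowest state index;
  bootstrap score ties resolve uniformly at random.
* Missing data: `-`, `?`, `X` are missing; `B`, `Z`, `J`, `U`, `O` in
  amino-acid input are converted to missing with a warning; p-distances use
  pairwise deletion; sites are 1-based in all user-facing output.
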