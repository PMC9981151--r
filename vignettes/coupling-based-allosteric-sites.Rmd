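---
title: "Predicting allosteric sites and key allosteric residues from evolutionary couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting allosteric sites and key allosteric residues from evolutionary couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosite)
```

## The problem

Allosteric regulation — control of a protein's functional site by ligand
binding, mutation or modification at a distant site — is hard to reason
about structurally, because the two sites rarely touch. Within an
allosteric pocket, only some residues actually transmit the signal; the
rest merely contribute binding affinity. Telling the two apart matters for
allosteric drug optimization (keep the signalling contacts, vary the rest)
and for enzyme engineering (distal mutations that modulate catalysis).

`allosite` exploits a sequence-level signature of this coupling. Residues
that are functionally coupled coevolve: across a family alignment, a
substitution at one position is compensated at its partners. A global
pairwise (Potts) model fitted to the family separates such *direct*
couplings from transitive correlation. The package's premise is that the
*weak* direct couplings between a candidate pocket and the orthosteric
pocket — pairs that are not in structural contact — carry allosteric
information, and that both allosteric pockets and the key residues inside
them can be read off these couplings.

## The model

A sequence $a = (a_1,\dots,a_L)$ over $q$ states (20 amino acids plus gap)
is assigned probability

$$P(a) \;=\; \frac{1}{Z}\exp\Big(\sum_i h_i(a_i) \;+\; \sum_{i<j}
J_{ij}(a_i,a_j)\Big),$$

with single-site fields $h$ and pairwise couplings $J$. The partition
function $Z$ is never evaluated: `fitPlm()` maximizes the weighted
pseudo-likelihood, i.e. for every column $i$ the conditional likelihood
$P(a_i \mid a_{\setminus i})$, which replaces $Z$ by cheap per-site local
partition functions. This per-site (asymmetric) formulation yields two
independent estimates of every block $J_{ij}$, reconciled by averaging
$J_{ij} \leftarrow (\hat J_{ij}^{(i)} + \hat J_{ji}^{(j)\top})/2$.

Redundancy in the family is handled by the standard 80%-identity
reweighting (`computeWeights()`): each sequence is down-weighted by the
size of its neighbourhood at $\ge 80\%$ identity, and the sum of weights
is the effective depth $N_\mathrm{eff}$. The objective carries L2
penalties $\lambda_h\|h_i\|^2 + \lambda_J\|J_{i\cdot}\|^2$ against the
unnormalized (weight-summed) data term, with defaults $\lambda_h = 0.01$
and $\lambda_J = 0.01\,(L-1)$ — the usual pseudo-likelihood DCA scaling.
Optimization is L-BFGS-B from a zero start, so a fit is deterministic
without any seed; convergence is declared at a projected-gradient
tolerance of $10^{-5}$ or recorded per site as a warning after 500
iterations.

Coupling strength between columns is the Frobenius norm of the
gauge-fixed block,
$\mathrm{FN}(i,j) = \|J'_{ij}\|_2$, where $J'$ is the block in the
zero-sum gauge (row/column state means removed). The average product
correction then removes the shared background:
$\mathrm{EC}(i,j) = \mathrm{FN}(i,j) - m_i m_j / \bar m$ with $m_i$ the
off-diagonal row mean and $\bar m$ the off-diagonal grand mean.

### Pocket scoring

Candidate pockets (from an external detector, a residue-list file, or
ligand proximity) are compared to the orthosteric pocket — defined as all
residues within 6 Å of the orthosteric ligand. Candidates overlapping the
orthosteric pocket by more than 50% are excluded; smaller overlaps are
trimmed away. The evolutionary coupling strength of pocket $m$ is

$$\mathrm{ECS}_m = \sum_{i \in \mathrm{pocket}_m}\;
\sum_{j \in \mathrm{orthosteric}} \mathrm{FN}(i,j),$$

normalized over the candidate cohort to a Z-score; pockets with $z > 0.5$
are called allosteric. ECS deliberately uses the *raw* FN, while
key-residue identification below uses the APC-corrected EC — the
asymmetry is kept on purpose, as the background product that APC removes
is common to all candidate pockets of one protein but not to individual
residue profiles. A top-$k$-pairs variant (`topKPairs`) guards against
pocket-size effects, and `randomPatchControl()` compares the
allosteric-orthosteric ECS against size-matched random surface patches.

### Key residues

For the $N$ residues of the allosteric pocket and the $M$ residues of the
orthosteric pocket, the profile matrix $E_{ij} = \mathrm{EC}(a_i, b_j)$ is
built. Every unordered pair of rows is compared with a two-sided pooled
Student's t-test at $\alpha = 0.05$; $C_{mi} = 1$ records a significant
difference, $d_i = \sum_m C_{mi}$ counts them, and $z_i$ is the
population-SD Z-score of $d_i$. Residues with $z > 0.8$ are key
allosteric residues; in "outside" (enzyme) mode the rows are *all*
residues outside the orthosteric pocket and the stricter $z > 0.9$ cutoff
is used, reflecting the larger cohort. No multiple-testing correction is
applied across the $N(N-1)/2$ tests: $d$ is a descriptive count
statistic, not an inference, and correcting it would simply rescale the
cohort-relative Z-scores it feeds.

The t-test variant is genuinely open — the profile rows share the same
orthosteric-column support, so a paired design is defensible, and unequal
row variances would argue for Welch. The default is the unpaired
pooled-variance Student test as the most literal reading of "compare the
mean values of two rows"; `test = "paired"` and `test = "welch"` are
exposed, and exact Z-scores (not the ranking, in our experience on
synthetic families) can shift between variants.

## Synthetic families and what they do (not) show

Because the method is only meaningful on deep alignments, the package
ships a generator rather than fixtures. `plantedFamilySpec()` defines a
family with a planted architecture; `sampleFamily()` Gibbs-samples it and
`makeToyStructure()` lays the residues on an extended chain with "ORT"
and "ALO" ligands placed so that the 6 Å / 8 Å proximity rules recover
exactly the planted pockets.

Defaults (chosen once, as the package's study conditions): $L = 60$
columns, $q = 8$ states, $n = 2000$ sequences, an 8-column orthosteric
block, an 8-column allosteric block of which 3 are key columns, and three
8-column decoy pockets. Every orthosteric-allosteric column pair carries a
ferromagnetic diagonal coupling of magnitude $c = 0.2$ over the seven
non-gap states — zero-sum-gauge Frobenius norm $c\sqrt 6 \approx 0.49$,
i.e. the size of a strong contact coupling in real families — and pairs
involving a key column are boosted five-fold. Fields are small
($\sigma = 0.1$) and the gap state is suppressed, so synthetic families
are gap-free. The sampler burns in for 1000 sweeps and keeps every 10th
sweep. The reduced alphabet and the single-chain sampler keep a full
benchmark fit to tens of seconds; $q = 21$ behaves identically but
slower.

What the generator does *not* emulate: phylogenetic correlation between
sequences (samples are thinned draws from one chain, effectively i.i.d.),
gaps and alignment errors, spatial contact couplings along the chain, and
conservation gradients. Passing the planted benchmarks therefore
demonstrates correctness of the inference and scoring machinery — that
planted signal of realistic magnitude is recovered, ranked and called —
not field performance on real families, which depends on alignment depth
and quality in ways the DCA literature documents at length.

## Numerical choices and degenerate inputs

* Zero-sum gauge and the gap state: the gap row/column of each block is
  excluded from the Frobenius norm by default (`excludeGaps = FALSE`
  restores the strict all-state norm); gap-stretch artifacts otherwise
  dominate FN on real alignments.
* APC of an all-zero FN matrix is defined as zero (0/0 guard); a constant
  off-diagonal FN is annihilated exactly.
* Z-scores use the population SD throughout (pockets and residues); with
  a handful of candidates the sample SD would systematically deflate z.
  All-equal cohorts give all-zero z and no calls rather than NaN.
* Zero-variance profile rows: equal means compare as "no difference"
  (p = 1), unequal constant rows as "different" (p = 0).
* Ranking ties break deterministically: descending z, then ascending
  pocket name / residue number.
* Identity for reweighting counts all columns, gap-gap included
  (`nonGapOnly = TRUE` switches to shared non-gap columns only — the
  choice is not settled in the DCA literature).
* `fitPlm()` stores the full $L \times L \times q \times q$ coupling
  array (~0.3 GB at $L = 300$, $q = 21$); fits on long proteins need
  memory accordingly.

## Problem sizes used in the tests

The shipped suite runs entirely on synthetic data: gradient checks on
$L \le 8$, $q \le 4$ instances against central finite differences;
exact-enumeration checks of the sampler on a two-column system;
planted-pair recovery on $L = 6$, $q = 3$, $n = 1000$ families over ten
seeds; the full benchmark (default spec above) over five seeds; and a
subsampling analysis at a depth of $7L$ sequences — the depth around
which key-residue calls stabilize, consistent with the package's own
robustness table (`subsampleRobustness()`).

## A worked example

```{r example, eval = FALSE}
spec <- plantedFamilySpec()
fam  <- sampleFamily(spec, seed = 1)
s    <- makeToyStructure(spec, querySequence(fam$aln))

res <- runPredictSites(fam$aln, s,
                       candidatePockets = c(list(
                         pocketFromLigand(s, "ALO", 8, name = "allosteric",
                                          role = "allosteric_known")),
                         decoyPockets(spec)),
                       orthoLigand = "ORT")
res$table

kr <- runKeyResidues(fam$aln, s, mode = "pocket", orthoLigand = "ORT",
                     alloLigand = "ALO", model = res$model)
subset(kr$table, isKey)
```

## Limitations

The method needs hundreds of effective sequences; below that, couplings
are regularization-dominated and the package warns rather than refuses.
Pocket definitions are consumed, not computed — results inherit whatever
residue composition the upstream pocket detector produced, and the
key-residue list is known to shift slightly between apo and holo pocket
definitions of the same site. Exact reproduction of any published
Z-scores further depends on unpublished choices (regularization strength,
t-test variant) that are exposed as options here.
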