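---
title: "Syllable-sequence networks: models, null models and design choices"
author: "songnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syllable-sequence networks: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songnet)
```

# The problem

Many songbirds order the discrete elements of their song — syllables —
nonrandomly, and individuals may differ consistently in how they do so.
`songnet` characterises this *sequential organisation* for species such as
the collared flycatcher, whose 3–5 s songs are free sequences of syllables
drawn from a moderately large repertoire rather than fixed song types. The
pipeline starts downstream of audio analysis: its input is a table of
labelled syllable tokens (type id plus duration, min/max/mean frequency and
bandwidth), grouped into songs and recordings.

# The network model

Each recording is turned into a directed network. For every song we count
first-order transitions — type A immediately followed by type B — and sum
the per-song adjacency matrices into one matrix for the recording. A→B and
B→A are distinct cells, so the matrix is asymmetric; transitions are never
counted across song boundaries. Thresholding the summed matrix at weight
&gt; 0 gives the unweighted directed graph on which six descriptors are
computed:

1. **repertoire size** — distinct syllable types (nodes);
2. **number of syllables** — tokens (the sample size of the matrix);
3. **average degree** — mean total degree, \(2E/n\) over distinct directed
   edges;
4. **average shortest path** — mean directed distance over *reachable*
   ordered pairs;
5. **clustering coefficient** — global transitivity
   \(3\,\triangle/\#\text{triples}\) of the undirected projection;
6. **small-worldness** — \(S=(C/C_{rand})/(L/L_{rand})\) on the undirected
   projection, with Erdős–Rényi baselines.

## Numerical conventions

Several conventions are deliberately explicit because syllable networks are
small, sparse and frequently disconnected:

* **Self-loops** (immediate repetition of a type) are always counted in the
  weight matrix but excluded from the derived graph by default
  (`includeSelfLoops = FALSE`); this matches the usual convention of graph
  toolkits, and the flag reverses it.
* **Disconnected graphs.** The average shortest path is taken over
  reachable ordered pairs only, so networks with isolated chains still get
  finite values; a graph with no reachable pair yields `NA`.
* **Degenerate clustering.** When no connected triple exists, transitivity
  is defined as 0 rather than `NaN`.
* **Small-worldness baselines.** The default is the analytic ER baseline
  \(C_{rand}=\bar k/n\), \(L_{rand}=\ln n/\ln\bar k\), which is undefined
  for \(\bar k \le 1\); such networks are flagged `NA` and excluded
  downstream. A Monte-Carlo mode (`mode = "montecarlo"`) instead averages
  \(C\) and \(L\) over simulated \(G(n,m)\) graphs; on ER-like graphs the
  two agree within about 15%, and the analytic mode is the default because
  it is deterministic and fast.
* **Directed vs undirected.** Path length stays directed (it reflects song
  order); clustering and small-worldness use the undirected projection,
  where triangles are meaningful.

# Null model and effect sizes

Whether observed structure exceeds chance is judged against a
*bout-preserving permutation null*: syllable order is shuffled independently
within each song, conserving song count, song lengths and each song's type
multiset. For each recording the departure of a descriptor from 100
shuffled replicates is summarised as Cohen's
\(d=(x_{obs}-\bar x_{null})/s_{null}\), with sampling variance
\(\mathrm{var}(d)=\bigl(1+d^2/2n\bigr)\,(n{+}1)/n\) for the
one-observation-versus-\(n\) contrast. Per-recording effects are pooled
with a DerSimonian–Laird random-effects meta-analysis (inverse-variance
weights \(1/(var_d+\tau^2)\), 95% CI \(\pm1.96\,se\)); random effects were
chosen over a fixed-effect model because recordings differ in repertoire
and length, and heterogeneity is expected. Recordings whose null SD is zero
have undefined d and are excluded from pooling with a warning.

The spectral counterpart compares the series of absolute mean-frequency
differences between consecutive syllables against the series from a
*single* shuffled copy (the many within-recording pairs make one
randomization sufficient), as a two-sample pooled-SD Cohen's d with the
standard variance \((n_1{+}n_2)/(n_1n_2)+d^2/2(n_1{+}n_2)\).

# Motif types

A motif type of length \(L\in[2,10]\) is an exact contiguous type
subsequence occurring in **at least two distinct songs** of a recording;
within-song repetition alone does not qualify (the permissive alternative
is available as `rule = "any_repeat"` because the original criterion could
be read either way). Counts are of distinct types, not occurrences.
Original and singly-shuffled recordings are compared per length with the
paired Wilcoxon signed-rank test (normal approximation; counts tie
heavily), with lengths at which all paired differences vanish reported as
undefined rather than tested.

# Size correction, correlations, repeatability

Network descriptors covary strongly with repertoire size and syllable
number, so analyses of individual differences use residuals from an OLS
regression of each descriptor on those two covariates. Small-worldness is
log-transformed first (its distribution is strongly right-skewed); zeros
are lifted by half the smallest positive value before the log.
Pairwise Pearson correlations among the six variables use a Bonferroni
multiplier equal to the number of pairs (15 for six variables).

Repeatability at a time scale (within day, between days, between years)
uses a balanced two-recordings-per-individual design and a random-intercept
LMM (REML) with age as a fixed covariate, giving the adjusted
\(R=V_{between}/(V_{between}+V_{within})\). A singular fit (between
variance 0) is recorded as \(R=0\), not an error. Confidence intervals are
a *fully parametric* bootstrap: responses are re-simulated from the fitted
Gaussian components (both random effects and residuals redrawn), the model
refitted and the percentile 2.5/97.5 bounds of \(R\) taken; 1000 iterations
by default. Percentile intervals were chosen (basic intervals are exposed
via `ciType`) because \(R\) is bounded in \([0,1]\) and percentile bounds
respect the range. \(R\) is called significantly above zero when the lower
bound exceeds \(10^{-6}\).

# Quality and fitness models

Quality models are Gaussian LMs of a (size-corrected) descriptor on body
condition, age and median-centred arrival date, with year as a discrete
fixed effect; every term is tested by likelihood ratio against the model
without it, and Bonferroni correction uses the number of descriptors
analysed (2 by default: by design only descriptors with significant
repeatability at some scale are eligible responses, overridable). Fitness
models are binomial GLMs (logit) of pairing success or next-year recapture
on both network descriptors plus the same covariates and year; the reported
pseudo-\(R^2\) is McFadden's \(1-D/D_0\) (the original analysis does not
state which flavour it used). Complete separation is flagged and left
unfitted rather than penalised. The within-individual age comparison is a
paired t test on the change across years; because a reported reference
point (t = −2.0, df = 12, P = 0.03) matches the one-sided tail
(\(P_{1}\approx0.034\)) but not the two-sided one (\(\approx0.069\)), the
default remains two-sided and `tail = "less"` reproduces the one-sided
reading.

The body-condition input is accepted as a precomputed score; the optional
helper `bodyConditionIndex()` computes a simple size-corrected mass
(weight-on-tarsus OLS residuals), since no specific formula is prescribed
for the input data.

# The synthetic generator

No field corpus ships with the package; `simulatePopulation()` generates
one with known ground truth. Its defaults encode the study conditions the
analysis expects:

* 176 individuals, 20 songs per recording;
* repertoire size truncated-normal (mean 47, SD 19.8, range 12–105);
* base song length Normal(7, 2.5) clipped at 2; with motif splices this
  yields roughly 100–350 syllables per recording (target envelope 99–374);
* per-individual *grammar*: a backbone cycle through the repertoire plus
  Poisson(\(\lambda=0.75\)) extra out-edges per type, giving mean total
  degree near 3.5; transition probabilities reweighted
  \(\propto\exp(\beta\,|\Delta f|/1000)\) with \(\beta=0.5\), which
  produces a modest positive frequency-alternation effect of the same
  order as observed in the field;
* a library of 3 fixed motifs of length 5–8, spliced into a song with
  probability 0.5 — enough for nearly every recording to share a length-5
  motif across songs while shuffled copies essentially never do;
* age: shifted geometric with mean ≈ 1.9 (truncated at 7); ageing thins
  the grammar (\(\lambda\) decreases by 0.1 per year), so average degree
  declines with age as observed;
* within-individual drift \(\varepsilon\) per time scale (0.05 within day,
  0.15 between days, 0.4 between years): each type's branches are redrawn
  with probability \(\varepsilon\) between the two recordings, producing
  the observed decay of repeatability with time scale;
* fitness proxies are Bernoulli draws from logistic models on age, arrival
  and condition; network descriptors have **no** direct fitness effect
  under the default ground truth, matching the null result they are tested
  against.

What the generator does *not* emulate: acoustic waveforms, higher-order
(non-Markovian) grammar beyond the spliced motifs, social context effects,
and observation-level measurement error beyond small jitter. Tests passing
on this corpus therefore validate the statistical machinery and the
qualitative signatures (direction of null-model departures, motif
contrast, repeatability decay, age effect), not any quantitative claim
about real flycatchers.

# Problem sizes used in the shipped checks

The package's own verification uses deliberately modest sizes chosen to
exercise every code path at desk scale: oracle equivalence on hundreds of
random graphs of ≤ 15 nodes and song sets of ≤ 20 songs; direction and
motif contrasts on a 50-individual population with 100 shuffles per
recording; repeatability recovery on 200 individuals × 2 recordings with
200 bootstrap iterations; and model calibration on 1000 simulated trait
tables of n = 176. The end-to-end pipeline demo runs on 10 individuals.

# Known limitations

* The repeatability design is strictly balanced (two records per
  individual); unbalanced multi-record designs are out of scope.
* The analytic small-worldness baseline degrades for very sparse graphs
  (\(\bar k\) near 1); such networks are excluded as undefined rather than
  extrapolated.
* The motif search is exact-match only; no gap or substitution tolerance.
* Effect-size variance formulas for the 1-vs-null contrast follow the
  standard small-sample two-group form with \(n_1=1\); other conventions
  exist and would rescale meta-analytic weights slightly.

# A minimal session

```{r example}
rec <- recordingFromSequences("demo", list(c("A","B","C"), c("A","B","D")))
net <- buildNetwork(rec)
weightMatrix(net)
computeMetrics(rec)
findMotifs(rec, 2, 3)
```
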