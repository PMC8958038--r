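---
title: "Scoring drug–disease association on functional networks: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-disease association on functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

proxtalk scores the association between a drug (its protein target set
*T*) and a disease (its associated gene set *S*) on an undirected
functional association network, and evaluates such scores as drug
repurposing classifiers. This vignette is the package's account of the
models it implements, the nulls they are normalized against, the tunable
parameters, and the choices made where the design was genuinely open.

## The setting and its central confound

Functional association networks are heavy-tailed: a few hub genes carry
hundreds of links. Any naive association statistic — the shortest path
from targets to disease genes, or the raw count of edges between the two
sets ("crosstalk") — is therefore dominated by degree: a drug that happens
to target a hub is close to, and shares edges with, *every* gene set. All
four scorers exist to cancel this confound, each with a different null
model, and each reports a z-score

$$ z = \frac{\text{raw} - \mu_{\text{null}}}{\sigma_{\text{null}}} $$

plus a one-sided standard-normal tail probability in the direction of
association (lower tail for the distance-like proximity score, upper tail
for crosstalk). `oriented_score()` maps every method onto a common
higher-is-stronger scale so that one evaluation code path serves all four.

## The four scorers

### Proximity (`proximity_score`)

Raw statistic: the average over targets of the hop distance to the nearest
disease gene,
$d(T,S) = \frac{1}{\lVert T\rVert}\sum_{t\in T}\min_{s\in S} d(t,s)$.
Edges are used unweighted: any confidence value is consumed only by the
loading threshold (default 0.8) and retained for reporting, never as a
path length.

Null: nodes are binned by degree (`build_degree_bins()`, 100 nodes per
bin, nodes sorted by degree with lexicographic tie-breaking; a trailing
bin smaller than half the bin size is merged into its neighbor so that
degree matching never draws from a degenerate bin). Both the target-like
and the disease-like set are resampled 1000 times with the per-bin
composition of the observed sets, and $d$ is recomputed for each replicate
pair. The mean and standard deviation of the 1000 replicate distances give
$\mu_R, \sigma_R$. Both an analytic lower-tail normal p-value and an
empirical permutation p-value $(\#\{d_{\text{null}} \le d_{\text{obs}}\} +
1)/(n_{\text{perm}} + 1)$ are reported, since the normal approximation is
a convenience, not part of the model.

Targets that cannot reach any disease gene are dropped from the average
with a warning; a pair in which *no* target reaches any disease gene has
no defined distance and raises a typed error (in `score_all_pairs()` such
pairs become `NA` rows with a `status` reason code instead of aborting the
run).

### NEAT-style hypergeometric crosstalk (`neat_score`)

Raw statistic: the crosstalk $x$, the number of distinct network edges
with one endpoint in each set. Null: link endpoints are modeled as a
hypergeometric draw — of the $N = 2|E|$ edge endpoints in the network, the
disease set owns $n = \sum_{s \in S}\deg(s)$ and the target set
$K = \sum_{t \in T}\deg(t)$, giving

$$ \mu_H = \frac{nK}{N}, \qquad
   \sigma_H = \sqrt{\mu_H\,\frac{N-K}{N}\,\frac{N-n}{N-1}}. $$

A note on parameterization: these are the classical hypergeometric mean
and standard deviation (exposed as `crosstalk_hypergeom_moments(N, K, n)`
at the formula level), and the package deliberately feeds them *degree
totals*, not node counts. With node counts the null mean would contain no
edge information at all and would understate the expected crosstalk by
roughly the network's mean degree, inflating every z-score on any real
network; with endpoint totals the model is the configuration-model
expectation and is empirically well calibrated (see the calibration
section). This is the only scorer with no randomness: rescoring a pair is
bitwise reproducible with no seed.

### BinoX-style binomial crosstalk (`binox_score`)

Null: crosstalk is modeled as $\mathrm{Bin}(n_x, p_x)$ where
$n_x$ (`max_crosstalk()`) is the number of node pairs that could carry a
crosstalk edge, $|T|\cdot|S| - o - o(o-1)/2$ with $o = |T \cap S|$ (pairs
inside the intersection counted once, self-pairs never — the same
convention `crosstalk_count()` uses, so $x \le n_x$ always). The per-pair
probability $p_x$ is estimated by randomizing the network $M$ times with
degree-preserving double-edge swaps (`shuffle_preserving_degree()`,
$\lceil 10 \times |E|\rceil$ attempted swaps by default — the standard
burn-in for approximate uniformity over degree-fixed simple graphs) and
averaging $x_i / n_x$ over the replicates. $M$ defaults to 100,
a compromise between the stability of $p_x$ and desk-scale runtime; the
ensemble can be generated once (`randomize_networks()`) and shared across
all pairs of a run, which is both faster and statistically paired.
$p_x \in \{0, 1\}$ leaves the binomial degenerate and raises a typed error
suggesting a larger $M$.

### ANUBIX-style beta-binomial crosstalk (`anubix_score`)

Crosstalk across degree-matched random sets is over-dispersed relative to
a binomial — clustering makes some placements much richer than others — so
this scorer fits $\mathrm{BetaBin}(n_x, \alpha, \beta)$ instead: 100
target-like sets are drawn degree-matched (the disease set stays fixed,
exactly as in the proximity null's sampling machinery), their crosstalk
with $S$ is computed, and $(\alpha, \beta)$ are estimated by maximizing
the beta-binomial likelihood (`fit_betabinomial()`, Nelder–Mead on
log-parameters, initialized at the method-of-moments estimate; the
optimizer result is never accepted if it is worse than its start). The
fitted distribution's mean and sd normalize the observed crosstalk.

When the sampled crosstalk shows *no* over-dispersion — common for drugs
with one or two targets, where counts are nearly Bernoulli — the
likelihood has no interior optimum in the concentration and the fit falls
back to $\alpha + \beta = 10^6$ at the sample-mean proportion, i.e.
an effectively binomial null, with a logged notice. Sampled counts are
capped at $n_x$ (a degree-matched sample can overlap $S$ less than the
observed targets do, making its own maximum slightly larger).

## Drug–drug similarity

For a disease with approved drugs, a candidate can instead be scored by
its network similarity to each approved drug's target set (target sets
play both set roles): the method's z is computed per reference and the
vector collapsed to $e^{-\min z}$ for proximity or $\max z$ for the
crosstalk methods. Leave-one-out self-exclusion is on by default — a
candidate identical to an approved drug would otherwise match itself
perfectly and inflate any benchmark — and exposed as a flag.

## Benchmarks

`build_benchmark()` applies, in order: restriction of all sets to network
members; exclusion of drugs with no in-network target and diseases with
fewer than 20 in-network genes (the threshold under which degree-matched
nulls and the disease-module assumption both become unreliable);
label assignment over the full drug × disease grid with unlisted pairs
defaulting to `unknown` (approved/off-label → positive,
clinical-trial/contraindicated → excluded, unknown → negative); and
exclusion of negatives whose targets overlap the disease genes — such
pairs are disproportionately unverified positives, and keeping them as
negatives penalizes exactly the methods that work. Positives are never
overlap-filtered, so the positive count is invariant to that filter.
Every stage's counts land in a provenance record, and
`excluded + positive + negative` always equals the grid size. A
sensitivity flag adds the removed labels back as positives;
an optional dedup collapses drugs with identical targets and identical
indications. `apply_time_stamp()` relabels later-approved pairs from
negative to positive (flagging them `new_positive`, with their source
label updated to approved), enabling prospective recall evaluation.

## Evaluation

Oriented scores are evaluated with: AUROC (exact Mann–Whitney form,
ties counted half); step-wise AUPR (interpolation-free — interpolated
variants are not comparable across implementations); the threshold at the
sensitivity–specificity intersection (grid of midpoints between distinct
scores, ties broken toward higher sensitivity); recall at that threshold
(equal to sensitivity by definition); MCC and F1 at the threshold
(reported, never used for selection); and the balanced-resample AUROC —
100 subsets keeping all positives with equally many negatives drawn
without replacement, the standard answer to the extreme class imbalance of
repurposing benchmarks. The negative draws depend only on the seed and the
label vector, so two methods evaluated on identically ordered tables with
the same seed have *paired* resamples; `compare_methods()` defaults to the
Wilcoxon signed-rank test on those pairs, with the rank-sum variant
available for unpaired designs. All p-values are Benjamini–Hochberg
corrected (`bh_correct()`). For nominating novel predictions,
`prediction_cutoff()` uses the descriptive rule mean + 2 population sds of
the oriented z-scores, and `prediction_sets()` partitions above-cutoff
pairs of two methods into agreed and method-unique sets.

## The synthetic study

`generate_benchmark()` produces the fixture everything is tested on:

* **Network** — preferential attachment (2000 nodes, 3 edges per new
  node), chosen over homogeneous random graphs precisely because
  heavy-tailed degrees are what the degree-aware nulls exist to handle.
* **Diseases** — 5 connected sets of 20–60 genes grown by neighborhood
  expansion: disease genes on functional networks are modular, and a
  scattered gene set would make the proximity signal unrealistically weak.
* **Drugs** — 30 drugs, 1–5 uniformly sampled targets each (real drugs
  have few targets; a median of about three is typical of curated
  drug–target sets).
* **Signal** — half the drugs are positive for one disease each. Each
  edge of each positive target is rewired onto a uniformly chosen disease
  gene with probability 0.5; rewiring (rather than edge addition) keeps
  the target's degree, so planted positives do not confound the
  degree-based nulls they are meant to be detected by. Positives
  additionally have one target replaced by a disease gene with probability
  0.3 (negatives: 0.02), reproducing the class-conditional target–gene
  overlap enrichment seen in curated benchmarks.

Problem sizes used by the tests and the acceptance script: the
planted-signal study uses the default 30 drugs × 5 diseases (150 pairs);
the zero-signal control — no rewiring *and* equal overlap probabilities —
is run at 100 drugs so its null AUROC is estimated with a standard error
of about 0.04 rather than 0.08; the null-calibration study scores 200
degree-matched random target sets of drug-like sizes (1–5) against one
fixed 40-gene disease module on a fresh 2000-node network.

## Numerical and degenerate-input choices

* Degenerate nulls ($\sigma = 0$, $p_x \in \{0,1\}$, no reachable disease
  gene) raise typed errors at the single-pair level; the all-pairs driver
  converts them to `NA` rows with reason codes.
* Proximity distances are read off a dense all-pairs hop-distance matrix
  (`node_distances()`), the fastest representation up to a few thousand
  nodes; very large networks would need a sparser strategy and are outside
  the intended scale.
* The prediction cutoff uses the population (divide-by-*n*) standard
  deviation: it is a descriptive summary of the score distribution, not an
  inference, and the choice is fixed so results reproduce exactly.
* All stochastic entry points require an explicit integer seed and derive
  any internal streams from it; nothing reads global RNG state implicitly.

## Calibration results, and what they do and do not show

With all defaults, scoring degree-matched random target sets against a
fixed disease module leaves each method's z distribution close to
standard: mean z within a few hundredths of zero and roughly nominal 5%
tails for all four methods at the documented seeds (the acceptance script
recomputes this for any seed). Two caveats the numbers themselves reveal:

* The proximity null resamples disease-like sets degree-matched but
  *scattered*, while a real disease module is clustered; a scattered
  40-node set covers the graph better and sits slightly closer to
  everything. The proximity z therefore carries a small
  module-compactness-dependent offset (positive mean z for compact
  modules) that varies with the planted module — visible when the
  calibration is rerun across generator seeds. Ranking across pairs, which
  is what the benchmarks measure, is unaffected; absolute proximity
  p-values for a single pair should be read with this in mind.
* The binomial (BinoX-style) null inherits whatever clustering the edge
  shuffle destroys; its slightly heavier-than-nominal tails on clustered
  graphs are the over-dispersion the beta-binomial scorer exists to absorb.

## Known limitations

* The generator plants *drug–disease* signal only. Drugs approved for the
  same disease get independently sampled targets: they share no targets
  and no direct edges, which real co-indicated drugs often do. Drug–drug
  similarity scoring therefore sees only second-order planted signal
  (through overlap-planted targets that are themselves disease genes), and
  on this fixture it does **not** match direct association performance —
  most visibly for the crosstalk methods. A passing planted-signal test
  says nothing about the relative merit of similarity-based repurposing on
  real data, where shared mechanism between co-indicated drugs is the
  dominant effect.
* Identifier matching is exact-string throughout; ontology mapping between
  drug/disease vocabularies is out of scope.
* Edges are unweighted after thresholding; weighted shortest paths and
  directed interactions are not modeled.
* The beta-binomial fallback makes one-target drugs effectively
  binomial-normalized; their ANUBIX and BinoX z-scores are then nearly
  redundant.
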