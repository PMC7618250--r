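---
title: "Foraging social networks under a density manipulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foraging social networks under a density manipulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

## The experiment this pipeline analyses

Wintering songbirds such as great tits forage in fission–fusion flocks at
feeders. Selective RFID feeders record every PIT-tagged bird that lands on
the perch and can open their flap only for programmed tags, which makes it
possible to manipulate *local population density*: at each experimental
site with two feeders, a randomly chosen 20% of the site's established
birds (those recorded at least 100 times before the manipulation) are
granted access only at one feeder (the low-density feeder) and excluded
from the other (the high-density feeder), which every other tagged bird
can use. Visits are recorded even when access is denied. The pipeline
quantifies what this does to local density, to the foraging social
network, and to the discovery of novel food patches.

`flocknet` implements every stage: a seeded colony simulator, flocking-event
detection from raw antenna reads, simple-ratio-index (SRI) networks and
their metrics, assortment by treatment with permutation nulls,
node-permutation inference for period-by-treatment contrasts, and
patch-discovery scoring.

## Flocking-event detection

Reads at one feeder arrive in bursts. `segment_reads()` first cuts the
stream wherever consecutive reads are more than `tau` seconds apart
(default 600 s). Within each segment, `fit_event_mixture()` fits univariate
Gaussian mixtures to the read times for K = 1..`K_max` components by EM
and picks K by minimum BIC; reads are labelled by maximum posterior
responsibility and label runs are forced to be contiguous in time, giving
non-overlapping events.

Numerical choices, all made for determinism and testability:

* **Initialisation.** Component means start at the `(k - 1/2)/K` quantiles
  of the segment's read times. A randomised k-means++-style seeding would
  break the requirement that identical inputs give identical events, so a
  deterministic quantile seeding is used instead.
* **Variance floor** of 1 s² prevents singular components when timestamps
  repeat at second resolution.
* **Convergence**: at most 500 EM iterations, absolute log-likelihood
  tolerance 1e-6.
* **Model selection**: BIC with `3K - 1` free parameters; the search stops
  after the criterion worsens on two consecutive K, which on feeder data
  (few, well-separated bursts per segment) never changes the selected K
  but bounds runtime.
* **Ties** in responsibility go to the component with the earlier mean.
* A one-read segment is a single event; a segment's single-component fit
  labels everything 1.

BIC is a transparent, testable surrogate for the Bayesian nonparametric
clustering used by some field software; equivalence is structural, not
numeric. A fixed tumbling-window detector (`method = "window"`, default
300 s windows) is provided as a fallback and as a fast detector for large
simulation studies; on well-separated data the SRI networks from the two
detectors agree with correlation above 0.9 (tested).

## Association networks and metrics

An association is co-membership in a flocking event. From the binary
group-by-individual matrix, `sri_network()` computes for each pair the
simple ratio index

$$ w_{ab} = \frac{T_{ab}}{D_{ab}}, $$

with \(T_{ab}\) the number of events containing both birds and
\(D_{ab}\) the number containing either; 0 means never in the same flock,
1 means always together. Pairs never observed (\(D = 0\)) carry weight 0
and are flagged unobserved.

Global metrics per network (`global_metrics()`): unweighted network
density (realised over possible dyads), average nonzero edge weight, and
the unweighted global clustering coefficient
\(3 \times \text{triangles} / \text{connected triples}\) (computed with
igraph). Daily per-feeder networks in which fewer than three individuals
have any association are dropped and logged, mirroring the field
analysis.

Node metrics (`node_metrics()`):

* weighted degree (strength) \(s_i = \sum_j w_{ij}\);
* average association strength \(s_i / k_i\) with \(k_i\) the number of
  nonzero edges (so strength = degree × average association strength,
  an identity the tests check);
* the Barrat weighted clustering coefficient
  \(C_i = \frac{1}{s_i (k_i - 1)} \sum_{j,h} \frac{w_{ij} + w_{ih}}{2}
  a_{ij} a_{ih} a_{jh}\) — the source analysis names the metric but not a
  formula, and Barrat's form is the bounded, standard choice (checked
  against igraph's implementation);
* weighted eigenvector centrality by power iteration (tolerance 1e-10),
  computed on each connected component separately with each component
  scaled to maximum 1; isolated nodes get 0. Per-component scaling avoids
  the dominant component silently zeroing every other component, at the
  price that each component has its own reference bird with score 1.
  On connected networks the result matches igraph's global computation.
* mean flock size over the events the bird attended.

## Assortment by treatment

`assortativity_discrete()` implements Newman's weighted assortativity for
a discrete label: with \(e_{kl}\) the fraction of total edge weight
joining label k to label l (both edge ends counted) and marginals
\(a_k = \sum_l e_{kl}\),

$$ r = \frac{\sum_k e_{kk} - \sum_k a_k^2}{1 - \sum_k a_k^2}. $$

r is 1 when all edge weight lies within types, −1 for a balanced
all-between network; an all-one-type network makes the denominator 0 and
is reported as undefined rather than silently NaN. The standard error is
Newman's edge jackknife, \(\mathrm{se} = \sqrt{\sum_e (r_{-e} - r)^2}\),
removing one nonzero edge at a time.

`assortment_null()` shuffles the labels over the nodes (network fixed,
default 1000 permutations) and reports the 2.5/97.5% null quantiles and a
two-tailed p-value with the +1 correction. One property deserves
emphasis: the permutation expectation of r is **not exactly zero** but
\(-1/(n-1) + O(1/n^2)\) — on a complete graph with balanced labels every
labelling gives exactly \(-1/(n-1)\). At the 20–40 bird scale of these
networks the null mean therefore sits near −0.03 to −0.05. This is an
intrinsic finite-size property of the coefficient (the analogue of
Moran's I having expectation \(-1/(n-1)\)), not an implementation bias;
tests assert centring up to this offset. Daily assortment skips days with
fewer than two individuals of either treatment, and birds without a
treatment label are dropped with a logged count.

## Design rules and density measures

`assign_feeder_roles()`: at a uniformly random half of experimental sites
the feeder holding the pre-period majority of visits becomes high-density,
at the other half low-density; ties break by feeder identifier and are
logged. `assign_bird_treatments()`: birds with at least `min_records`
(default 100) pre-period reads are eligible; `round(0.2 × eligible)`
(at least one) are sampled into the low treatment; everyone else keeps
high-feeder access. "Recordings" means raw antenna reads, denied visits
included, and a site-day is excluded when exactly one feeder recorded
nothing (`filter_failed_days()`), the zero-read proxy for equipment
failure.

Individual-level inclusion requires at least `min_records` reads in *both*
periods at a site; birds seen at several sites are scored per site. The
proportion of visits to the assigned feeder is computed on access-granted
reads, so that under full compliance it is exactly 1 — denied attempts at
the unassigned feeder measure non-compliance, not use of a resource.

## Inference

`fit_period_treatment_model()` fits
`response ~ period * treatment (+ day)` with random intercepts (glmmTMB)
or site fixed effects (glm), and extracts (period, treatment) cell means
and Tukey-adjusted pairwise contrasts via emmeans. The response
transformations used in the source analysis (inverse for average edge
weight, square for clustering, square root for latency, log for arrival
order) are applied before fitting and recorded with the result. AR1
residual structures and beta error families are deliberately out of scope:
significance for network metrics comes from the permutation scheme below,
not from the parametric machinery.

`node_permutation_test()` shuffles node identities within each
site-period network, keeping the network — and therefore the multiset of
metric values per site-period — fixed, reattaches the metrics to the
shuffled identities, refits, and stores every pairwise cell contrast.
Observed contrasts falling outside the central 95% of their null are
significant at the 5% level; p-values use the +1 correction. The refit is
a reduced fixed-effects linear model (no-intercept cell factor plus
additive site terms), so each permutation costs a single least-squares
solve against a fixed design; with the design matrix fixed, shuffling
identities is exactly a stratified permutation of the response. The null
of a 6-bird network matches exhaustive enumeration of all relabellings
(tested). Permutations never cross sites, matching the per-site design.

Two subtleties matter for calibration, both verified by simulation:
treatment is randomised *within the eligible set*, so exchangeability —
and hence a nominal type-I error — holds only on the filtered analysis
set (birds with enough reads in both periods), which is exactly the set
the individual-level analysis uses; and a planted null requires the
simulator's high-bird stray visits to be switched off along with
compliance, otherwise a genuine (if tiny) behavioural difference between
treatments exists.

## Patch discovery

A trial deploys novel feeders for one day, starting at the first second of
the recording window. Eligible birds are those recorded at the site's
selective feeders on the trial day with at least 100 reads over the
manipulation period. A bird discovers if it has any read at either novel
feeder; latency is time from trial start to first arrival, and arrival
order groups birds arriving within 10 minutes of each other
(`order_with_ties()`). Tie groups anchor at the group's *first* arrival —
the chain rule (anchor at the previous arrival) can merge unbounded spans
and is deliberately not used; the choice is documented and switchable via
`tie_window`. Discovery probability, log order and square-root latency are
modelled with `discovery_models()`.

## The synthetic colony

`simulate_colony()` generates the whole study: a pre period with free
access, role and treatment assignment by the design rules above, then the
manipulated period. What it emulates, and the defaults chosen as a
realistic winter-feeder scenario:

* **Bursty fission–fusion visits**: flocking events arrive per feeder as
  a Poisson process (`flock_rate`, 3/feeder-hour) inside the 07:00–17:00
  recording window; members emit `1 + Poisson(2)` reads jittered
  `Normal(0, 45 s)` around the event centre (clipped at 3 sigma).
* **Sociality**: a fraction (`pair_fraction` 0.4) of birds form bonded
  pairs — wintering great tits keep foraging with past and future breeding
  partners — whose preference weights lie strictly above the non-bonded
  baseline; recruitment into an event is logistic in
  `preference_scale × w_ij`, normalised so the expected flock size is
  about `flock_size_mean` (5) when the whole site population is
  available. Because the normalisation is over the *site* population,
  fewer available birds mean smaller flocks — the availability scaling
  that reproduces the observed smaller flocks, sparser and less clustered
  networks at the low-density feeder.
* **Partial compliance**: a low-assigned bird follows its assignment with
  probability `compliance` per event, and otherwise visits the
  high-density feeder, where it is recorded but denied (`access = 0`).
  The field observation is only that restricted birds still spent "an
  appreciable" time at the other feeder; the default 0.6 is a simulator
  convenience, not an estimate. High birds stray to the low feeder with
  probability `stray_prob` (0.05), likewise denied.
* **Outages**: with probability `failure_rate` per site-day one feeder
  records nothing, feeding the day-exclusion filter.
* **Discovery**: `simulate_discovery_trial()` is a network-based-diffusion
  generator — in one-minute steps a naive bird arrives with hazard
  \(\lambda_0 (1 + s z_i)\), \(z_i\) the summed SRI weight to informed
  birds; `social_effect = 0` switches transmission off. The baseline
  \(\lambda_0 = 0.0027\)/min makes a lone bird discover within a 10-hour
  day with probability ≈ 0.8, matching the observed 119/148 discovery
  rate.

Randomness is split per (site, day, feeder) from the master seed, so any
subset of days regenerates identically; identical configuration and seed
give byte-identical output.

What the simulator does **not** emulate: spatial movement and the 40 m
feeder geometry, mixed-species flocks, weather- or predation-driven
activity changes, diurnal activity peaks, and individual personality
differences in discovery. Passing tests therefore show that the pipeline
recovers structure *of the kind the analysis assumes*; they cannot show
that field data meet those assumptions.

## Problem sizes and runtime choices

The package-level studies run at deliberately reduced scale so the whole
suite stays interactive: recovery and calibration studies use 1–2 sites,
14–30 birds per site, 2–3 pre and 3–6 experimental days, a
proportionally reduced eligibility threshold (the full design's 100 reads
corresponds to about two weeks of pre-period data), 200 permutations per
test and 50–200 replicates, and the window detector where hundreds of
replicates are needed. The acceptance script (`scripts/acceptance.R`)
reports the analytic assortativity extremes (two 10-node cliques; a
balanced complete bipartite 10+10 network), the mean assortativity of a
40-node simulator network under 1000 uniformly random labelings, and the
SRI of a pair that always forages together.

## Known limitations

* The GMM detector over-splits dense streams when bursts overlap within a
  segment (clipped read jitter makes tails lighter than Gaussian); the
  criterion that matters downstream — SRI agreement between detectors —
  is robust to this.
* Published standard errors for assortativity may come from a different
  estimator than the edge jackknife; numeric agreement is not guaranteed.
* The permutation refit is a reduced fixed-effects model, not the full
  AR1/random-effects GLMM; this mirrors the permutation logic, not the
  parametric model, and is the package's claim to significance.
* Network density of a daily network counts all birds present in that
  day's events as nodes; counting only connected birds is a documented
  alternative the field wording leaves open.
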