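# flocknet

Foraging social networks from RFID feeder visit streams, for field
ecologists running density-manipulation experiments with selective
("programmable-flap") feeders on PIT-tagged birds.

Wintering passerines such as great tits forage in fission–fusion flocks.
With two selective feeders per site it is possible to manipulate local
population density: a randomly chosen 20% of a site's established birds
(those recorded ≥ 100 times in a pre-experimental period) keep access only
at the *low-density* feeder and lose it at the *high-density* feeder,
which every other tagged bird can use; every landing is recorded whether
or not the flap opens. `flocknet` turns the resulting raw antenna-read
streams into the quantities such an experiment is analysed with, and ships
a seeded colony simulator so the entire pipeline is testable without any
field data.

## What it computes

* **Flocking events** — reads at a feeder are segmented at gaps > τ
  (600 s) and clustered within segments by a univariate Gaussian mixture
  fitted with EM, K selected by BIC; a fixed tumbling-window detector is
  the fast fallback. Events feed a binary group-by-individual matrix.
* **Association networks** — edges weighted by the simple ratio index,
  the proportion of flocks containing either bird in which both occurred:
  `w_ab = T_ab / D_ab ∈ [0, 1]`.
* **Network metrics** — global: unweighted density, mean nonzero edge
  weight, global clustering (3·triangles / connected triples); per bird:
  weighted degree `s_i = Σ_j w_ij`, average association strength
  `s_i / k_i`, Barrat weighted clustering, weighted eigenvector
  centrality (power iteration, per component, max 1), mean flock size.
* **Assortment by treatment** — Newman's weighted assortativity
  `r = (Σ_k e_kk − Σ_k a_k²) / (1 − Σ_k a_k²)` from the mixing matrix
  `e_kl` of edge weight joining label k to l, with Newman's edge-jackknife
  SE and a node-label permutation null (1000 shuffles, two-tailed p with
  the +1 correction).
* **Inference** — period × treatment cell means and Tukey-adjusted
  pairwise contrasts (glmmTMB/emmeans), and a node-permutation test that
  shuffles bird identities within each site-period network (structure
  fixed) and refits per permutation; significance = observed contrast
  outside the central 95% of its null.
* **Patch discovery** — eligibility filters, discovered yes/no, latency
  from trial start, and arrival order with birds arriving within 10 min
  grouped as ties.
* **Synthetic colony** — Poisson flock arrivals in a 07:00–17:00 window,
  preference-weighted recruitment with bonded pairs, partial compliance of
  restricted birds (denied visits recorded with `access = 0`), feeder
  outages, and an optional network-based-diffusion generator for novel
  patch discovery. Identical config + seed ⇒ byte-identical output.

## Worked example

A two-site colony, three pre-experimental and six experimental days,
compliance 0.8:

```r
library(flocknet)

cfg <- sim_config(n_sites = 2, birds_per_site = 30, days_pre = 3,
                  days_exp = 6, eligibility_min_reads = 40,
                  compliance = 0.8, seed = 2024)
sim <- simulate_colony(cfg)
#> <colony_sim> 9678 reads, 1090 planted events, 60 birds
#> <experiment_design> 2 experimental + 0 control site(s), 3 + 6 days
#>   treatments: high=50, low=10

filt   <- filter_failed_days(sim$visits, sim$design)
events <- detect_flocks(filt$visits, method = "window")   # 1015 events
sd_    <- site_density_series(filt$visits, events, sim$design)
aggregate(cbind(prop_recordings, n_individuals, mean_flock_size)
          ~ role + period, data = sd_, FUN = mean)
#>   role period prop_recordings n_individuals mean_flock_size
#> 1 high during            0.72            29             4.8
#> 2  low during            0.28            15             1.9
#> 3 high    pre            0.50            28             3.4
#> 4  low    pre            0.50            29             3.4
```

Before the manipulation the two feeders are equivalent (half the
recordings each, same flock sizes); during it, the low-density feeder
keeps about a quarter of the site's recordings, half the visitors and
flocks of 2 rather than 5 — the manipulation worked. The during-period
network now assorts by treatment:

```r
pn   <- period_networks(events, sim$design)
np   <- pn[[which(vapply(pn, function(x)
          x$site == "S1" && x$period == "during", TRUE))]]
tr   <- setNames(sim$design$treatments$treatment, sim$design$treatments$tag)
labs <- tr[rownames(np$network)]
assortment_null(np$network, labs, n_perm = 1000, seed = 1)
#>      r    se null_low null_high null_mean     p n_perm
#> 1 0.39 0.093   -0.074    0.0096    -0.037 0.001   1000
```

The observed coefficient (0.39 ± 0.09) lies far outside the null range of
label-shuffled networks ([−0.07, 0.01]): birds of the same treatment
forage together more than chance expects. Restricted birds also end up
less connected and less central:

```r
nm <- node_metrics(np$network, np$gbi)
nm$treatment <- labs[nm$tag]
aggregate(cbind(weighted_degree, weighted_eigenvector, mean_flock_size)
          ~ treatment, data = nm, FUN = mean)
#>   treatment weighted_degree weighted_eigenvector mean_flock_size
#> 1      high             2.5                 0.74             5.7
#> 2       low             1.2                 0.25             2.9
```

`run_pipeline(config)` chains all stages (simulate/load → detect →
networks → metrics → assortment → permutation tests → discovery) and
writes tidy CSVs with JSON schema sidecars plus a manifest of seeds and
exclusions; see `?run_pipeline`.

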