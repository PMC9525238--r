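# habtrans

Inference of habitat-preference evolution across large molecular
phylogenies: how often lineages cross the marine/non-marine boundary (the
"salt barrier"), in which direction, when, and what the ancestral habitats
were.

The package is aimed at microbial ecologists and evolutionary biologists
working with environmental-sequencing phylogenies (OTU trees with branch
lengths in substitutions/site and per-tip habitat annotations). It provides
the full analysis chain — tree and metadata I/O, the evolutionary model,
Bayesian rate estimation, model comparison, ancestral reconstruction,
transition counting and dating, community-level checks — together with a
synthetic-data generator with recorded ground truth, so every stage is
testable without any external data.

## The model

Habitat preference is a binary trait evolving along the phylogeny under a
two-state continuous-time Markov chain (Mk2) with instantaneous rates

    q_MN : marine -> non-marine        q_NM : non-marine -> marine

(both in transitions per substitution/site). The stationary distribution is
`pi = (q_NM, q_MN) / (q_MN + q_NM)` and the transition probabilities have
the closed form `P_ij(t) = pi_j + (delta_ij - pi_j) exp(-(q_MN + q_NM) t)`.
Likelihoods are computed by Felsenstein pruning with per-node scaling;
clade-specific rate regimes can be painted onto branches (a clade's stem
branch belongs to its regime, nested clades resolve to the most specific).
The *global rate* of a clade is the scalar `r = pi_M q_MN + pi_NM q_NM`
obtained by normalizing the rate matrix — the expected number of habitat
transitions per unit branch length at stationarity, regardless of
direction.

Estimation is Bayesian: an exponential prior on each rate whose mean is
itself drawn uniformly on (0, 2), and a reversible-jump MCMC that mixes
between the equal-rates and unequal-rates models. Marginal likelihoods for
model comparison (homogeneous vs clade-heterogeneous rates) come from
stepping-stone sampling; `logBF = 2 (logZ_A - logZ_B) >= 10` is treated as
decisive. Ancestral habitats are reconstructed both marginally (per-node
posterior probabilities, up-down algorithm) and jointly (exact
maximum-likelihood history, Pupko dynamic programming). Reconstructed
histories yield directed transition events; an event is *counted* only if
it founds a clade with at least two tips in the new habitat (the
persistence rule), and events are dated on relative chronograms (mean path
length, root age = 1). Community-level distinctness uses unweighted UniFrac
with a Monte-Carlo permutation test, and sequence-similarity networks are
scored by Newman's habitat assortativity.

## Worked example

```r
library(habtrans)

# a synthetic clade: 150 tips, marine->non-marine rate 0.8, reverse 0.2
tr  <- simulate_tree(150, seed = 4)
sim <- simulate_history(tr, rate_model(0.8, 0.2), seed = 5)
table(sim$atree$labels)
#>     marine non_marine
#>         28        122

# posterior of the transition rates (reversible-jump MCMC)
post <- sample_posterior(sim$atree, gens_per_tree = 2000, seed = 6)
print(summary(post), digits = 3)
#>       regime q_mn_mean q_mn_lo q_mn_hi q_nm_mean q_nm_lo q_nm_hi
#> 1 background     0.847   0.318    1.53     0.168  0.0707   0.318
#>   global_rate_mean ratio_lo ratio_hi p_equal
#> 1            0.276     2.52     10.5       0
```

The posterior recovers the simulated asymmetry: the marine-to-non-marine
rate is estimated about five times the reverse rate, the 95% interval of
the ratio excludes 1, and the equal-rates model receives essentially no
posterior mass (`p_equal = 0`). `global_rate_mean` is the normalized-matrix
overall transition speed.

```r
# joint-ML habitat history, persistence-filtered events, relative timing
mod <- rate_model(summary(post)$q_mn_mean, summary(post)$q_nm_mean)
ev  <- event_times(count_transitions(joint_ml_states(sim$atree, mod)),
                   mpl_chronogram(tr))
ev[ev$counted, c("direction", "persistent_tip_count", "relative_time")]
#>    direction persistent_tip_count relative_time
#> 2      NM->M                    2     0.9076908
#> 3      NM->M                    2     0.9636923
#> 4      NM->M                    3     0.8667268
#> 6      NM->M                    6     0.5864354
#> 11     NM->M                    2     0.9384147
#> 12     NM->M                    6     0.6790961
#> 14     M->NM                    2     0.8617083
#> 16     NM->M                    2     0.8791216

# how phylogenetically distinct are the two communities on this tree?
marine <- names(sim$atree$labels)[sim$atree$labels == "marine"]
unifrac_unweighted(tr, marine, setdiff(tr$tip.label, marine))
#> [1] 0.814464
```

Eight transition events survive the persistence filter; `relative_time`
runs from 0 (root) to 1 (present), so most of these switches are recent.
`run_clade_analysis()` wraps this whole chain (eligibility rules, rate
posteriors, model comparison, event tallies, subsampling sensitivity) over
many clades and emits a JSON report; see the methods vignette
(`vignettes/habitat-transitions.Rmd`) for the statistical details and
design choices.

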