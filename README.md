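# netattack

Simulation of symptom-deactivation attacks on psychopathological symptom
networks, for researchers in network psychometrics who want to test
whether *central* symptoms (high degree or strength) and *bridge*
symptoms (high modular bridgeness or overlap) are better treatment
targets than arbitrary ones.

A symptom network is an undirected weighted graph: nodes are symptoms,
edges are estimated pairwise interactions (partial correlations
$\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ from a Gaussian
graphical model, or logistic couplings from an Ising model — both
LASSO-regularized with EBIC model selection,
$\mathrm{EBIC} = -2\ell + k\ln n + 2\gamma k\ln p$). The package:

1. **generates or estimates networks** — synthetic ensembles matched to
   the descriptive profile of published cross-sectional networks
   (5–120 nodes, densities 0.067–0.861, signed weights), planted-module
   fixtures with known ground truth, plus `estimate_ggm()` /
   `estimate_ising()` for raw data;
2. **ranks symptoms** by degree, strength, modular overlap and modular
   bridgeness (effective number $1/\sum_m p_m^2$ of a symptom's fuzzy
   module membership and of its module connection profile);
3. **simulates attacks** — removing symptoms one at a time in descending
   order of each measure, or uniformly at random (2,000 replicates),
   recording connectivity, number of components, and average path length
   after every removal;
4. **reduces trajectories** to five outcomes: impact magnitude (peak −
   initial) and attack extent (proportion removed to first reach the
   peak) for components and path length, and the extent to a 50%
   connectivity drop;
5. **compares conditions** across networks with 20%-trimmed-mean
   dependent-samples bootstrap-t tests (omnibus $F_t$ vs. a bootstrap
   critical value; post hoc psihat, 95% CI, test statistic, and one
   familywise critical value per outcome family).

## Worked example

Build a network of two 6-symptom disorders sharing one symptom, and ask
which symptom each measure nominates:

```r
library(netattack)
pm  <- gen_planted_modules(c(6, 6), shared_nodes = 1)
net <- pm$network
net
#> symptom_network: 11 symptoms, 30 edges (density 0.545)
#>   weights in [0.000, 1.000], 0 negative edge(s)
head(symptom_measures(net), 4)
#>   symptom degree strength  overlap bridgeness module
#> 1     S01     10       10 1.541401   1.983607      2
#> 2     S02      5        5 1.078617   1.162839      2
#> 3     S03      5        5 1.078617   1.162839      2
#> 4     S04      5        5 1.078617   1.162839      2
```

S01 is the planted shared symptom: it tops every measure — 10
connections, and its membership and connection profile both spread over
the two modules (overlap 1.54, bridgeness 1.98 ≈ "effectively two
modules"), while pure one-disorder symptoms sit near 1.

Run the full study on a small synthetic ensemble:

```r
nets <- gen_network_ensemble(ensemble_spec(12, node_range = c(8, 30), seed = 5))
report <- run_study(study_config(networks = nets, n_sims = 200,
                                 robust = robust_config(B = 500, seed = 2), seed = 7))
report
#> study_report: 12 networks x 5 conditions
#>   omnibus significant: components_magnitude, pathlength_magnitude, connectivity_extent
report$omnibus$components_magnitude
#> robust omnibus: F_t = 7.121, F_crit = 5.258 (significant at alpha = 0.05, n = 12)
head(report$posthoc$components_magnitude[, 1:5], 4)
#>                    pair    psihat     ci_low   ci_high test_statistic
#> 1     random vs. degree -0.873125 -2.2081319 0.4618819    -2.85269503
#> 2   random vs. strength -0.873125 -2.1798394 0.4335894    -2.91446071
#> 3 random vs. bridgeness  0.126875 -0.2938486 0.5475986     1.31535099
#> 4    random vs. overlap  0.001875 -0.6182283 0.6219783     0.01318863
```

The omnibus test says the five attack conditions differ in how much they
fragment these networks ($F_t = 7.12$ exceeds its bootstrap critical
value 5.26). The negative psihat for random vs. degree (−0.87) means the
random condition's trimmed-mean impact on the number of components is
smaller than the degree condition's — targeted deactivation of
high-degree symptoms breaks the networks apart more than random
deactivation, though with only 12 networks this pairwise difference is
not itself significant at the familywise threshold.

## Repository layout

- `R/`, `src/` — implementation (S3 classes; compiled per-step metric kernel)
- `tests/testthat/` — unit, property and acceptance tests with pure-R
  enumeration oracles
- `vignettes/symptom-network-attack.Rmd` — methods, design choices,
  limitations
- `scripts/acceptance.R` — end-to-end study runner
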