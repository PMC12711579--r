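# meioco

Crossover interference analysis from F2 genotype data.

`meioco` is for geneticists who map meiotic crossovers (COs) in segregating F2
populations — e.g. dense-marker genotyping-by-sequencing of an *Arabidopsis*
Col × L*er* cross — and want to quantify **crossover interference**: the
tendency of COs on a chromosome to be spaced further apart (positive
interference) or closer together (negative interference, clustering) than
independent placement predicts.

## What it computes

An F2 individual's genome records two independent meioses; COs appear as
switches between marker genotype classes (`AA`, `AB`, `BB`). The package:

* calls COs from genotype transitions with a support-threshold segment caller,
  representing each CO by the midpoint of its flanking-marker interval;
* extracts **cis-double-crossovers** (cis-DCOs) — two COs on the same
  transmitted haplotype, visible as parental–heterozygous–parental triples
  (`AA–AB–AA`, `BB–AB–BB`) — and their inter-CO distances;
* builds the random-placement null by resampling pairs of CO midpoints per
  chromosome, bins both distance distributions (3.15-Mb bins) and fits gamma
  distributions to each by maximum likelihood;
* tests whether short cis-DCOs (< 5 Mb) sit closer to chromosome ends than
  chance by a permutation test with add-one-corrected empirical p-values;
* computes **coefficient-of-coincidence** profiles,

      CoC(d) = observed double-CO frequency at inter-interval distance d
               / frequency expected under independence,

  in two constructions (classical interval pairs, and the cis-DCO distance
  histogram against the resampled null) — CoC = 1 means no interference,
  CoC < 1 positive interference, CoC > 1 at short distances CO clustering;
* produces 300-kb windowed CO landscapes, telomere→centromere arm-scaled
  profiles, arm/pericentromere counts, and group comparisons
  (Kruskal–Wallis + Dunn, pairwise Wilcoxon, Bonferroni-corrected).

A built-in meiosis simulator generates F2 populations with known CO truth
under Poisson (no interference), stationary gamma-renewal (bivalent shape ν,
chromatid-thinned to the gamete) or Neyman–Scott clustered placement, so every
stage is testable without external data.

## Worked example

Simulate a wild-type-like population with strong positive interference
(gamma shape ν = 5), then analyse it:

```r
library(meioco)
genome <- synthetic_genome(n_chrom = 5, chrom_length = 30e6)
pop <- simulate_f2_population(sim_config(
  genome, co_intensity = 0.85, model = "gamma_renewal", nu = 5,
  n_individuals = 300, marker_spacing = 5e4, seed = 7))
fit <- co_interference(pop, params = analysis_params(n_perm = 1000, seed = 7))
print(fit)
```

```
Crossover interference analysis
  chromosomes: 5  groups: all
  [all] 300 individuals, 2514 COs (8.38 per individual), 184 cis-DCOs
        CoC (interval pairs), shortest class: 0.605
```

The caller recovers ~8.4 COs per individual (2 meioses × 5 chromosomes ×
0.85), and the shortest-distance CoC of 0.605 reflects the simulated
interference (an F2 individual superposes two meioses, so individual-level CoC
under strong interference plateaus near 0.5, not 0). The summary and gamma
coefficients:

```r
summary(fit)$table
#>  group n_individuals n_co mean_co n_cis_dco median_dco_distance gamma_shape
#>    all           300 2514    8.38       184            12104087    5.538833
#>  coc_shortest  coc_mean p_end_bias
#>     0.6051423 0.9246221   0.973027

coef(fit)
#>   group   series    shape         rate
#> 1   all observed 5.538833 4.403297e-07
#> 2   all expected 1.343738 1.385579e-07
```

The observed cis-DCO distances fit a gamma with shape ≈ 5.5 (regular spacing,
median 12.1 Mb) while the resampled random-pairing null fits shape ≈ 1.3; the
permutation p of 0.97 says short cis-DCOs show no bias toward chromosome ends
— as expected under this generative model. `plot(fit)` draws the distance
histograms with gamma overlays, the CoC profile, and the per-chromosome CO
landscape. Re-running the same configuration and seeds reproduces every number
exactly.

For a Poisson (no-interference) simulation the same analysis gives mean
CoC ≈ 1.0 across distance classes; for clustered placement the shortest-bin
CoC rises to ~3 and the observed short-distance cis-DCO frequency exceeds the
resampled expectation — the negative-interference signature.

## Package tour

| Function | Purpose |
| --- | --- |
| `genome_map()`, `synthetic_genome()` | chromosome geometry, pericentromeres |
| `sim_config()`, `simulate_f2_population()` | synthetic F2 populations with truth |
| `segment_population()`, `call_crossovers()` | genotype segmentation and CO calls |
| `extract_cis_dcos()`, `expected_distance_sample()` | cis-DCOs and the resampled null |
| `bin_distances()`, `fit_gamma()` | distance distributions and gamma MLE |
| `short_dco_position_test()` | permutation test for chromosome-end bias |
| `coc_profile()` | CoC by interval pairs or distance histogram |
| `window_co_frequency()`, `scaled_landscape()`, `region_counts()` | landscapes |
| `compare_groups()`, `percent_change_summary()` | group statistics |
| `co_interference()` | one-call analysis returning a classed result object |
| `run_pipeline()` | file-in/file-out orchestration with JSON provenance |

See `vignette source in vignettes/crossover-interference.Rmd` for the methods
account: model assumptions, parameter meanings and defaults, numerical
choices, and what the simulator does and does not emulate.
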