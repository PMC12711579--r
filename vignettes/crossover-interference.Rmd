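---
title: "Measuring crossover interference from F2 genotype data"
author: "meioco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crossover interference from F2 genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

During meiosis, homologous chromosomes exchange segments at crossovers (COs).
Class I COs are subject to *interference*: two COs on the same chromosome tend
to be spaced further apart than expected if they formed independently. Loss of
synaptonemal-complex components can abolish interference or even reverse it,
producing *negative interference* — COs that cluster at short distances.

The classical measure is the **coefficient of coincidence**,

$$\mathrm{CoC}(d) \;=\; \frac{\text{observed frequency of double COs in interval
pairs at distance } d}{\text{frequency expected under independent placement}},$$

with CoC = 1 under independence, CoC < 1 under positive interference, and
CoC > 1 at short distances under CO clustering.

In an F2 population genotyped at dense SNP markers (e.g. a Col × L*er*
*Arabidopsis* cross), each individual's genome records two independent meioses.
COs appear as switches between genotype classes (`AA`, `AB`, `BB`) along a
chromosome. Two COs on the *same* transmitted haplotype — a *cis* double
crossover (cis-DCO) — are visible as a parental–heterozygous–parental triple
(`AA–AB–AA` or `BB–AB–BB`); the `AA–AB–BB` (trans) pattern instead reflects one
CO from each parental meiosis and is uninformative about interference. The
distances between cis-DCO transitions, compared with distances between randomly
re-paired CO midpoints, measure interference directly from segregating
populations without cytology.

`meioco` implements this analysis end to end — CO calling from genotype
transitions, cis-DCO extraction, resampled random-placement nulls, gamma fits,
a permutation test for positional bias, CoC profiles, and windowed CO
landscapes — together with a synthetic meiosis simulator with tunable
interference, so every stage can be validated against known ground truth.

## The synthetic meiosis generator

`sim_config()` + `simulate_f2_population()` generate F2 populations under three
generative models, per gamete per chromosome:

* **`poisson`** — the no-interference reference: CO count is
  Poisson(`co_intensity`), positions i.i.d. uniform. An optional `end_bias`
  exponent skews the placement density toward the telomeres
  ($f(x) \propto (\min(x, L-x)/L)^{-\beta}$, $0 \le \beta < 1$), mimicking the
  distal recombination bias seen in real landscapes.
* **`gamma_renewal`** — the standard gamma renewal model of positive
  interference. Chiasma positions on the *bivalent* form a stationary renewal
  process with gamma(ν, λ) inter-event distances, λ = 2·`co_intensity`·ν/L, so
  the bivalent carries 2·`co_intensity` chiasmata on average. Each chiasma
  involves two of the four chromatids, so the transmitted chromatid retains
  each chiasma independently with probability 1/2. This "simulate the bivalent,
  thin to the gamete" construction matters: thinning preserves the mean but
  dilutes interference, so gamete-level interference is realistically weaker
  than the bivalent-level shape ν would suggest. ν = 1 recovers the Poisson
  model exactly; we verify that equivalence by a Kolmogorov–Smirnov test in the
  suite.
* **`clustered`** — negative interference as a Neyman–Scott cluster process:
  Poisson(`cluster_rate`) seeds placed uniformly, each spawning
  1 + Poisson(`cluster_size_mean` − 1) COs at Laplace(`cluster_scale`) offsets,
  clipped to the chromosome. A cluster process is the minimal generator of the
  negative-interference signature: an excess of very short inter-CO distances
  over the random-placement expectation.

Stationarity of the renewal start is exact, not burned in: the first
inter-event distance is drawn from the closed-form equilibrium
(forward-recurrence) distribution
$F_e(x) = (\lambda/\nu)\,x\,(1 - F_{\nu,\lambda}(x)) + F_{\nu+1,\lambda}(x)$,
inverted numerically per track. Draws beyond the chromosome end simply yield a
chiasma-free bivalent.

Defaults encode a wild-type-like *Arabidopsis* F2 design: five 30-Mb
chromosomes, `co_intensity` 0.84 COs per gamete per chromosome (≈ 8.4 COs per
F2 individual genome-wide, allocated proportional to length), mean marker
spacing 50 kb (a realistic genotyping-by-sequencing marker density), no
missingness unless requested. `obligate_co` (rejection sampling at the bivalent
level, capped at 1000 redraws) is off by default since the analysis stages do
not depend on CO assurance.

What the generator deliberately does **not** emulate: read-level noise and
genotype miscalls (only marker dropout via `missing_rate`), chromatid
interference, gene conversion, segregation distortion, sex-specific maps, and
real marker-density heterogeneity. Passing tests therefore validate the
*analysis logic*, not robustness to every artefact of real
genotyping-by-sequencing data; the support-threshold caller is the only line of
defence against genotyping flicker.

## Crossover calling

Real pipelines call COs from read counts with hidden-Markov smoothing; `meioco`
starts from genotype-level input and uses a transparent support-threshold
caller (`segment_population()`): missing calls are dropped, maximal runs of
identical genotype become segments, and any run supported by fewer than
`min_support` markers (default 3) is dissolved — its markers ignored, flanking
same-genotype segments merged — iterating until stable. Each adjacent segment
pair yields one CO bounded by the flanking markers, represented everywhere by
its interval **midpoint**. A direct `AA`/`BB` adjacency implies two allele
changes and is emitted as two stacked, flagged events.

Consequences worth knowing: with `min_support` = 3, true COs landing within two
markers of a chromosome end are dissolved, and same-gamete CO pairs closer than
three markers merge away. On noiseless 50-kb-spaced markers with
`min_support` = 1 the caller recovers ≥ 99% of true COs with midpoint error
bounded by the marker spacing (verified against the simulator's truth archive).

## The interference analysis

**cis-DCO extraction** (`extract_cis_dcos()`): every consecutive segment triple
(P, AB, P) with the same parental genotype P on both sides yields one event;
its distance is the difference of the two transition midpoints. Overlapping
triples (three COs forming two nested patterns) are all counted and flagged.

**Random-placement null** (`expected_distance_sample()`): per chromosome,
`n_pairs` (default 200) pairs of CO midpoints are resampled uniformly *with
replacement* from the pooled observed midpoints of the genotype group, and
absolute differences recorded. Resampling with replacement is well defined for
small pools; because the pool is the empirical CO distribution, the null
inherits the observed CO landscape while destroying within-gamete spacing.

**Distance distributions** (`bin_distances()`): both series are binned in
uniform bins (default 3.15 Mb), normalized within series, medians recorded, and
gamma distributions fitted to each by maximum likelihood (`fit_gamma()`, via
`fitdistrplus`), initialized at the method-of-moments estimate — the MLE
log-likelihood is verified to dominate the moment fit. Distances are rescaled
by their mean before optimization (rates of order 10⁻⁷ per bp are poorly scaled
otherwise) and the fitted rate mapped back. Zero distances, which a gamma
density cannot support, are offset by half the smallest positive distance; the
count of affected points is kept in the fit object.

**Positional permutation test** (`short_dco_position_test()`): for short
cis-DCOs (distance < 5 Mb by default) the statistic is the mean normalized
distance of event midpoints to the nearest chromosome end. Each permutation
replaces every event midpoint with a uniform position on its own chromosome
(default 10,000 iterations). The primary p-value is one-sided toward the ends —
the direction in which clustering is biologically expected — with the two-sided
value also reported, and uses the add-one correction
$p = (1 + \#\{\bar d_{null} \le \bar d_{obs}\})/(1 + n_{perm})$ so p is never
exactly zero and remains valid under discreteness. Calibration (p uniform when
events truly are uniform) is checked over 200 replicate datasets.

**CoC profiles** (`coc_profile()`) in two constructions that must agree at
CoC = 1 under independence — shipping both provides an internal cross-check:

* `interval_pairs` (classical): chromosomes are tiled into 3.15-Mb intervals;
  for interval pair (i, j), observed = fraction of individuals with ≥ 1 CO in
  both, expected = product of marginal interval frequencies; CoC per distance
  class |i − j| pools the summed observed over summed expected across
  chromosomes (weighting each chromosome by its CO activity). Note the unit of
  observation is the F2 *individual*, which superposes two independent
  meioses; superposition dilutes gamete-level interference roughly as
  (1 + CoC_gamete)/2 at low CO densities, so individual-level CoC under strong
  interference plateaus near 0.5 rather than 0.
* `distance_histogram`: observed cis-DCO distance frequencies divided bin-wise
  by the resampled expected frequencies. When the group's per-chromosome mean
  CO count λ is supplied, the expected series is first rescaled so its total
  matches the independence expectation of double-CO counts,
  $n_{ind}\,\mathbb{E}\binom{N}{2} = n_{ind}\lambda^2/2$ with N ~ Poisson(λ);
  without rates it reduces to a plain ratio of relative frequencies. The
  rescaling interpretation is our own, documented choice; the interval-pair
  mode is the independent check that it is calibrated (both sit at 1 under
  Poisson simulations).

Bins with zero expected mass are masked (`NA`), never reported as infinite.

## Landscapes and group comparisons

`window_co_frequency()` bins CO midpoints into 300-kb windows (counts conserve
totals exactly; a CO whose uncertainty interval spans a boundary is assigned by
midpoint alone). `scaled_landscape()` maps window centres onto a
telomere(0)→centromere(1) axis per arm and averages across all arms in 100
equal scaled bins — averaging, not summing, is the default so chromosomes of
different arm number and length contribute comparably; summing is available.
`region_counts()` splits per-individual counts into arm and pericentromere
using the user-supplied pericentromere intervals (in real data these come from
DNA-methylation profiles; the synthetic genome places them as the central 20%).

`compare_groups()` performs the field's standard battery: Kruskal–Wallis on
per-individual totals, Dunn's pairwise z-tests (tie-corrected, implemented
in-package and cross-checked against the Kruskal–Wallis statistic in the
two-group case) and two-sided Wilcoxon rank-sum tests on arm and pericentromere
counts, all Bonferroni-adjusted. `percent_change_summary()` covers the simple
fertility arithmetic (percent change of a pooled group mean against a
reference; percentage-point differences for quantities already in percent).

## Numerical and design choices

* Coordinates are 1-based inclusive; windows half-open [start, start + w);
  BED-style export would be 0-based half-open.
* Single-chromosome tracks with a centromere at an end degenerate to one arm
  and are handled (with a note), for toy genomes.
* All randomness flows from one seed (`sim_config(seed=)` for generation,
  `analysis_params(seed=)` for the analysis), making populations and whole
  pipelines byte-reproducible; `run_pipeline()` embeds the seed in its JSON
  report and writes no timestamps.
* Validation problem sizes: the calibration studies in the test suite use
  2,000 simulated individuals on five 30-Mb chromosomes at 0.85 COs per gamete
  per chromosome (matching the scale of published F2 designs of ~260
  individuals per genotype, upscaled for tight Monte-Carlo error on CoC);
  caller-fidelity and cis-DCO audits use 200–500 individuals.

## A worked run

```{r example}
library(meioco)
genome <- synthetic_genome(n_chrom = 5, chrom_length = 30e6)
pop <- simulate_f2_population(sim_config(
  genome, co_intensity = 0.85, model = "gamma_renewal", nu = 5,
  n_individuals = 300, marker_spacing = 5e4, seed = 7))
fit <- co_interference(pop, params = analysis_params(n_perm = 1000, seed = 7))
summary(fit)
coef(fit)
```

```{r plot, fig.width = 9, fig.height = 3}
plot(fit)
```

## Limitations

The caller is genotype-level: it cannot model allele-count uncertainty, so
heavy genotyping error must be handled upstream. Interference strength is
*described* (CoC, gamma shape of distance distributions), not *estimated* as a
likelihood-based renewal shape from gamete data. cis-DCOs see only same-gamete
CO pairs whose intervening heterozygous segment survives in the F2 — a pair
masked by a CO on the homologous gamete is invisible, which is why the CoC
under strong positive interference is bounded away from zero at the individual
level. All intensities are per physical length; no genetic-map rescaling is
applied.
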