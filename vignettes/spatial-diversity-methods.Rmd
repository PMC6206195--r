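---
title: "Methods: spatial mapping of mitochondrial diversity, AMOVA, and SDM consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial mapping of mitochondrial diversity, AMOVA, and SDM consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscape)
```

`divscape` analyzes georeferenced mitochondrial sequence data from
landscape-scale surveys: where is genetic diversity concentrated, how
much of it is structured by river basins, and where do distribution
models agree on suitable habitat. This vignette documents the statistical
procedures, the conventions and numerical choices behind them, and what
the synthetic-data generator does and does not emulate.

## Data model

An alignment is a matrix of equal-length sequences over `A C G T - N`.
`N` is stored but treated as missing data by every statistic; `-` is an
alignment gap. A sample table links each specimen (id, latitude,
longitude, river basin, mitochondrial phylogroup) to one alignment row.
Phylogroup labels are taken as given — tree inference is out of scope;
any upstream phylogenetic workflow can supply them.

## Repeat-sample deduplication

Noninvasive sampling can collect the same individual twice. Two samples
are candidate repeats only if their rows are bitwise identical,
including `N` positions — no mismatch tolerance, because any tolerance
threshold would be arbitrary. Among identical haplotypes, a greedy pass
in input order keeps a sample iff it is at least `min_km` (default 1 km,
above the home-range scale of a water shrew) from every already-kept
sample of that haplotype; a pair at exactly `min_km` is kept on both
sides. Greedy first-kept-wins makes the result deterministic and
input-order reproducible. Distances are haversine on a sphere of radius
6371.0088 km; the sub-0.5% ellipsoidal error is immaterial at both the
1 km and the 75 km scales used here.

## Diversity estimators

* π (nucleotide diversity): mean pairwise p-distance over all n(n−1)/2
  pairs. Each pair uses **pairwise deletion**: a site enters the
  comparison only when both characters are `A/C/G/T`. Pairwise deletion
  maximizes the data behind the headline statistic. A pair with zero
  comparable sites is an error, not a zero.
* θ_W (Watterson): S/(a_n·L) with **complete deletion** — only columns
  free of non-ACGT characters count, keeping S and its denominator L
  consistent.
* Haplotype diversity: (n/(n−1))(1 − Σ f_k²) over bitwise-identical row
  classes.
* Distance matrices: `p` (computed here), `JC69` and `K80` (delegated to
  `ape::dist.dna`, pairwise deletion). A saturated pair (p ≥ 3/4 for
  JC69) raises an error rather than returning `NaN`. The distance model
  feeding AMOVA defaults to `p` with the corrections available by
  argument: the choice of model is exposed as configuration because
  either is defensible for closely related mitochondrial lineages, where
  the corrections are nearly the identity.

π is reported to 4 decimal places in serialized outputs, matching the
precision at which such surveys report diversity values.

## Moving-window diversity surface

For every sampling point, the window is the **closed** 75 km
great-circle ball around it (a neighbor at exactly the radius is a
member; the boundary convention has to be fixed somewhere and inclusive
matches "found within a radius"), restricted to samples carrying the
center's phylogroup label, the center included. The window's π is
reported only when at least `min_samples` (default 5) samples support
it; smaller windows are omitted, not zero-filled. Windows sit on
sampling points, not on a raster: interpolating between points would
manufacture precision the sampling design cannot support.

The phylogroup restriction is the scientifically load-bearing choice:
where two deeply divergent lineages meet, an unrestricted window would
report the between-lineage divergence as "diversity". Restricted
windows measure within-lineage variation only, so contact zones are not
artificially elevated. The acceptance suite checks both directions: no
systematic elevation with the restriction, clear elevation without it.

## One-way AMOVA

Squared pairwise distances are decomposed with the standard one-level
Excoffier–Smouse–Quattro sums:

SS_total = (1/n)·Σ_{i<j} d²_ij, SS_within = Σ_g (1/n_g)·Σ_{i<j∈g} d²_ij,
SS_among = SS_total − SS_within; σ²_within = MS_within,
σ²_among = (MS_among − MS_within)/n_c with
n_c = (n − Σ n_g²/n)/(k−1); Φ_ST = σ²_among/(σ²_among+σ²_within).

A negative σ²_among (possible under method-of-moments) is retained as
computed; only the *displayed* percent variation is clamped to [0,100].
Besides the σ²-based percent, the SS-ratio percent is also reported,
since summaries in the literature do not always say which of the two a
printed percentage is.

Significance: group labels are permuted with group sizes fixed, and
p = (1 + #{Φ* ≥ Φ})/(1 + n_perm) with the observed configuration counted
once — the conventional unbiased permutation estimator (default
n_perm = 999). The comparison uses a 1e−12 slack so ties at the observed
value count as exceedances. The seed is an explicit argument (default 1)
and is echoed in printed output; the caller's RNG state is restored
afterwards. Sum-of-squares conservation is tested to 1e−9, and the
decomposition is cross-checked against an independent implementation
(`vegan::adonis2`, whose one-factor partition of a distance matrix is
algebraically the same decomposition).

## SDM post-processing

Only post-processing of externally fitted suitability models is in
scope. Three operations:

* **Predictor pruning** drops a variable iff its absolute Pearson
  correlation with any already-kept variable reaches the threshold
  (default 0.8), scanning greedily in input order. Which member of a
  correlated pair survives is decided by input order (in practice, BIO
  variable numbering); the procedure is order-dependent by construction
  and documented as such. Zero-variance variables are an error.
* **Percentile thresholding** sets the cutoff at the given percentile
  (linear interpolation, `stats::quantile` type 7) of the model's
  suitability at the presence localities — the "percentile training
  presence" convention — and marks cells with suitability ≥ cutoff.
  Because the convention is not universal, `over = "cells"` computes the
  percentile over all data cells instead. Raising the percentile never
  enlarges the predicted area.
* **Consensus** is the cellwise sum of binary layers (value = number of
  models agreeing); `NA` in any input propagates, and inputs must share
  shape and georeference to 1e−9.

Rasters are held as matrices with a lower-left-corner affine reference
and round-trip through ESRI ASCII grids, a plain-text dialect sufficient
for single-band suitability layers.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analyses
assume, with defaults matching the landscape the package was built for:
132 samples, 2 phylogroups on an Iberia-sized box (36–44°N, 9°W–3°E),
752 bp cytochrome *b* for all samples plus a 450 bp D-loop fragment
(272 bp gap-free core) for 103 of them, between-lineage p-distance
target 1.16%, per-group diversity targets 0.0050 and 0.0003, ten
longitude-band basins, and an among-basin variance fraction of 0.19.

Mechanics and the reasoning behind them:

* **Geography.** Phylogroup ranges are adjacent longitude slabs widened
  by half the contact-band width (default 30 km), so neighbors overlap
  in narrow contact zones. Basins are equal-width longitude bands.
  Coordinates are uniform within a group's range.
* **Between-group divergence** is calibrated at the *sample* level: the
  star-ancestor separation equals the target minus each group's expected
  leaf-to-ancestor distance, because the quantity surveys report is the
  mean p-distance between sampled sequences, not between unobservable
  ancestors.
* **Within-group descent** defaults to a star: every sample draws
  Binomial(L, π_g/2) substitutions from its group ancestor, so realized
  group diversity concentrates tightly at its target. The alternative
  `genealogy = "coalescent"` evolves each group along a Kingman
  genealogy (`ape::rcoal` branch lengths in coalescent units,
  `phangorn::simSeq` mutations at rate π_g/2), reproducing the
  genealogical correlation of real single-locus data — under it π and
  θ_W share an expectation, which the test suite verifies. The star
  default trades that realism for replicate-to-replicate stability: a
  single non-recombining locus has so much genealogical variance that
  region-level parameter-recovery checks would be dominated by it.
* **Basin structure.** Substitutions shared by all of a basin's members
  within a group are added at a rate solved per replicate from the
  realized within-group distances (method-of-moments matching of
  E[d²between]/E[d²within] = 1/(1−f)), so the configured fraction f is
  the true among-basin variance fraction of each simulated dataset. An
  unconditional calibration would leave the replicate-mean far from f
  whenever realized diversity deviates from its expectation.
* **Mutation model** is uniform over the three alternative bases, with
  no rate heterogeneity, no transition bias, no indels: enough to
  exercise p-distances, π, and AMOVA, and nothing downstream here is
  sensitive to richer substitution dynamics.
* **Rasters.** `simulate_rasters()` builds a shared Gaussian-bump
  "true" suitability field plus smooth model-specific noise, clamped to
  [0,1], with a one-cell no-data border; presence points are sampled
  proportional to the true field.

What the generator does **not** emulate: recombination and
heteroplasmy; demographic history (bottlenecks, expansions — realized
diversity is stationary by construction); uneven, river-biased sampling
effort; sequencing error and alignment uncertainty; realistic drainage
geometry (basins are longitude bands, so with two phylogroups the deep
split nests inside the basin factor and dominates a whole-dataset
AMOVA); and realistic climate layers. Passing tests therefore
demonstrate the correctness and calibration of the estimators and
pipeline on data satisfying their assumptions — not robustness to the
violations real surveys bring.

## Degenerate inputs and failure modes

Errors are classed conditions, not message strings: alphabet violations
(`U` and non-N IUPAC ambiguity codes are rejected on input, never
silently recoded), shape mismatches, duplicate identifiers, unlinked
`seq_name`s, pairs with no comparable site, fewer than 2 sequences,
fewer than 2 groups, zero-variance predictors, saturated distances,
all-gapped alignments, and geometry-mismatched rasters each have their
own class. The pipeline validates every referenced input file before any
stage runs, so a misconfigured run leaves no partial outputs.

## Problem sizes in the test suite

The suite verifies estimators against brute-force enumeration on 100+
random alignments (n ≤ 10, L ≤ 50, tolerance 1e−12); AMOVA against
direct arithmetic and `vegan::adonis2` on 20+ random instances, plus a
500-replicate permutation-null calibration (n_perm = 199, rejection rate
at α = 0.05 required in [0.03, 0.07]); parameter recovery on 100
replicate landscapes of 132 samples each (surface maximum in a
doubled-diversity region ≥ 90% of replicates; among-basin percent
within ±5 points of its target on average); and the contact-zone
non-inflation property on pooled windows from 5 landscapes of 200
samples (Mann–Whitney, α = 0.01, with a positive control). These sizes
keep the full suite under a minute on one CPU while leaving each check
statistically decisive.

## Known limitations

* The moving-window surface has no uncertainty quantification; window
  values from overlapping windows are strongly correlated.
* Single-level AMOVA only; no hierarchical designs or pairwise Φ_ST
  matrices between basins.
* p/JC69/K80 distances only; no Γ rate heterogeneity or model averaging.
* The 1 km deduplication rule is a fixed spatial cutoff, not an
  identity model; with dense sampling it can drop genuinely distinct
  individuals sharing a haplotype.
* ESRI ASCII is the only raster dialect; cells are assumed square and
  north-up.
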