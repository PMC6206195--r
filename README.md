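# divscape

Landscape-scale analysis of mitochondrial genetic diversity in
georeferenced samples.

`divscape` implements the analysis stack used in phylogeographic surveys
of Iberian semi-aquatic mammals (water shrews, desmans), where hundreds
of noninvasively collected samples — mostly feces picked off emerged
rocks in mountain rivers — are sequenced for short mitochondrial
fragments (cytochrome *b*, D-loop) and analyzed for spatial structure.
The package covers every step between "aligned sequences plus
coordinates" and "maps, variance components, and consensus rasters":

- **Repeat-sample collapsing.** Feces of one individual can be sampled
  twice. Samples with bitwise-identical haplotypes are collapsed unless
  they lie at least 1 km apart (more than a water shrew's home range);
  distinct haplotypes are never collapsed.
- **Alignment assembly.** Gap-position elimination reduces a gappy
  D-loop alignment to its common core; gene partitions are concatenated
  with `N`-padding for specimens sequenced for only one gene.
- **Diversity estimators.** Nucleotide diversity
  π = mean pairwise p-distance (pairwise deletion of `N`/gaps),
  Watterson's θ_W = S/(a_n·L) (complete deletion), haplotype diversity
  (n/(n−1))(1−Σf_k²), within/between-group p-distances, and p/JC69/K80
  distance matrices.
- **Moving-window diversity mapping.** For each sampling point, π of all
  samples of the *same phylogroup* within a 75 km radius, reported only
  when supported by ≥ 5 samples. The phylogroup restriction keeps window
  values from being inflated in contact zones where divergent
  mitochondrial lineages meet.
- **One-way AMOVA.** Excoffier–Smouse–Quattro variance decomposition of
  squared pairwise distances by river basin, with Φ_ST and a
  label-permutation null:
  σ²_within = MS_within, σ²_among = (MS_among − MS_within)/n_c,
  Φ_ST = σ²_among/(σ²_among + σ²_within).
- **SDM post-processing.** Pearson-correlation pruning of predictor
  variables (|r| ≥ 0.8 dropped), percentile-training-presence
  thresholding of continuous habitat-suitability rasters, and cellwise
  multi-model consensus (ESRI ASCII grid I/O).
- **Synthetic-data generator.** Geo-referenced datasets with the exact
  statistical structure the analyses assume: allopatric phylogroups with
  narrow contact bands, calibrated between-lineage divergence,
  per-group diversity targets, and a tunable among-basin variance
  fraction — so the whole pipeline is testable without any download.

## Worked example

Simulate a two-phylogroup landscape at the default study conditions
(132 samples, 752 bp cytochrome *b*, ten river basins), then run the
pipeline pieces:

```r
library(divscape)

cfg <- sim_config(seed = 42)
sim <- simulate_dataset(cfg)
sim$alignment
#> DNA alignment: 132 sequences x 752 bp

# collapse putative repeat samples (identical haplotype within 1 km)
dd <- dedup_by_haplotype(sim$samples, sim$alignment, min_km = 1)
nrow(dd$kept)
#> [1] 132

# strip D-loop gap positions to its common core, then concatenate
core <- eliminate_gap_positions(sim$dloop)
cc <- concatenate_alignments(list(cytb = sim$alignment, dloop = core))
cc$partitions
#>    name start  end
#> 1  cytb     0  752
#> 2 dloop   752 1024

# phylogroup-aware moving-window diversity map
surf <- diversity_surface(dd$kept, sim$alignment,
                          radius_km = 75, min_samples = 5)
surf
#> Moving-window nucleotide diversity: 26 window(s), radius 75 km, >= 5 samples
#>   pi range: 0.0000 - 0.0074

# one-way AMOVA with river basin as the single factor
d <- distance_matrix(sim$alignment, model = "p")
res <- amova_oneway(d[dd$kept$seq_name, dd$kept$seq_name], dd$kept$basin,
                    n_perm = 999, seed = 1)
res
#> One-way AMOVA
#>                df         SS          MS      sigma2
#> Among groups    9 0.00898325 9.98139e-04 7.48128e-05
#> Within groups 122 0.00230554 1.88979e-05 1.88979e-05
#> Total         131 0.01128879          NA          NA
#> Phi_ST = 0.798338  (80% of variation among groups)
#> Permutation p-value = 0.001  (999 permutations, seed 1)
```

The 272 bp D-loop core plus 752 bp cytochrome *b* give the 1,024 bp
concatenation; specimens without a D-loop sequence carry `N` across its
columns. The window π range (0.0000–0.0074) brackets the two simulated
phylogroup diversity targets (0.0003 and 0.0050). The AMOVA's 80% here
reflects the simulated geography: with basins laid out as longitude
bands, the deep between-lineage split nests inside the basin factor and
dominates the decomposition. On a single-lineage landscape the same
statistic recovers the generator's within-lineage basin effect (19% by
default) — that is the configuration the acceptance script reports.

Everything is also callable as one configured run:

```r
run_pipeline(list(out_dir = "results/run1", seed = 42,
                  simulate = list(n_samples = 132), n_perm = 999))
```

which writes the per-stage outputs plus a `manifest.json` echoing every
parameter, count, and file produced.

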