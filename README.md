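# driftdiet

Diet analysis for stream fish predator communities from 18S V9
metabarcoding of gut contents, paired with drift-net surveys of prey
availability.

Molecular gut-content analysis reads a predator's diet off the DNA in
its gastrointestinal tract: a universal eukaryote marker is amplified,
sequenced, and resolved into per-sample proportions of prey taxa.
driftdiet implements the full analysis chain for such a study and the
statistics that make it ecological — who eats what, how much predator
diets overlap, whether overlap shifts between a period of high prey
abundance (the nocturnal "drift" pulse of larval fishes and aquatic
insect larvae) and a later low-abundance period, and which prey are
actively selected relative to their availability in the river.

It is aimed at fish and food-web ecologists who have (or want to
simulate) three kinds of data: sequence count tables from predator GI
samples, mock tissue homogenates of known composition for calibrating
amplification bias, and nightly drift-net counts with individual dry
masses for prey availability.

## What it computes

**Sample processing** — quality screening (length > 175 bp, homopolymer
runs ≥ 8 bp, dataset-wide singletons), greedy OTU clustering at ≤ 2
edits, reference assignment to ecologically significant units (ESUs) at
≥ 95% identity, rarefaction to 1950 reads, predator self-read removal,
exclusion of samples with < 20 prey reads, and standardization to prey
proportions.

**Amplification bias** — relative correction factors from mock
homogenates,

    RCF_t = (S_t / S_m) × (B_m / B_t),

the odds ratio of a family's sequence share S_t to its biomass share
B_t (S_m, B_m the complements); RCF > 1 flags overrepresentation.
Optional correction of diet proportions by p_i / RCF_t, and the
biomass–sequence Pearson correlation.

**Dietary overlap** — Schoener's index on pooled per-species diets,

    α = 1 − 0.5 × Σ_i |p_xi − p_yi|,

with α > 0.6 flagged as substantial, and a paired sign-flip permutation
test (99,999 iterations by default) for the mean change in α between
periods; Bray–Curtis distance is exported as the exact complement
1 − α.

**Prey selectivity** — Manly's selection index and Chesson's
electivity per species × sampling day against the previous night's
drift availability,

    α_i = (r_i / n_i) / Σ_j (r_j / n_j),
    ε_i = (m α_i − 1) / ((m − 2) α_i + 1),

with r the diet proportion, n the availability proportion (zeros
floored at 0.001 of total biomass), and m the number of surveyed ESUs.

**Synthetic communities** — a fully seeded generator
(`community_config()`, `generate_reference_db()`,
`simulate_diet_samples()`, `simulate_mock_homogenate()`,
`simulate_drift_survey()`) producing reference FASTA, GI count tables
with known true diets and bias, and drift surveys, used by the test
suite for end-to-end parameter-recovery checks.

The package also ships the motivating study's printed calibration
tables (`mock_homogenate_table()`, `drift_biomass_table()`,
`overlap_pairs_table()`) as plain-text fixtures.

## Worked example

Correction factors from the packaged mock-homogenate table, and the
overlap-change test on the packaged pairwise overlap table:

```r
library(driftdiet)

compute_rcf(mock_homogenate_table()[c(1, 2, 11), ])
#>         family biomass_pct sequence_pct   rcf overrepresented undefined
#>  Acipenseridae        8.68        15.49 1.928            TRUE     FALSE
#>   Catostomidae        7.18         3.72 0.499           FALSE     FALSE
#>     Cambaridae        6.42        19.34 3.495            TRUE     FALSE

pairs <- overlap_pairs_table()
paired_sign_flip_test(pairs$alpha_drift, pairs$alpha_postdrift,
                      n_perm = 99999, seed = 1)
#> Paired sign-flip permutation test (two.sided)
#>   mean paired difference: -0.05577
#>   p = 0.00275 over 99999 iterations, 78 pairs
```

Reading: sturgeon (Acipenseridae) and crayfish (Cambaridae) DNA
amplifies roughly 2× and 3.5× beyond their biomass share, while sucker
(Catostomidae) DNA amplifies at half of it — the marker is biased, so
read proportions are interpreted as relative, not absolute, diet
composition. Across the 78 predator species pairs, dietary overlap
drops by 0.056 on average from the high-abundance drift period to the
postdrift period, a small but significant decline (p ≈ 0.003): with
prey scarce, predators partition the niche.

A fully synthetic end-to-end run:

```r
res <- run_pipeline(pipeline_config(seed = 1, n_perm = 9999))
print(res)   # samples retained/excluded, filter counts, RCFs,
             # overlap matrices, permutation test, selectivity
```

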