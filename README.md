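# gekkodiet

Quantitative dietary ecology from stomach-flushing surveys of insectivorous
lizards, built around the analysis of a survey of the Critically Endangered
black-eyed bent-toed gecko (*Cyrtodactylus nigriocularis*) at Ba Den
Mountain, Vietnam: 51 individuals (15 males, 33 females, 3 subadults), 407
prey items in 22 categories.

It is written for field herpetologists and trophic ecologists who have two
delimited tables — one row per captured specimen (sex/age group, snout-vent
length, mouth width, body mass) and one row per recovered prey item
(category, maximum length and width) — and want the standard composition
table, importance ranking and group comparisons, reproducibly and with typed
validation errors instead of silent row drops.

## What it computes

**Prey volume.** Each item is approximated as a prolate spheroid from its
maximum length *L* and width *W*:

    V = (4π/3) · (L/2) · (W/2)²   [mm³]

(with an optional π = 3.14 mode matching the classical field formula; all
percentages are invariant to the choice).

**Diet composition and the Index of Relative Importance.** Per prey
category: the number of stomachs containing it (F), the number of items (N)
and the summed volume (V), each as a percentage of its column total, and

    IRI = (%F + %N + %V) / 3

computed from unrounded percentages and rounded only at presentation. `%F`
supports both denominator conventions found in the diet literature (sum of
occurrences, the default; or number of stomachs). `rank_by_iri()` orders
categories by IRI with an optional `min_F` filter for dropping incidental
single-stomach categories from headline rankings.

**Group comparisons.** Wilcoxon rank-sum (Mann-Whitney) tests between sex or
age groups on item length/width/volume and per-stomach count/total volume —
reporting both the rank-sum W and Mann-Whitney U, with exact enumeration
p-values for tie-free samples up to n_a·n_b = 400 — plus Kendall's tau-b
(tie-corrected, exact null by enumeration for small tie-free samples),
Pearson correlation and ordinary least squares for morphometrics.

**Sequence divergence.** Uncorrected pairwise p-distance on an aligned COI
FASTA (gap and ambiguity handling via pairwise deletion or IUPAC
compatibility), the conventional conspecificity check for barcoded
specimens.

**Synthetic surveys.** A seeded generator reproducing the survey's
statistical structure — correlated trivariate log-normal morphometrics per
group, zero-truncated negative-binomial stomach counts (mean 7.98, SD 8.42),
a 22-category prey multinomial, and calibrated log-normal prey dimensions
(pooled length 7.53 ± 6.55 mm, width 1.44 ± 1.10 mm) — so every pipeline
stage is testable without field data.

## Worked example

```r
library(gekkodiet)

# Published per-category aggregates bundled with the package
comp <- composition_from_counts(nigriocularis_composition())
format(comp)[1:5, c("category", "F", "pct_F", "N", "pct_N", "pct_V", "iri")]
#>   category           F pct_F     N pct_N pct_V   iri
#> 1 Araneae           20 26.7    146 35.9  10.4  24.3
#> 2 Opiliones         13 17.3     96 23.6   8.86 16.6
#> 3 Achatinidae        5  6.67    23  5.65 19.7  10.7
#> 4 Blattidae          5  6.67    45 11.1   8.59  8.77
#> 5 Scolopendridae     6  8       14  3.44 11.3   7.59

rank_by_iri(comp, top_k = 6, min_F = 2)
#> [1] "Araneae" "Opiliones" "Achatinidae" "Blattidae" "Scolopendridae" "Acrididae"
```

The IRI column reads: spiders contribute 24.33% of the combined
frequency/abundance/volume importance, harvestmen 16.59%, giant land snails
10.67%, and so on; the six labels are the most important recurrent prey
groups (categories found in at least two stomachs).

A full synthetic pipeline run:

```r
ds <- generate_dataset(synthetic_config(seed = 42))
ds
#> <diet_dataset> 51 specimens (15 male, 33 female, 3 subadult), 344 prey items, 18 prey categories

size_summary(ds, "length")
#>   dimension     n  mean    sd   min   max
#> 1 length      344  7.47  6.36   0.6  46.1

compare_groups(ds, grouping = "sex",
               metrics = c("item_length", "count_per_stomach"))[, c("metric", "statistic", "p_value")]
#>   metric            statistic p_value
#> 1 item_length          13992.  0.0185
#> 2 count_per_stomach      404.  0.425
```

Report writers (`report_composition()`, `report_comparisons()`,
`report_synthetic()`, `report_divergence()`) produce deterministic CSV/YAML
output; `inst/scripts/gekkodiet-cli.R` wraps them as
`compose | compare | simulate | seqdiv` subcommands.

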