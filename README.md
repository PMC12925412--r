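# wingscape

Quantitative wing colour-pattern analysis and DNA-barcode networks for
integrative moth taxonomy.

Museum collections hold the evidence for most subspecies decisions, but
wing-colour diagnoses are traditionally made by eye. `wingscape` makes them
quantitative and repeatable: it takes calibrated cone-catch images of
isolated wings (plus specimen metadata) and an aligned mtCOI barcode set,
and asks whether the named taxa are actually separable once sex, specimen
wear, fading with age and geography are accounted for.

## What it computes

**Image wing.** Each cone-catch stack (q_L, q_M, q_S) becomes four analysis
channels — luminance `Lum = (q_L + q_M)/2` and the receptor-noise-limited
(RNL) chromatic coordinates (Weber fraction 0.05, JND units):

    X = (ln q_L − ln q_M) / √(ω_L² + ω_M²)                       (red–green)
    Y = (ln q_S − weighted mean of ln q_L, ln q_M) · scaling     (blue–yellow)
    Sat = √(X² + Y²)

Pattern granularity is measured with a quadrature Gabor bank: six spatial
scales (0.03125–1 cm) × four stripe orientations (0°, 45°, 90°, 135°),
giving per-scale energy `E`, verticality `V = E₉₀ − E₀` and directionality
`D = max E / mean E`, their across-scale sums, and the scale of peak energy.
Together with wing area/length/breadth this yields a 203-column feature
vector per specimen. Features are z-scored, decomposed by PCA (negative-sum
components sign-flipped), and the first components are modelled with

    PC_k ~ sex + taxon + wear + age + latitude + longitude + (1 | collection group)

via `lme4`.

**Molecular wing.** Aligned mtCOI barcodes get Kimura 2-parameter distances
with pairwise deletion (`K = −½ ln((1−2P−Q)√(1−2Q))`), between-group
summaries, gap/ambiguity-masked haplotype collapsing, and a deterministic
median-joining network with mutation-weighted edges and network statistics.

**Synthetic world.** Because the physical specimens are not
redistributable, `generate_dataset()` renders wing images with known,
settable effect magnitudes (male darkness −0.10 and contrast ×0.8, taxon
contrast ×0.85, wear-dependent scale loss 2/10/30%, fading 0.002/yr, pixel
noise 0.01) and `simulate_barcodes()` builds a star-shaped synthetic
alignment. Every downstream stage is tested against these.

## Worked example

```r
library(wingscape)

# simulate a 72-specimen collection and analyse it
bank <- build_gabor_bank(c(0.03125, 0.0625, 0.125), px_per_cm = 64)
ds   <- generate_dataset(72, effect_config(), seed = 1, size_px = c(24, 48))
ft   <- dataset_features(ds$images, bank, ids = ds$meta$id)
res  <- analyze_dataset(ft[-1], ds$meta)

res$pca
#> pca_result: 72 specimens, 3 components kept (53.3/12.6/11.8% of variance)
res$luminance_pc
#> PC3
#>   3
subset(res$lmm, effect %in% c("sexmale", "taxonfennokarelica") & component == "PC3")
#>    component             effect df  estimate        se         t            p
#> 16       PC3            sexmale 63 -2.955359 0.7626178 -3.875282 0.0002563664
#> 17       PC3 taxonfennokarelica 63 -2.952126 1.9882466 -1.484789 0.1425864431
```

The injected sex effect is recovered on the luminance-dominated component
(males darker and less contrasting: negative estimate, p < 0.001), while
the taxon contrast placeholder stays indistinguishable from noise at
n = 72 — the same qualitative picture the method is designed to resolve.

```r
# barcode wing on the synthetic star-shaped alignment
aln <- simulate_barcodes(seed = 1)
gs  <- group_distance_summary(aln)
round(100 * gs$ingroup_range, 2); round(100 * gs$outgroup_range, 2)
#> [1] 0.07 0.53
#> [1] 2.90 3.24
net <- median_joining(collapse_haplotypes(aln))
net
#> haplo_network: 18 haplotypes + 0 median vectors, 17 edges, total length 33
network_stats(net)$n_singletons
#> [1] 14
```

A full run can also be driven from the command line
(`inst/cli/wingscape.R`): subcommands `simulate`, `extract`, `analyze`,
`barcode`, configured by a JSON file; every output is stamped with a
configuration hash and the seed.

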