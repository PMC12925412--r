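---
title: "Methods: wing colour-pattern metrics and barcode networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wing colour-pattern metrics and barcode networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wingscape` implements two analysis wings used in integrative moth taxonomy:
a quantitative wing colour-pattern pipeline (channels → granularity → PCA →
mixed models) and an mtCOI barcode pipeline (K2P distances → haplotypes →
median-joining network). This vignette records the models, the tunable
parameters and the design decisions, so that a green test suite can be read
for what it does and does not establish.

## The image model

The unit of analysis is a *cone-catch image*: a three-channel stack of
modelled photoreceptor quantum catches \(q_L, q_M, q_S\) for an isolated
wing, produced upstream by a chart-calibrated camera model, together with a
binary wing mask and a scale in pixels per centimetre. Catches are
reflectance-scaled and floored at \(10^{-6}\) because the colour model takes
logarithms.

### Channels

Four analysis channels are derived per specimen:

* **Lum** — mean of the longwave and midwave catches, \((q_L + q_M)/2\).
  The upstream camera model names its receptors "X" and "Y"; we read these
  as the L and M channels of the stack (first two planes) and document that
  choice here, since the alternative reading (CIE tristimulus) is not
  available from a three-catch stack.
* **X, Y** — receptor-noise-limited (RNL) chromatic coordinates in the
  standard log-linear form. With \(f_i = \ln q_i\) and Weber fractions
  \(\omega\) (default 0.05 for all three receptors),
  \(X = (f_L - f_M)/\sqrt{\omega_L^2 + \omega_M^2}\) is the red–green
  opponent axis and
  \(Y = \bigl(f_S - \tfrac{\omega_M^2 f_L + \omega_L^2 f_M}{\omega_L^2+\omega_M^2}\bigr)
  \sqrt{\tfrac{\omega_L^2+\omega_M^2}{\omega_L^2\omega_M^2 + \omega_L^2\omega_S^2 + \omega_M^2\omega_S^2}}\)
  the blue–yellow axis, both in just-noticeable-difference units. The model
  is stated by name in the methods literature without equations; we adopt
  the standard trichromatic construction that the common imaging toolboxes
  implement. One Weber fraction is applied to all receptors unless
  configured otherwise.
* **Sat** — the Euclidean distance \(\sqrt{X^2+Y^2}\) from the achromatic
  point.

X, Y and Sat are invariant to scaling all catches by a constant; achromatic
pixels map exactly to the origin. These invariances are enforced by tests.

### Granularity

Pattern "energy" is measured with a quadrature Gabor bank: six spatial
scales (0.03125–1 cm, octave spacing) × four stripe orientations (0°, 45°,
90°, 135°). For scale \(s\) the carrier wavelength is \(\lambda = s \cdot
\text{px/cm}\); the isotropic Gaussian envelope has \(\sigma = 0.5\lambda\)
and the kernel is truncated at \(3\sigma\). The even component is
DC-corrected to exact zero mean. Orientation denotes the *stripe* direction:
a vertical grating excites the 90° filter, which makes "verticality"
\(V = E_{90} - E_{0}\) well defined and testable on gratings. Per scale we
also report the orientation mean \(E\) and the directionality \(D =
\max_\theta E_\theta / \bar E\) (defined as 1 when \(\bar E = 0\), the
isotropy limit); across scales, the sums of \(E\), \(V\), \(D\), the scale
of maximal energy (ties broken toward the smaller scale) and the statistics
at that scale.

**Boundary handling.** Pixels outside the mask are filled with the in-mask
mean before filtering, so the wing silhouette contributes no spurious
energy, and the mask is eroded by a quarter wavelength per scale before
averaging the response magnitude. Eroding by the full kernel half-width
(1.5 wavelengths) would empty every realistic wing mask at the 1 cm scale —
a moth forewing is not three centimetres broad — so mean-fill plus
quarter-wave erosion is the package's reading of "exclude the boundary";
the error contract remains: a mask that vanishes at some scale raises an
error naming that scale.

**Feature schema.** Three wing-size metrics (area; major length and minor
breadth of the minimum-area bounding box, which is exact on rectangles) plus,
per channel: the mask mean, 6 scales × (4 orientation energies, \(E\),
\(V\), \(D\)) and 7 across-scale summaries — 203 columns in total.
Published metric counts for this kind of analysis vary with the breakdown
(plausible schemas give 195–207 columns), so the package fixes and
documents its own schema rather than forcing any particular count. Whether size metrics enter the PCA is
switchable (`include_size`), defaulting to inclusion.

### PCA and mixed models

Features are z-scored (constant columns dropped with a warning) and
decomposed by SVD — correlation PCA, because 203 metrics live on wildly
different scales. A component whose loadings sum to a negative value is
multiplied by −1 (scores and loadings), which changes nothing but the sign
convention; the flip is recorded. "The luminance-dominated PC" is the
retained component with the largest absolute loading on `Lum_mean`.

Each retained component is modelled as

```
PC_k ~ sex + taxon + wear + age + latitude + longitude + (1 | collection_group)
```

with `lme4`, REML, female/*badiata* reference levels, z-scored numeric
covariates, and specimen age measured from the newest collection year in the
dataset. Specimens without subspecific annotation are excluded. Degrees of
freedom use the residual approximation \(n - p\) and the `df_method`
attribute records this; a Satterthwaite correction is not available in the
supported dependency set, and df approximations are in any case not
comparable across software. Singular fits (group variance estimated at
zero) are reported, not raised; with a single collection group the model
falls back to OLS.

## The synthetic specimen world

Museum photographs are not redistributable, so the package generates its
own: a half-ellipse wing (straight trailing edge, apex right) with a basal
field, a darker median fascia and a pale terminal field, textured with a
transverse striation (0.1 cm period) and correlated speckle — real wings
are textured at all scales, and it is this texture whose removal makes wear
measurable. The stated effects, all settable in `effect_config()`:

| effect | default | mechanism |
|---|---|---|
| sex, darkness | −0.10 reflectance | additive shift of L and M catches (males) |
| sex, contrast | ×0.8 | deviation-from-mean scaling (males) |
| taxon, contrast | ×0.85 | deviation scaling (*fennokarelica*) |
| wear, scale loss | 2 / 10 / 30 % | feathered patches attenuated to the mean wing tone |
| fading | 0.002 / yr | relaxation of all channels toward their means |
| noise | sd 0.01 | per-pixel Gaussian on each catch |

Wear patches are cut from a smoothed Gaussian field at an exact pixel
fraction and *feathered*: scale cover thins gradually at patch borders and
the bare-membrane tone equals the wing mean. Two design iterations were
needed here. Hard-edged pale patches *increase* Gabor energy (they cut new
contrast edges into locally flat pattern fields), violating the intended
"wear erodes pattern" monotonicity; mean-tone feathered attenuation
guarantees it, at the cost of the patches not being literally "pale". The
sex/taxon/fading effects are all anchored on the channel means, so the
expected male–female luminance gap equals the configured offset exactly —
that is the oracle the generator tests use.

The default 72-specimen design reproduces a realistic museum series'
composition (40♂/32♀; 29 *badiata* / 41 *fennokarelica* / 2 unannotated;
wear 28/37/7), with collection groups formed from location × campaign-year
and coordinates that confound taxon with geography, as real museum material
does. What the generator does **not** emulate: vein structure, specular
reflection, calibration error, non-stationary illumination, or any real
difference between the taxa — a green recovery test establishes that the
pipeline detects effects of the injected kind and size, not that the
biological conclusions are right.

Magnitudes: the sex effects follow the reported direction (males darker and
less contrasting); the taxon contrast multiplier is a placeholder, since no
quantitative magnitude for the *fennokarelica* pallor has ever been
published. Noise sd 0.01 is ~1% reflectance, typical for calibrated
photography.

## Simulation profiles and budgets

Full-geometry analysis (64 × 128 px wing at 64 px/cm, 6 scales) costs ≈1.5 s
per specimen, dominated by 96 FFT convolutions. Property-based acceptance
needs hundreds of full pipeline replicates, so simulations run on a reduced
profile: 24 × 48 px wing (0.55 × 0.25 cm), the three smallest scales, 119
features. The sex-recovery criterion uses 40 replicates (threshold ≥ 38 =
95%), the type-I criterion 200 replicates against the exact binomial 95%
acceptance region of Binomial(200, 0.05). The reduction changes image and
bank geometry only; `n = 72`, the default and null effect configurations and
the significance thresholds are exactly the stated ones.

## Barcode analyses

* **K2P** with pairwise deletion (only sites where both records carry
  unambiguous A/C/G/T are compared): mixed full-length and ~440 bp fragments
  make complete deletion destructive. Summary values can shift under the
  alternative; the choice is recorded here. The implementation is the
  package's own closed form; the test oracle is `ape::dist.dna(model =
  "K80", pairwise.deletion = TRUE)`.
* **Between-group summaries** are means over all cross-group pairs;
  "ranges" are min/max over between-group means among ingroup annotations,
  and against the outgroup.
* **Haplotypes**: columns carrying a gap or ambiguity in *any* in-scope
  record are masked network-wide (the convention of network software, making
  haplotype counts reproducible), identical records merge. The outgroup
  (default group label `tellensis`) is excluded from networks.
* **Median joining**: the ε-relaxed minimum spanning network on Hamming
  distances, repeatedly augmented with consensus (median) vectors of
  triplets and pruned of unsampled nodes with degree < 3, to a fixpoint. A
  median is added only if it strictly reduces the total network length
  (minimum spanning tree length over the node set). Candidate medians come
  from triplets connectable in the current network first; if none reduces
  the length the search widens to all triplets, then to pairs and triples of
  candidates — medians can be individually neutral (splitting an edge) yet
  jointly shortening, and the widened search escapes those plateaus on small
  inputs. All ties break lexicographically by sequence, so the network is
  independent of input order. On star-like toy instances (each haplotype 1–2
  mutations from a common backbone — the regime the method is built for) the
  result matches exhaustive Steiner-minimal search; on arbitrary dense
  instances no median-joining variant guarantees Steiner minimality (the
  problem is NP-hard), and adversarial toys can defeat the heuristic. This
  boundary is deliberate and tested.

The synthetic barcode generator (`simulate_barcodes()`, explicitly a
synthetic stand-in) encodes a star-shaped world — a dominant central
haplotype, shallow ingroup divergence, a ~2.7% divergent outgroup, four
short-fragment records — to exercise masking, pairwise deletion and network
construction end to end.

## Numerical choices

* Catch floor \(10^{-6}\) (below 16-bit quantisation), log base e.
* FFT convolution on 2-3-5-smooth padded sizes; kernel FFTs cached per bank
  and geometry. The FFT path is tested against direct spatial convolution
  to \(10^{-12}\).
* `maxEnergy` ties toward the smaller scale; D = 1 at zero energy;
  orientation rotation covariance holds exactly for 90° steps.
* PCA sign flips recorded; scores reconstruct the standardized data to
  machine precision at full rank.
* Mixed-model p-values from t with residual df; exact df matching across
  software is explicitly out of scope.
* All randomness flows through per-specimen integer seeds derived from one
  dataset seed (kept below 2³¹).

## Known limitations

* The wing is a half-ellipse with three bands; no venation or fringe.
* Satterthwaite/Kenward–Roger dfs unavailable; p-values at these sample
  sizes are mildly anti-conservative for group-level covariates when group
  variance is positive (the null world estimates it at ~0, where the
  residual approximation is sound).
* Median joining is heuristic beyond the star-like regime, as discussed.
* Alternative metric-count conventions exist; the schema here is fixed
  and documented, not reconciled with them.
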