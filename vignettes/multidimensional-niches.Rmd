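---
title: "Multidimensional isotopic niche modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional isotopic niche modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoniche)
```

## The problem

Hutchinson's niche is an n-dimensional hypervolume, but isotopic niche
studies usually collapse it to the bulk δ¹³C–δ¹⁵N plane. Bulk values
confound baseline variation with trophic enrichment, so sympatric species
can appear to overlap almost completely while actually partitioning
resources along axes the biplot cannot see. Compound-specific amino acid
isotopes recover those axes: source amino acids (phenylalanine, lysine,
glycine) retain baseline δ¹⁵N while trophic amino acids (glutamic acid,
alanine, and others) enrich with each trophic step, and the amino-acid
δ¹³C spectrum separates carbon sources. Adding bulk δ³⁴S distinguishes
benthic/coastal from pelagic feeding independently of trophic level.
`isoniche` operationalises this as four nested niche spaces (1D, 2D, 3D,
5D) and a fully Bayesian niche model on each.

## Building the dimension spaces

PCA is run separately, with centring and unit scaling, on the ten
amino-acid δ¹³C values and the ten δ¹⁵N values of all complete-case
samples. Bulk δ³⁴S is standardized to mean 0, variance 1 (`stdDeltaS`).
The four approaches use fixed axis sets:

| Approach | Axes |
|---|---|
| 1D | PC1-Nss |
| 2D | PC1-Css, PC1-Nss |
| 3D | PC1-Css, PC1-Nss, stdDeltaS |
| 5D | PC1-Css, PC1-Nss, stdDeltaS, PC2-Css, PC2-Nss |

PC1 of each element is a baseline/source proxy (it correlates strongly
with the corresponding bulk value — `validate_proxies()` reports these
correlations together with trophic indices such as Glx−Phe and the
parametrized trophic position `TP = (Glx − Phe − β)/TDF + 1`, defaults
β = 3.4 ‰ and TDF = 7.6 ‰, both configurable since published calibrations
vary by tissue and taxon).

Three numerical conventions are pinned for reproducibility:

- **Component orientation.** A PCA component's sign is arbitrary. We fix
  each component so its largest-|loading| variable has a positive loading
  (first index wins ties). This makes loadings invariant to row order and
  positive column rescaling; correlation reports carry orientation
  metadata so externally published signed correlations can be matched
  after flipping.
- **Loading "contributions".** Per-variable contributions to a component
  are squared loadings × 100, summing to 100 per component — the usual
  way loading percentages are reported for scaled PCA.
- **Missing data.** Complete-case only (all 20 amino-acid values plus
  bulk δ³⁴S present); no imputation. Bulk δ¹³C/δ¹⁵N may be missing
  because they are validation proxies, not model axes.

No Suess-effect (anthropogenic δ¹³C baseline drift) correction is applied;
time-dependent baseline corrections require external regional tables and
published comparisons show corrected and uncorrected PC1 axes correlate
near-perfectly. This is a documented limitation for strongly
time-structured carbon data.

## The niche model

Per group, coordinates are modelled as i.i.d. N(μ, Σ) with the
non-informative prior π(μ, Σ) ∝ |Σ|^−(d+1)/2, giving the conjugate
posterior Σ|X ~ IW(S, n−1), μ|Σ,X ~ N(x̄, Σ/n) (S = centred sum of
squares). Sampling draws Σ⁻¹ from a Wishart via `stats::rWishart`
(Bartlett decomposition) and inverts by Cholesky; μ follows from another
Cholesky. This posterior is proper only for n ≥ d + 2; smaller groups are
reported as *not estimable* rather than silently regularised, because a
ridge prior would change the method (and sample-size insensitivity is one
of its selling points).

- **Niche size** at probability α is the volume of the α-ellipsoid,
  V = [2π^{d/2}/(d Γ(d/2))] · χ²_{d,α}^{d/2} · |Σ|^{1/2}, applied per
  posterior draw. Units are axis-unitsᵈ, so sizes are comparable across
  species within an approach but not across approaches. The determinant
  makes high-dimensional sizes sensitive to small eigenvalues; values for
  d > 3 should be compared, not interpreted absolutely.
- **Directional overlap** of A onto B: per paired posterior draw k,
  the probability that X ~ N(μ_{A,k}, Σ_{A,k}) lands in B's α-ellipsoid,
  estimated with `n_mc` Monte-Carlo points (default 1,000 — at that count
  the per-draw binomial error is ≤ 1.6 percentage points and is averaged
  away over draws). Defaults: α = 0.95, i.e. "the 95% of the data" region.
- **Layman metrics** are computed on posterior *centroid* draws, not raw
  points, so community structure inherits posterior uncertainty: per draw,
  CD (mean distance of species centroids to their unweighted mean — the
  community centroid is unweighted by sample size, following the original
  convention), NND (mean nearest-neighbour distance), SDNND (population-SD
  of the nearest distances; the divide-by-S convention is pinned since
  both appear in the literature), and per-axis ranges. CD/NND/SDNND are
  translation- and rotation-invariant; ranges are axis-dependent by
  design. For two species NND = 2·CD and SDNND = 0 identically.

## Comparing posteriors

Two groups are compared by:

- **Bhattacharyya coefficients** Σᵢ√(pᵢqᵢ) between the two samples'
  histograms on `n_bins` equal-width bins spanning their union range
  (default 100; for smooth posteriors the value drifts by under 0.03
  between 50 and 200 bins, which a test asserts). Computed per marginal
  centroid axis and between niche-size posteriors. Shared binning makes
  the coefficient exactly symmetric. If every value in both samples is
  identical the union range is degenerate and the coefficient is 1 by
  convention.
- **A conservative centroid-difference probability.** Each group's K
  centroid draws are shuffled (seeded) and split into equal test and null
  halves; p is the fraction of paired indices where the between-group
  distance exceeds the *sum* of both within-group test–null distances:
  p = mean(‖μ_At − μ_Bt‖ − ‖μ_At − μ_An‖ − ‖μ_Bt − μ_Bn‖ > 0).
  Subtracting both within-group terms is what makes the estimate
  conservative. The symmetric form (each group contributes its own
  test–null distance) is used; it is the only internally consistent
  reading of the construction. Direct simulation shows the null level is
  dimension-dependent: ≈ 0.17 in 1D, ≈ 0.08 in 2D, ≈ 0.01 in 5D, so the
  statistic should be used in 2D and above, which is where niche
  comparisons are made in practice. The reported `centroid_distance` is
  the mean Euclidean distance between paired centroid draws — a posterior
  summary, deliberately simple since several defensible definitions
  exist.

## Temporal comparison

`temporal_analysis()` compares one species between two collection-year
periods (defaults 1970–1989 vs 1990–2006; year 1989 is period 1, 1990 is
period 2). The dimension spaces are built **once** on the full
complete-case dataset, so both periods share the PCA basis and sulphur
standardization — refitting PCA per period would make centroid shifts
unidentifiable. Each period then gets its own posterior, niche-size
summary, both directional overlaps and the comparison statistics. An
approach where either period has n < d + 2 is flagged not estimable while
the others proceed.

## The synthetic-data generator

Real datasets of this kind are small (tens of samples across several
species) and unpublished ones are not redistributable, so the package
ships a generator with *planted truth* so every stage is testable. Each
species occupies a multivariate normal region on five latent axes —
carbon source, secondary carbon, nitrogen baseline, trophic nitrogen,
sulphur — and a fixed loading map projects latent positions onto the 21
tracers with additive Gaussian noise (default residual SD 0.5 ‰, a
realistic analytical-plus-biological spread). Bulk δ¹³C/δ¹⁵N are weighted
amino-acid means plus noise, planting the proxy correlations that
`validate_proxies()` checks. Collection years are uniform over each
species' range; the optional period effect (centroid shift, covariance
scale) applies to samples at or after the period cut (default 1990), while
period *assignment* happens at analysis time from the year column.

`default_community()` packages a five-species, 63-sample configuration
echoing a coastal seabird assemblage: a storm-petrel analogue far from all
others (baseline nitrogen and sulphur), two alcid analogues separated only
on carbon source and sulphur, and two cormorant analogues close on all
axes. Within-species latent SD is 0.5, so planted separations of 2 latent
units are 4 SD (strong) and 0.5 units are 1 SD (weak). Per-species counts
(18/16/11/9/9) keep every species estimable in 5D while remaining
realistically unbalanced; real allocations vary, so they are configurable.

What the generator does *not* emulate: isotope fractionation chemistry,
diet-to-tissue transfer, non-normal niche shapes, temporal autocorrelation
within periods, measurement-batch effects, and correlated (non-diagonal)
tracer noise. Passing tests therefore demonstrate the *statistical
machinery* is correct under the model's own assumptions — multivariate
normality above all — not that real niches are normal.

## Numerical choices and degenerate inputs

- Quantiles use the linear-interpolation estimator (R type 7); posterior
  modes use a Gaussian-kernel density with Silverman's bandwidth on a
  512-point grid. A constant draw vector returns itself as mode.
- Niche-size summaries follow the mode/5%/95% convention; community
  metrics the mean/2.5%/97.5% convention (both also available).
- All stochastic stages take explicit seeds; orchestration functions draw
  per-stage sub-seeds from one master seed, so whole pipelines reproduce
  byte-identically (asserted by tests).
- Zero-variance PCA columns, non-positive-definite covariances, axis
  mismatches, empty filters and too-small groups all raise immediate,
  named errors.

Validation relies on independent oracles: closed-form ellipsoid volumes
against rejection-sampling hit rates; overlap against normal-CDF and
numeric-integration results in 1D/2D and against the exact self-overlap
value α; the Bhattacharyya coefficient against exp(−Δ²/8) for
equal-variance normals; Layman metrics against a brute-force O(S²)
implementation and plane geometry; the posterior against its analytic
moments (E[Σ] = S/(n−d−2)) and against planted truths at n = 5,000. Test
problem sizes (K between 300 and 10,000, n_mc 150–10,000) are chosen so
the full suite runs in about a minute while keeping Monte-Carlo error well
inside each tolerance; the reproduction script uses K = 5,000 and
n_mc = 1,000.

## Known limitations

- The multivariate-normal niche is unimodal and elliptical; multimodal or
  skewed tracer distributions violate it silently.
- Hypervolume sizes in high dimensions are driven by |Σ|^{1/2} and react
  strongly to weakly informed axes; treat 5D sizes as ordinal.
- The Bhattacharyya coefficient depends mildly on binning; it is a
  descriptive overlap measure, not a calibrated test.
- The centroid-difference probability's null level varies with dimension
  (see above); it is conservative, not size-controlled.
- Nearest-neighbour metrics (NND/SDNND) on posterior centroid draws shrink
  as groups' posteriors concentrate; they measure centroid configuration,
  not data-cloud packing.
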