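---
title: "Morphometric teratogen screening with micropatterned hPSC colonies: models and methods"
author: "teratoMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric teratogen screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teratoMorph)
```

# The assay

Human pluripotent stem cell (hPSC) colonies grown on geometrically confined
adhesive islands ("micropatterns") differentiate, under mesoendoderm
induction, into a spatially organized pattern: by day 3 the
BRACHYURY-positive (T+) mesoendoderm cells form an annular ring displaced
roughly 200 um inward from the colony edge. Because the ring's formation
integrates differentiation *and* collective cell migration, teratogenic
compounds disturb it dose-dependently — widening the ring, pushing it toward
the colony centre, or fragmenting it — at concentrations below their
cytotoxic threshold, whereas non-teratogenic compounds leave it intact up to
cytotoxic doses.

The quantitative pipeline implemented here turns that observation into a
classification rule:

1. image each colony (one single-channel fluorescence image per colony) at
   four dose groups — control, low, medium, high;
2. segment colony and T+ region, extract 19 morphometric features per colony;
3. compress the features into morphologic clusters and compute per-colony
   cluster readouts;
4. per cluster, test for dose effects (one-way ANOVA), then locate the
   **disruption concentration (DC)** — the lowest dose whose vs-control
   post-hoc contrast is significant under Bonferroni correction;
5. estimate the compound's **IC25** on embryonic cells from an 8-point
   viability curve, and call the compound **teratogenic iff DC < IC25**.

Because no imaging data are deposited for this assay, the package ships a
first-class synthetic-data generator that emulates the day-3 phenotype and
its dose-dependent disruption, with exact ground-truth masks. Every
downstream stage is validated against that ground truth and against
closed-form oracles.

# The synthetic colony model

`generateColonyImage()` renders a circular colony (default diameter 1000 um,
the screening micropattern, area $\pi \cdot 500^2 \approx 7.85\times10^5$
um^2) at 2 um/px on a dark background, with three intensity levels:
background 20 a.u., T- colony carpet 60 a.u., T+ ring 200 a.u. (16-bit
scale), plus additive zero-mean Gaussian noise clipped to $[0, 65535]$.
The T+ ring occupies radii 250-350 um, chosen so that the mean T+-to-outline
distance for a uniform annulus,

$$ R - \frac{2(b^3 - a^3)}{3(b^2 - a^2)} = 500 - 302.8 \approx 197\ \mathrm{um}, $$

reproduces the observed ~200 um inward displacement. Disruption at level
$d \in [0,1]$ follows the thalidomide-like phenotype: half-width
$h = h_0 (1 + w\,d)$ (default $w = 1$: the ring doubles in width at full
disruption) and centre-line radius $\rho_c = \rho_0 - \kappa d$ (default
$\kappa = 150$ um), with optional fragmentation of the ring into arcs.
Parameter combinations that would push the ring past the centroid or the
colony edge are rejected with an error naming the violated bound.

Replicate-to-replicate variation in `generateDoseSeries()` is geometric
jitter — centroid offset uniform in ±10 px, all radii scaled by a factor
uniform in ±5% — plus the pixel noise. These defaults are the package's
choice of a realistic within-group variance; the number of replicate
colonies per group defaults to n = 10, also a package choice (the assay's
replicate count per group is not fixed by its published description). The
group-to-disruption map defaults to (0, 1/3, 2/3, 1).

The generator deliberately does **not** emulate photorealistic cell texture,
single-cell migration, uneven illumination, or 3-D ridge structure. Passing
tests therefore demonstrate the pipeline's correctness and statistical
calibration on images with the assumed structure (annular signal, Gaussian
noise, jittered geometry), not robustness to staining artefacts or
illumination gradients in real micrographs — such images should be
flat-field corrected upstream.

Noise is additive Gaussian rather than Poisson: it is the simplest model
that exercises Otsu-threshold robustness, and at the intensities involved
the distinction is immaterial for thresholding behaviour.

# Segmentation

**Colony detection.** The colony is identified by intensity difference from
the background. Because a stained colony has *three* intensity populations
(background, T- carpet, bright T+ ring), a single two-class Otsu split of
the full-image histogram lands between carpet and ring — it separates the
brightest population, not the colony. `detectColony()` therefore applies an
exhaustive two-threshold (3-class) Otsu to the full-image 256-bin histogram
and keeps everything above the *lowest* threshold; when the histogram
cannot support three classes it falls back to the plain two-class split.
The colony mask is the largest connected component with holes filled; the
centroid is the unweighted mean of mask pixel coordinates; the outline is
the 8-connected boundary. Images whose largest component is smaller than
`minArea` (default 1e4 px) raise "no colony found".

**T+/T- split.** `segmentTpos()` applies the classical 2-class Otsu to
colony pixels only. Conventions are fixed for bit-reproducibility:
histograms use 256 equal-width bins over the observed range, foreground is
*strictly greater* than the threshold, and objective ties break toward the
smallest threshold. T+ components below `minComponentArea` (default 20 px)
are removed as speckle. An empty T+ mask is flagged (`noTpos`), not thrown:
complete absence of a mesoendoderm pattern is a biologically meaningful,
reportable outcome. The implementation is property-tested for exact
equality with a brute-force search over all candidate thresholds.

# The 19-feature roster

The published description of the assay names the feature families — T+
area, relative distance to colony centroid and outline, and the standard
deviation, coefficient of variation, skewness, kurtosis, entropy and energy
of the T+ distribution — without an exhaustive list. The roster implemented
here (`morphFeatureNames()`) concretizes those families into 19 fixed
attributes: area and area fraction; mean distances to centroid and outline
(um); ten statistics of the normalized radial position
$\rho = d(\text{pixel}, \text{centroid})/R$ with $R = \sqrt{A_{colony}/\pi}$
(mean, median, sd, CV, skewness, Fisher excess kurtosis, entropy, energy,
IQR, and the 5th/95th percentiles as inner/outer edges); intensity sd,
entropy and energy of the T+ pixels; and the T+ connected-component count
(fragmentation). Both absolute (um) and normalized distances are provided
because the original description does not say which normalization was used.

Numerical conventions: radial entropy/energy use a fixed 64-bin histogram
of $\rho$ on $[0, 1.2]$ (values clamped; entropy in bits, so the range is
$[0, 6]$ bits and energy $[1/64, 1]$); intensity entropy/energy use 256
bins over the observed T+ intensity range (a single-valued region gives
entropy 0, energy 1 by convention); kurtosis is Fisher excess so a normal
radial profile scores 0; distances to the outline are Euclidean distances
to the nearest outline *pixel*, computed by a distance map, which
undershoots the continuous boundary by under a pixel — well inside the 1%
agreement with the closed-form annulus integrals that the tests require.
Normalizing $\rho$ by the equivalent radius $R$ (rather than per-direction
boundary distance) keeps the definition meaningful for any colony shape.

# Feature filtering and morphologic clustering

Four of the 19 attributes showed only random trends in the original screen
and were excluded before clustering; their identity was not published, so
exclusion is configuration here. `filterExtraneous()` supports an explicit
drop list and an `auto` mode that operationalizes "random trend" as
*correlating with nothing*: a feature is dropped when its maximum absolute
Pearson correlation with every other feature stays below 0.4. The
threshold matters only loosely; latent-driven features correlate at
|r| > 0.8 in simulation while independent columns stay near 0.

`clusterFeatures()` clusters the retained features on the **signed**
correlation distance $d = 1 - r$ with complete linkage, cut at $k = 7$
clusters (the screen's cluster count; configurable). The signed distance —
not $1 - |r|$ — is deliberate: cluster readouts average z-scored member
features, which is only meaningful when members co-vary in the same
direction; anti-correlated features would cancel. Likewise z-scoring before
averaging is what makes "feature average values" well-defined across
features with incompatible units. Zero-variance features are excluded with
a warning (their correlation is undefined); ties and labels are
deterministic (cluster ids follow first appearance in the canonical feature
order). No automatic selection of $k$ is attempted.

# Dose-response statistics and the DC

Per cluster, a classical fixed-effects one-way ANOVA compares the four
groups; clusters are screened at the family alpha (0.05) without
multiplicity adjustment across clusters, faithful to the assay's practice
of inspecting each cluster's dose-response plot. Within each significant
cluster all $\binom{4}{2} = 6$ pairwise two-sided unpaired t-tests are
computed (pooled variance by default — "unpaired t-test" with no Welch
qualifier — with Welch available by argument), and a dose is disruptive
when its **vs-control** contrast has $p < 0.05/6 = 0.0083$. The divisor is
fixed at 6 by the design regardless of how many contrasts end up being
inspected. The DC is the lowest disruptive concentration over all
significant clusters; if no cluster passes ANOVA, DC is "none" and the
compound is immediately non-teratogenic. Degenerate post-hoc inputs
(constant readouts) yield NA p-values, which count as not significant
rather than propagating an error.

Simulation tests confirm calibration: under the null (all groups at
disruption 0) the per-cluster ANOVA p-values reject at ~5%
(within [0.02, 0.09] over 200 simulated series), and in the
medium-dose-disruption scenario the DC lands on the medium concentration in
at least 90% of seeds.

# Cytotoxicity and the IC25

`fitIC25()` fits the four-parameter logistic
$v(c) = b + (t - b)/(1 + (c/\mathrm{ic50})^h)$ by Levenberg-Marquardt least
squares with fixed data-driven starting values (top from the vehicle mean,
bottom from the smallest dose mean, ic50 at the dose nearest half-range,
hill 1), so the fit is deterministic. The IC25 is defined as 25% inhibition
relative to the *fitted vehicle level*: the analytic solution of
$v(c) = 0.75\,t$,

$$ \mathrm{IC}_{25} = \mathrm{ic50}\left(\frac{t - b}{0.75\,t - b} - 1\right)^{1/h}. $$

When the fitted curve never reaches $0.75\,t$ within the tested range the
IC25 is right-censored and carried as the explicit bound "> cMax" — never
silently converted to a number. If the least-squares fit fails, the
estimate falls back to direct curve reading (linear interpolation of group
mean viability against log concentration), mirroring manual curve reading.
One algebraic caveat the tests encode: $\mathrm{IC}_{25} < \mathrm{ic50}$
holds exactly when $b < t/2$ — for very high floors the 25%-inhibition
point can sit beyond the midpoint, so the property is asserted under that
condition.

# The classification rule

`callTeratogenicity()` applies the strict rule: teratogenic iff a DC exists
and DC < IC25(embryonic), where a censored IC25 "> x" is compared through
its lower bound x (conservative: DC < x implies DC < IC25). DC at or above
the IC25 indicates disruption attributable to embryonic cytotoxicity, hence
non-teratogenic; equality is non-teratogenic because the rule is strict.
Units must match exactly — there is no silent unit conversion. The five
canonical screening fixtures (thalidomide, retinoic acid, D-penicillamine,
valproic acid as teratogens; penicillin G as the negative control) are
reproduced from their printed DC/IC25 values in the test suite; this
validates the decision rule, not the upstream measurements, whose raw
images are not publicly available.

# Kymographs

`buildKymograph()` samples each frame of a time-lapse stack at unit-spaced
points along a polyline (endpoints included, so a line of arc length $L$ px
yields $\mathrm{round}(L) + 1$ columns — sampling positions symmetric under
polyline reversal, making reversal an exact column flip) by bilinear
interpolation, with nearest-neighbour available for bit-exact work. For an
odd line width $w > 1$ the profile is averaged over $w$ perpendicular
offsets, suppressing uncorrelated noise by $\approx 1/\sqrt{w}$. The
default frame interval is 20 min. The average-intensity Z-projection used
to draw the region of interest is exposed as the helper `zProjection()`;
no automatic front tracking is attempted beyond the midpoint-crossing edge
locator used for validation.

# Validation problem sizes

The simulation suites run at a coarser pixel size (8 um/px, images
~150 x 150 px) than the default imaging resolution so that multi-seed loops
stay quick; the scientific geometry is unchanged. Sizes used: 200 series of
4 x 4 colonies for the ANOVA null calibration; 50 series of 4 x 10 colonies
for DC recovery; 100 viability tables for IC25 recovery; 8 seeds per
end-to-end scenario (teratogenic / inert / cytotoxic-only). Single-image
oracle checks (closed-form annulus integrals, the ~200 um displacement) run
at the full default resolution.

# Known limitations

* Colony detection assumes one colony per image and no illumination
  gradient; heavily vignetted or multi-colony fields are out of scope.
* On an unstained *and* noisy colony the 3-class histogram split can bite
  into the background, slightly inflating the colony mask; with the
  stained images the assay analyses (or noise-free fixtures) detection is
  exact.
* The identities of the original screen's four dropped features and of the
  features inside its seven clusters are unpublished; the auto-drop rule
  and the roster here reproduce the cluster *semantics* (dispersion,
  position, area, kurtosis, energy readouts) rather than an exact published
  partition.
* No batch/mixed-effects modelling, no trend tests, and no FDR across
  compounds; concentrations are compared within one compound at a time.
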