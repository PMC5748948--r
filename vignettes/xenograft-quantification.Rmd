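---
title: "Quantifying xenografted tumor-cell proliferation in zebrafish embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying xenografted tumor-cell proliferation in zebrafish embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoquant)
```

## The assay and the model

Zebrafish embryo xenografts read tumor growth out of two fluorescence
micrographs per embryo: one at 0 hours post injection (hpi), one at 72 hpi.
The GFP-labeled tumor mass sits in the yolk, which itself autofluoresces —
dimly, broadly, and with fish-to-fish variability. The quantity of interest
is the proliferation index

$$PI = \frac{nGFP_{72}\cdot GMV_{72}}{nGFP_{0}\cdot GMV_{0}},$$

where $nGFP$ is the count of pixels strictly brighter than a threshold and
$GMV$ the mean intensity of those pixels. $nGFP \cdot GMV$ is simply the
summed above-threshold intensity — a proxy for total fluorescent tumor
burden — so the PI is the 72 hpi / 0 hpi burden ratio: above 1 the graft
proliferated, below 1 it died back, exactly 1 it is stable.

The model's central assumption is that tumor signal and autofluorescence are
separable **by intensity alone**: autofluorescent pixels occupy the dim end
of the 0–255 scale, tumor pixels the bright end, and a single per-image
threshold can sit between them. No spatial segmentation is attempted.

## Automatic threshold selection

`compute_sweep()` counts $nGFP(t)$ for every integer threshold
$t = 0..t_{max}$ (default 50). As $t$ rises, the curve falls steeply while
autofluorescent pixels are being discarded, then flattens once only the
tumor mass remains. `select_threshold()` formalizes "flattens": with the
step decay $d(t) = (nGFP(t-1) - nGFP(t))/nGFP(0)$, the threshold is the
smallest $t$ such that $d(t') < \text{tolerance}$ (default 0.10) for *all*
$t' \in [t, t_{max}]$.

Requiring stability *from $t$ onward*, rather than stopping at the first
quiet step, is a deliberate design choice: an autofluorescence intensity
distribution with a shoulder — many pixels concentrated near one plateau
value $a$ — produces near-zero decay below $a$, one large step at $a$, and
nothing after. A first-quiet-step rule would stop below the shoulder and
count the entire yolk as tumor; the from-here-onward rule lands at $a + 1$.

Two edge cases are flagged, never silently absorbed:

* **flat curve** — no step ever exceeded the tolerance; the embryo shows no
  autofluorescence shoulder at all. The threshold is fixed at 1 (removing
  zero-valued background, keeping all signal) and `flat_curve = TRUE` is
  recorded so the correction is auditable.
* **saturated** — the final step still exceeded the tolerance; the curve
  never stabilized inside the sweep. The threshold is pinned at $t_{max}$,
  `saturated = TRUE` is set and a warning raised, because the measurement
  may still contain autofluorescence.

The two timepoints select thresholds independently and the **maximum** is
applied to both images before measuring: comparing areas over time is only
meaningful at a single shared threshold.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `t_max` | 50 | intensity (0–255) | sweep extent; yolk autofluorescence lives well below this |
| `tolerance` | 0.10 | fraction of $nGFP(0)$ | decay step below which the curve counts as stable |
| `epsilon` | 1e-9 | PI units | half-width of the "stable" band around PI = 1; the classification is effectively a strict trichotomy |
| `r_min`, `r_max` | — | px | Hough radius bounds, from the known approximate cell size |
| `edge_strength` | 0.5 | fraction of max gradient | relative edge cutoff; relative so counts are invariant to exposure scaling |
| `min_separation` | `r_min` | px | non-maximum suppression distance; touching cells below it merge into one detection |
| `accum_threshold` | 0.3 | fraction of $2\pi r$ | fraction of a full rim that must vote for a detection |
| `k` | 1.5 | IQR multiples | Tukey fence multiplier for outlier removal |
| `alpha` | 0.05 / 0.01 | — | significance level of the group comparison |

## Numerical choices

* **Comparator.** Pixels are counted with a strict `> t`, so $t = 0$ ("no
  threshold") counts every positive pixel while excluding true-black
  background. Whether the boundary pixel belongs above or below is an
  arbitrary convention; it is stated once and used everywhere.
* **Scale.** All thresholds live on the 0–255 scale. 16-bit inputs are
  linearly rescaled by 255/65535 — never percentile-stretched, which would
  silently move every threshold. After rescaling, values are rounded to six
  decimals so 8-bit sources are bit-exact integers again and the strict
  comparator cannot be tripped by floating-point fuzz.
* **Integer thresholds.** The sweep is integer-valued by construction; the
  selected threshold is therefore an integer in $[1, t_{max}]$.
* **Blank images.** A blank 72 hpi image is a legal observation (total
  death, PI = 0); a blank 0 hpi image zeroes the PI denominator and raises
  an undefined-baseline error — such an embryo would have been discarded as
  incorrectly injected, and the batch driver routes it to the discard
  report rather than dropping it.

## The phantom generator

`render_embryo()` draws the world the pipeline assumes: an elliptical yolk
with a constant autofluorescence plateau $a$ in its core (fraction
`plateau_frac` of the elliptical radius) falling linearly to 0 at the
ellipse edge, plus one or more uniform bright disks for the tumor mass,
plus optional additive Gaussian noise clipped to $[0, 255]$. The
plateau-plus-falloff profile reproduces the steep-then-flat sweep decay of
real embryos while keeping closed-form ground truth; the plateau is what
gives the selection rule a non-trivial shoulder to clear. Ground truth
(mass area and mean intensity, autofluorescence area, cell centers for
droplet phantoms) is computed from the noise-free geometry, and rendering
is bit-reproducible given the seed.

What the phantoms deliberately do **not** emulate: embryo morphology, the
optics (no point-spread function), Poisson photon statistics, illumination
gradients, or registration error between timepoints. A green test
establishes that the algorithms are implemented correctly on the stated
world — not that the assay's biological assumptions hold on real fish.

### The noisy regime, analyzed

With noise $\sigma = 3$, the plateau step at $t = a$ is smeared over
roughly $\pm 2\sigma$ integer bins, so its largest single-step decay is
about $0.13 \times$ the plateau's share of $nGFP(0)$ — for realistic
geometries below the 10% tolerance. The selection then settles at the
*noise shoulder* ($t \approx 2\sigma$, where the clipped-Gaussian
background tail stops shedding 10% steps) rather than above $a$. PI
recovery in noise therefore requires the residual contamination energy
above that shoulder — background false positives plus autofluorescence —
to be small against the mass term $nGFP \cdot GMV$. The PI-recovery test
family is chosen once from that analysis: a small, dim yolk (plateau 4,
semi-axes 14×18 px) beside a large bright mass (radius 26 px, intensity
190) in a 160×160 frame keeps contamination below ~2% of the mass energy,
which bounds the PI error by ~6% even at an area×intensity product of 0.25.
Noise-free, the same family selects a threshold above the autofluorescence
and recovers the ground-truth PI exactly. The asymmetry is intrinsic to
intensity thresholding, not an implementation artifact: autofluorescence
overlapping the noise band is indistinguishable from noise.

## Cell counting

The droplet counter is a gradient-vote circular Hough transform: Sobel
gradients; edge pixels at $\ge$ `edge_strength` of the maximum gradient
magnitude; one vote per edge pixel per integer radius, cast $r$ pixels
along the gradient direction (at a bright disk's rim the gradient points at
the center); per-radius accumulators 3×3 box-summed; per-pixel best radius;
peaks gated at `accum_threshold` $\times 2\pi r$ votes; greedy non-maximum
suppression at `min_separation` on centroid-refined centers. The
gradient-vote variant was chosen over full-circle voting for its
accumulator sharpness and linear cost in edge pixels; radii are swept at
integer steps because the cells' approximate size is known and the
accumulator cost scales with the radius count. Clumps merging into single
detections under crowding are accepted by design — at high injection loads
(400–500 cells) only an estimate is required, and the suite holds the
estimate to within 15% there while requiring exactness for well-separated
fields of up to 50 cells.

## Cohort statistics

* **Survival.** Pooled percentage $100\sum a_i / \sum n_i$; the reported
  spread is the sample SD ($n-1$) of the per-replicate proportions on the
  0–1 scale — the convention that uniquely reproduces all three published
  cohort rows this layer is validated against.
* **Outliers.** Tukey fences at $k = 1.5$ IQR with *inclusive* quartiles
  (linear interpolation at $(n-1)p + 1$; R's `type = 7`, identical to
  spreadsheet `QUARTILE`), matching the spreadsheet screens used in
  practice. The fence multiplier and quartile method are conventions chosen
  here; the source workflow names only "IQR".
* **Comparison.** Homoscedasticity is assessed with Levene's test on
  absolute deviations from group medians (Brown–Forsythe variant) at 0.05 —
  robust to the non-normality that motivates the non-parametric fallback in
  the first place. Homoscedastic pairs get a pooled-variance Student's
  t-test; heteroscedastic pairs get Kruskal–Wallis, the standard
  "one-factor ANOVA for non-parametric data", which with two groups is a
  tie-corrected rank-sum test. The specific variance test is a choice made
  here (the source workflow names the property, not the test). Groups whose
  absolute deviations are all identical (e.g. two constant groups) are
  treated as homoscedastic with an undefined Levene statistic.
* **No multiplicity correction** is applied across pairwise comparisons,
  matching the source workflow's practice; the comparison table exposes raw
  p-values so a user can apply one.

## Known limitations

* Intensity-only separation fails when tumor signal is as dim as the
  autofluorescence, or when autofluorescence exceeds `t_max`.
* The PI conflates area growth with intensity change; expression-level
  drift in GFP between 0 and 72 hpi reads as proliferation or death.
* No registration: the two timepoints are measured independently, which is
  correct for the ratio but means per-pixel maps are not comparable.
* The counter's radius estimate is quantized to integer steps and its
  detections merge under heavy overlap; counts at 400–500 cells are
  estimates, not enumerations.
* 3-D quantification (confocal stacks) is out of scope; all measures are
  2-D projections.
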