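---
title: "Extended correlation functions for multiplex imaging point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended correlation functions for multiplex imaging point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 5)
library(mxpcf)
```

## The setting

Multiplex immunohistochemistry assigns each segmented cell a centroid
(x, y, in micrometres), a categorical label (cell type) and, often,
continuous measurements such as mean stain intensity. `mxpcf` treats
such a cell table as a *marked point pattern* on a rectangular region
of interest and provides a family of statistics that all answer
variations of one question: do cells of given kinds occur near each
other more or less often than chance?

"Chance" throughout is complete spatial randomness (CSR): points placed
independently and uniformly, with intensity matched to the observed
per-type counts. Every statistic in the package is a ratio calibrated
to equal 1 under CSR, so values above 1 read as attraction/clustering
and values below 1 as exclusion, at a given length scale.

## Pair correlation function and cross-PCF

Counts of pairs are collected in annuli: a sequence of inner radii
$r_k$ starting at $r_\mathrm{start}$, spaced $\Delta r$ apart, each
annulus of width $\varepsilon$ (defaults $r_\mathrm{start}=0$,
$\Delta r = \varepsilon = 10$ µm up to 300 µm; with
$\Delta r = \varepsilon$ the annuli tile the range without overlap).
For points of one type $C$,

$$ g(r) \;=\; \frac{|D|}{N_C (N_C - 1)} \sum_{i \neq j}
   \frac{\mathbf{1}\!\left(d_{ij} \in [r, r+\varepsilon)\right)}{A_r(x_i)}, $$

where $|D|$ is the domain area and $A_r(x_i)$ is the area of the
annulus centred at $x_i$ that lies **inside** the rectangle. Dividing
each point's contribution by its own clipped annulus area is the edge
correction: a point near the boundary simply has less area in which
neighbours could fall, and the ratio remains unbiased under CSR. The
clipped areas are computed in closed form (circular-segment
decomposition against the four half-planes of the rectangle), so the
statistic is exact and deterministic — no Monte-Carlo edge correction.

The cross-PCF $g_{AB}(r)$ replaces the single type by an ordered pair:
annuli are centred on the $A$ points and $B$ points are counted, with
normalisation $N_A N_B$. It is symmetric in its marks except through
the edge correction (the clipped areas are evaluated at the $A$
points); when the two marks coincide, self-pairs are excluded and the
normalisation reverts to $N_C(N_C-1)$, which makes `cross_pcf(p, C, C)`
identical to `pcf(p, C)`.

Self-pairs are excluded with the $N_C(N_C-1)$ normalisation because
that combination keeps the CSR expectation exactly 1 at every radius
and preserves the reduction identity above.

Significance is assessed by simulation: `csr_envelope()` draws patterns
with the observed per-type counts, evaluates the statistic on each and
returns pointwise quantiles (default 2.5%/97.5%). The envelope is
pointwise — with 30 radius bins, an entirely CSR curve will still poke
out somewhere about one time in three — so excursions should be read
per-radius, not as a global test.

```{r pcf-example}
p <- generate_dataset_1(seed = 1)
g <- radial_grid(r_max = 150)
plot(cross_pcf(p, "C1", "C2", g), main = "dataset I cross-PCF")
```

## Topographical correlation maps

The PCF tells *whether* two types correlate, not *where*. The TCM
decomposes the correlation spatially. Each cell $i$ of type $A$ gets a
local statistic

$$ \Gamma_i \;=\; \frac{n_B(i, r) / A_r(x_i)}{N_B / |D|}, $$

the edge-corrected density of $B$ cells within distance $r$ of that
cell, relative to the global $B$ density — its personal contribution to
the cumulative (K-function-type) cross-correlation up to radius $r$.

$\Gamma$ is a ratio, so its scale is lopsided: 3-fold enrichment gives
3, 3-fold depletion gives 1/3. The linearised mark symmetrises the two
directions:

$$ \Gamma'_i = \begin{cases}
  \min(\Gamma_i, \alpha) - 1, & \Gamma_i \ge 1 \\
  1 - \min(1/\Gamma_i, \alpha), & 0 < \Gamma_i < 1 \\
  -(\alpha - 1), & \Gamma_i = 0
\end{cases} $$

so that $\Gamma' = 0$ at the CSR level, a $k$-fold enrichment and a
$k$-fold depletion map to $\pm(k-1)$, and both directions saturate at
$\pm(\alpha - 1)$. The cap $\alpha$ (default 5) is the largest fold
change the map resolves; without it a single cell pair at tiny
separation would dominate every map. This piecewise form was chosen as
the simplest map satisfying those three contracts (CSR fixed point,
fold-change symmetry, saturation); any monotone map with the same
properties would order the cells identically.

The map itself sums unnormalised Gaussian kernels centred at the $A$
cells, each scaled by $\Gamma'_i$:

$$ \mathrm{TCM}(x) = \sum_{i \in A} \Gamma'_i
   \exp\!\left(-\frac{\lVert x - x_i \rVert^2}{2\sigma^2}\right), $$

evaluated on a raster anchored at the domain's lower-left corner
(default spacing 10 µm). Defaults: $r = 50$ µm, roughly two to three
cell diameters, and $\sigma = r/2$ so the kernel's ~2σ support matches
the radius at which correlation was measured — the map does not claim
spatial precision finer than the statistic it displays. Kernels are
unnormalised so an isolated cell contributes a peak of height exactly
$\Gamma'_i$, making amplitudes comparable across maps; the surface is
bounded by $(\alpha-1) N_A$ in absolute value. The TCM is asymmetric
in its marks: kernels sit on $A$ cells, so TCM(A,B) localises "where
$A$ cells see $B$ enrichment".

```{r tcm-example}
plot(tcm_surface(p, "C1", "C2", r_tcm = 50, grid_spacing = 20),
     main = "TCM: C1 vs C2")
```

## Neighbourhood correlation functions

Pairwise statistics cannot distinguish "A-B, B-C and A-C each
colocalise somewhere" from "A, B and C colocalise together". The NCF
measures genuine $k$-way co-occurrence. For every tuple taking one
point per mark, its *neighbourhood size* is the radius of the tuple's
minimum enclosing circle (MEC) — the smallest circle containing all
$k$ points. Unlike the maximum pairwise distance, this radius responds
to every point in the tuple and reads directly as "the radius of the
region the cells share". The MEC is computed by Welzl's randomized
incremental algorithm, validated in the test suite against exhaustive
enumeration over pairs and triples.

Observed MEC radii are binned on the same annulus grid as the PCF and
divided by the CSR expectation:

$$ \mathrm{NCF}(r) = \frac{\text{observed tuples with MEC radius in bin}}
   {(\prod_i N_{C_i}) \; \hat p_{\mathrm{CSR}}(\text{bin})}, $$

where $\hat p$ is estimated by drawing random $k$-tuples uniformly in
the *same* rectangle (default $10^5$ samples, seeded). Sampling the
null on the data's own domain absorbs edge effects into the
denominator, so no analytic edge correction is needed. Per-bin
binomial standard errors are always reported; bins whose expected
count is zero are reported as missing (`NA`), never as 0, since an
observed/expected ratio is undefined there.

Two presentation conventions exist — per-bin counts or cumulative
counts up to $r$ — and the package implements both; the binned form is
the default because it matches the PCF's annulus convention, with
`cumulative = TRUE` available. Tuple enumeration grows as the product
of the per-type counts, so tuples whose largest pairwise distance
exceeds $2 r_\mathrm{max}$ are discarded before any circle is
computed; the bound MEC radius ≥ (max pairwise distance)/2 makes this
pruning exact.

```{r ncf-example}
p2 <- generate_dataset_2(seed = 1, variant = "pairwise")
plot(ncf(p2, c("A", "B", "C"), n_samples = 2e4, seed = 2),
     main = "NCF, pairwise variant")
```

## Weighted PCFs for continuous marks

Thresholding a continuous stain intensity into positive/negative cells
discards information and makes results sensitive to the cutoff. The
weighted PCF instead sweeps a *target mark* $M$ across the observed
range and weights each potential partner cell by how close its mark
$m_j$ is to the target, using a triangular kernel

$$ w(m, M) = \max\!\left(0,\; 1 - \frac{|m - M|}{\delta}\right), $$

which is 1 at $m = M$, decays linearly and has compact support of
half-width $\delta$. Then

$$ \mathrm{wPCF}(M, r) = \frac{|D|}{N_C \, W_M} \sum_{i \in C}
   \sum_{j \neq i} \frac{w(m_j, M)\,
   \mathbf{1}(d_{ij} \in [r, r+\varepsilon))}{A_r(x_i)},
   \qquad W_M = \sum_j w(m_j, M). $$

Each row (fixed $M$) is interpreted exactly like a cross-PCF against
"cells with mark near $M$". If the marks are concentrated at discrete
levels and $\delta$ is below the gap between levels, the rows at those
levels reproduce the hard-classified cross-PCFs exactly — the
continuous statistic contains the thresholded one as a special case
(verified in the test suite). The two-continuous-marks variant weights
both ends of each pair, with per-mark target grids and (possibly
different) half-widths, normalised by $W_{M_1} W_{M_2}$.

$\delta$ trades mark resolution against statistical support; the
default is one tenth of the observed mark range (with a 101-point
target grid over that range), and both are recorded in the output so
sensitivity to the choice can be checked by rerunning with other
values. Points with `NA` in the continuous column receive weight 0 and
do not enter $W_M$. Targets where $W_M = 0$ are reported missing. The
statistic is invariant under affine rescaling of the mark provided the
targets and $\delta$ are rescaled identically, so units of intensity
do not matter.

## Segmentation-free mode

Where segmentation is unavailable or unreliable, `lattice_sample()`
converts an intensity raster directly into a point pattern: one point
per node of a regular lattice (default spacing 20 µm, nodes centred in
their cells so the pattern is symmetric under image flips), carrying
the local pixel intensity as a continuous mark and, optionally, a
positive/negative label from a threshold. The wPCF then applies
unchanged, with lattice nodes in place of cell centroids; at high
target intensities its rows recover the shape of the thresholded
cross-PCF.

## The synthetic study patterns

Two constructions, used by the tests and reproducible with any seed,
exercise every statistic without external data. Both live on a
1000 × 1000 µm domain and draw cluster offspring from isotropic
Gaussians (a Thomas-type construction with fixed offspring counts);
out-of-domain draws are redrawn rather than clipped, so per-type
counts are exact and there is no boundary pile-up.

**Dataset I** (two types + a continuous mark): on the left half, 20
cluster centres shared by both types (10 points each per centre) —
strong short-range colocalization; on the right half, 10 independent
centres per type — segregation. C2 cells carry a continuous mark,
uniform on [0, 0.5) for cells left of the midline and on [0.5, 1]
right of it, keyed on the cell's own position so the mark is an
honest per-cell readout rather than a cluster label.

**Dataset II** (three types, two variants): three cluster centres at
(350, 350), (650, 350), (500, 610) — an equilateral-ish triangle of
side ≈300 µm. In the *pairwise* variant each centre hosts two of the
three types (25 + 25), so every pair colocalises but no centre has all
three (50 cells per type); in the *triplet* variant every centre hosts
25 of each type (75 per type). Pairwise statistics cannot tell the
variants apart; the NCF separates them sharply. With cluster spread
σ = 25 µm, any three-type tuple in the pairwise variant must span at
least two centres, so its MEC radius is at least about
(300 − 4σ)/2 = 100 µm: the NCF is 0 below that scale and climbs to 1
over roughly 100–300 µm. The centre coordinates and σ were fixed once
to realise exactly that geometry.

These generators emulate clustering, colocalization and mark-position
association, but not features of real tissue such as anisotropy,
tissue-compartment boundaries, cell-size exclusion effects, or
segmentation/classification error. Tests passing on them validate the
statistics' calibration and construction, not robustness to those
artefacts.

## Numerical and design notes

* **Exact geometry.** Disc/annulus-rectangle intersection areas are
  closed-form; the test suite checks them against a 0.1 µm
  pixel-counting oracle. Annuli that fall entirely outside the domain
  contribute 0 (no neighbour can exist there), avoiding 0/0.
* **Half-open bins.** All distance bins are $[r, r+\varepsilon)$;
  degenerate tuples with coincident points have MEC radius 0 and land
  in the first bin.
* **Closed domain.** Points exactly on the rectangle boundary are
  inside; MEC containment uses a 1e-9 relative tolerance.
* **Determinism.** Every stochastic routine takes a seed, uses it
  locally and restores the caller's RNG state. Observed NCF counts are
  deterministic; only the null is sampled.
* **Problem sizes.** The calibration checks in the test suite use
  1000-point CSR patterns (20 seeds) for the PCF and $10^5$ CSR tuple
  samples for the NCF null, sizes at which the Monte-Carlo error is
  well below the tolerances asserted.

## Known limitations

Rectangular domains only (no masks or holes); homogeneous CSR null
(no inhomogeneous intensity estimation); the NCF's tuple enumeration
is product-of-counts and is practical for up to a few hundred cells
per type within `r_max`; the CSR envelope is pointwise, not a global
rank test.
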