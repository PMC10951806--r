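# mxpcf — extended correlation functions for multiplex imaging

`mxpcf` quantifies spatial relationships between cell types in
multiplex immunohistochemistry images. Its input is the standard
product of a segmentation/classification pipeline: a cell table with
one row per cell — centroid coordinates in µm, a categorical mark
(cell type) and optional continuous marks (stain intensities) — on a
rectangular region of interest. It is written for image analysts and
computational pathologists who need more than cell-count compositions:
*where* and *at what length scales* cell populations attract, avoid,
or co-assemble.

All statistics are ratios calibrated to 1 under complete spatial
randomness (CSR):

* **PCF / cross-PCF** — `pcf()`, `cross_pcf()`: the classical pair
  correlation function over annuli `[r, r+ε)`,

  `g_AB(r) = |D| / (N_A N_B) · Σ_i Σ_j 1(d_ij ∈ [r, r+ε)) / A_r(x_i)`,

  with exact closed-form annulus-area edge correction `A_r(x_i)`
  (area of the annulus inside the rectangle). `csr_envelope()` adds
  pointwise simulation envelopes.
* **TCM** — `tcm_surface()`: a topographical correlation map that
  localizes correlation. Each type-A cell gets a local statistic
  `Γ_i = (n_B(i,r)/A_r(x_i)) / (N_B/|D|)`, linearized to a
  fold-change-symmetric mark `Γ'` (capped at ±(α−1)), and the map sums
  Gaussian kernels scaled by `Γ'` over the A cells.
* **NCF** — `ncf()`: neighbourhood correlation function for k ≥ 2
  types. Every k-tuple (one cell per type) is scored by the radius of
  its minimum enclosing circle; per radius bin, observed tuple counts
  are divided by the CSR expectation `(Π N_i)·p(bin)` estimated by
  Monte-Carlo sampling on the same domain. Distinguishes genuine
  three-way colocalization from coincident pairwise attraction.
* **wPCF** — `wpcf()`, `wpcf_continuous()`: weighted PCFs that treat a
  continuous mark without thresholding, weighting each partner cell by
  a triangular kernel `w(m, M) = max(0, 1 − |m−M|/δ)` around a sweep
  of target marks M.
* **Synthetic generators** — `generate_dataset_1()` (mixed vs
  segregated two-type clusters with a continuous mark),
  `generate_dataset_2()` (three types, pairwise-only vs triplet
  colocalization), `generate_csr()`.
* **Plumbing** — `read_cell_table()` / `write_cell_table()` (CSV),
  `lattice_sample()` (segmentation-free mode: regular lattice over an
  intensity raster), plus a CLI at `inst/cli/mxpcf.R`.

## Worked example

```r
library(mxpcf)

p <- generate_dataset_1(seed = 1)     # 300 C1 + 300 C2 cells, 1000x1000 um
mark_counts(p)
#>  C1  C2
#> 300 300

g <- radial_grid(r_max = 100)         # annuli [0,10), [10,20), ..., [90,100)
curve <- cross_pcf(p, "C1", "C2", g)
head(as.data.frame(curve)[, c("r", "value")], 5)
#>    r value
#> 1  0 3.926
#> 2 10 4.024
#> 3 20 3.479
#> 4 30 3.013
#> 5 40 2.350
```

The cross-PCF is ~4 at short range: C1 cells see about four times more
C2 cells within a few cell diameters than CSR predicts — the shared
clusters on the left half of the pattern. Is that significant?

```r
env <- csr_envelope(p$domain, c(C1 = 300, C2 = 300),
                    list(name = "cross_pcf", mark_a = "C1",
                         mark_b = "C2", grid = g),
                    n_sims = 39, seed = 2, observed = curve)
env
#> CSR envelope: 39 simulations, quantiles (0.025, 0.975), 10 radii
#> observed curve inside envelope at 0.0% of radii
```

The observed curve lies outside the 95% CSR envelope at every radius.

Pairwise statistics can be blind to higher-order structure. In the
pairwise variant of dataset II each *pair* of the three types shares a
cluster, yet no cluster holds all three — and the NCF sees it:

```r
p2 <- generate_dataset_2(seed = 1, variant = "pairwise")
nc <- ncf(p2, c("A", "B", "C"), radial_grid(r_max = 300),
          n_samples = 1e5, seed = 2)
as.data.frame(nc)[c(6, 11, 16, 21), ]
#>      r observed expected  value mc_stderr
#> 6   50        0    91.25  0.000     0.000
#> 11 100       60   381.25  0.157     0.009
#> 16 150    24899  1016.25 24.501     0.856
#> 21 200     1338  1761.25  0.760     0.020
```

No A-B-C neighbourhood of radius ≤ ~100 µm exists at all (the
inter-cluster distance forbids it), and the pile-up at ~150 µm is the
two-cluster span. The triplet variant instead gives values ≫ 1 in the
smallest bins. See `vignettes/extended-correlation-functions.Rmd` for
the model details, parameter guidance and design notes.

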