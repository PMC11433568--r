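---
title: "Neutrosophic multi-scale texture descriptors for image retrieval: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrosophic multi-scale texture descriptors for image retrieval: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrotex)
```

## The problem

Content-based image retrieval for grayscale (typically medical) images ranks
a database by visual similarity to a query. Texture carries most of the
diagnostic signal in CT and MR slices, but plain local binary patterns (LBP)
are fragile: a single noisy pixel flips sign bits, and fixed 8-neighbor
sampling sees only one spatial scale. `neutrotex` implements a descriptor
family that addresses both weaknesses by (a) working in the neutrosophic
domain, where each pixel carries truth/indeterminacy/falsity memberships
rather than one intensity, and (b) quantizing large circular neighborhoods
down to 8 noise-damped values before thresholding.

## The model

### Neutrosophic transform

For an image $Z$ with $w \times w$ local mean $\bar Z$ (replicate-padded box
filter), the three membership images are

$$T = \frac{\bar Z - \bar Z_{min}}{\bar Z_{max} - \bar Z_{min}}, \qquad
I = \frac{\delta - \delta_{min}}{\delta_{max} - \delta_{min}}, \qquad
F = 1 - T,$$

with $\delta = |Z - \bar Z|$. $T$ is a smoothed, contrast-normalized view;
$I$ highlights pixels that disagree with their neighborhood (edges, noise,
fine texture); $F$ is the complement of $T$. All three are min–max
normalized, so the descriptors computed from $T$ and $I$ are exactly
invariant to affine intensity rescaling $Z \mapsto aZ + b$, $a > 0$ — a
property the test suite asserts.

### Circular sampling and quantization

At scale $r$, $8r$ points are sampled on the circle of radius $r$ around
each pixel, at angles $\theta_n = 2\pi n/(8r)$ with sample 0 due east and
the index running counter-clockwise; off-grid points are bilinearly
interpolated (lerp form, exact on constant and affine images; coordinates
within $10^{-6}$ of a grid point snap to it). The $8r$ samples are collapsed
to 8 per-arc values in two ways:

* **median quantization** (`median_quantize`): the median of each arc of
  $r$ consecutive samples. A single corrupted sample inside an arc cannot
  move the median, which is the core of the noise tolerance.
* **mean absolute local differences** (`mean_local_difference_quantize`):
  the mean of $|sample - center|$ per arc, which averages noise down by
  $\sqrt{r}$.

### The three per-pixel patterns

With $s(x) = 1$ for $x \ge 0$ and $0$ otherwise (ties count as 1,
consistently everywhere):

* **MsTrP**: bits $s(\mathrm{mqp}_k - p_c)$, riu2-mapped. 10 labels.
* **NrTxP**: bits $s(\mathrm{mldqp}_k - \nu_r)$, riu2-mapped, where
  $\nu_r$ is the mean over the $8r$ pixels of the square ring at Chebyshev
  distance $r$ of the full-grid mean-absolute-local-difference image
  $\mu ld_r$. 10 labels.
* **RiTxP**: the single bit $s(p_c - \mu_r)$, with $\mu_r$ the mean image
  value over the same square ring. 2 labels.

The riu2 mapping assigns a pattern with at most two circular bit
transitions its popcount (0–8) and all non-uniform patterns the shared
label 9 — 10 labels out of 256 raw codes, invariant to circular shifts and
hence to image rotation. A 90° image rotation shifts the $8r$ samples by
exactly $2r$ positions, i.e. the 8 arcs by 2, so all three label maps
commute with quarter-turn rotation; the suite checks this both per-map and
on the final descriptor.

### Descriptor assembly

Per scale and per neutrosophic channel, the joint histogram
MsTrP × RiTxP (20 bins, RiTxP index fastest) is concatenated with
NrTxP × RiTxP (20 bins): 40 bins instead of the 200-bin three-way joint
histogram (10 × 10 × 2), which is implemented nowhere as an output — it is
the documented rejected design, kept only as an arithmetic identity in the
acceptance checks. The full descriptor concatenates scale-major, then
T, I, F within each scale: $120 S$ values for $S$ scales.

### Retrieval and evaluation

Ranking uses the extended Canberra distance
$\sum_\tau |a_\tau - b_\tau| / (a_\tau + \bar a + b_\tau + \bar b)$: each
term lies in $[0, 1)$, the sum is scale-free, and the added means stop
near-empty histogram bins from dominating. Ties are broken
lexicographically by image id so runs are platform-reproducible. Metrics
are avgP (precision at depth $\eta$), avgR (recall against the class
size), their harmonic mean (Fscore) and mean average precision (MavgP),
all on the 0–100 scale, plus the coefficient of variation
(population SD / mean) of a rate across the clean and noisy conditions.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `w` | 3 | pixels | local-mean window of the transform; 3 is the smallest odd window and preserves fine texture. Configurable because no canonical value exists. |
| `scales` | 1–9 (min side ≥ 64 px), else 1–5 | pixels | radius set of the multi-resolution sweep; small images cannot support large rings without losing most of their valid region, and the 64 px cutoff keeps 61 px-class images at five scales. |
| `normalize` | `TRUE` | — | each 20-bin block becomes a probability histogram, making images of different sizes comparable; raw counts stay available. |
| `eta` | 100 | images | retrieval depth, the field's usual top-100 convention; capped at the database size. |
| `exclude_self` | `FALSE` | — | a database member used as query self-matches at distance 0; including it is the convention in the LBP-retrieval literature, the flag removes it. |
| noise $\sigma$ | 5–50 | 8-bit intensity | the benchmark corruption range; per image, $\sigma$ is drawn uniformly, noise added, result clipped to [0, 255]. |

## What the synthetic generator emulates — and what it does not

`generate_texture_dataset` builds classes from four texture families
(oriented sinusoidal gratings, checkerboards, Gaussian blob fields, fine
gratings) with class-specific frequency/period/density and per-image
phase, offset and orientation jitter. This mirrors what the descriptor must
separate in real use — classes that differ in local texture statistics and
in global structure — and it exercises every pipeline stage with known
ground truth under a single seed.

It does **not** emulate CT or MR physics: no partial-volume blur, no
anatomy-shaped correlated structure, no acquisition artifacts, no
inter-class subtlety of, say, ventricular-shape differences. Passing the
packaged benchmarks therefore demonstrates the machinery (determinism,
rotation invariance, relative noise stability against a plain-LBP
baseline), not clinical-grade retrieval rates: the synthetic classes are
deliberately separable, so absolute precision figures here are optimistic
relative to hospital data.

The benchmark shipped in the acceptance tests uses 4 classes × 25 images of
64 × 64 pixels with $\eta$ = 25 (the class size), the nine default scales,
and the full 5–50 noise range — small enough to run in minutes on one core,
large enough that the plain single-scale LBP baseline visibly collapses
under the same corruption while the multi-scale median/mean-quantized
descriptor does not.

## Numerical choices and degenerate inputs

* **Ties**: $s(0) = 1$ in all three patterns; an even-sized arc's median is
  the mean of the two middle order statistics.
* **Ring statistics**: the defining ring expressions are sums over $8r$
  members but are named means, so both $\nu_r$ and $\mu_r$ are divided by
  $8r$; an unnormalized sum would make the RiTxP threshold scale-dependent,
  contradicting its description as a local mean. The ring members of
  $\mu_r$ are read as the image values on the square ring of the
  $(2r+1)\times(2r+1)$ window.
* **Borders**: pattern labels exist only in the valid region
  $[1+r, M-r] \times [1+r, N-r]$; outside it the maps carry the sentinel
  −1 and contribute to no histogram. The $\mu ld_r$ image, which $\nu_r$
  consults at ring positions, is computed on the *full* grid using
  replicate-padded (coordinate-clamped) sampling so all three maps share
  one valid region.
* **Degenerate channels**: a constant image makes the T- or I-channel
  normalization denominator zero; the channel is set identically to 0
  (hence $F \equiv 1$) with a warning, keeping every downstream label
  defined.
* **Zero denominators in the distance** contribute 0; this is reachable
  only when both descriptors are identically zero.
* **Interpolation**: the lerp form of bilinear interpolation is used
  because it returns constants exactly, which keeps the all-ties case of a
  flat image at label 8 for all three patterns.

## Open design points and how they were resolved

* The mean-average-precision expression in the source material is not
  well-formed as printed; the standard definition (per-query average
  precision over relevant ranks within $\eta$, divided by the class size,
  averaged over queries) matches the metric's name and its observed
  ordering MavgP ≥ avgP, and is what `aggregate_metrics` implements,
  checked against a rank-enumeration oracle.
* Whether histograms are normalized before concatenation is left
  switchable; probability histograms are the default since the distance's
  mean-offset terms presuppose comparable magnitudes.
* The local-mean window $w$ has no canonical published value; 3 is the
  default and it is exposed in every interface.
* Self-retrieval is included by default (the comparison literature's
  convention) with `exclude_self` provided, since published protocols are
  ambiguous about counting the self-match.

## Known limitations

* Pure-R per-pixel reference paths exist for testing, but production label
  maps come from compiled code; exotic platforms without a C++ compiler
  cannot build the package.
* DICOM input is not supported; convert to PNG/TIFF first.
* The descriptor is invariant to 90° rotations by construction and
  approximately stable under arbitrary rotations (through riu2), but the
  suite only asserts the quarter-turn case, where the sampling lattice maps
  onto itself.
* Retrieval is exact brute-force scoring ($O(\omega)$ distances per
  query); no approximate-nearest-neighbor index is provided.
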