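# neutrotex

Multi-scale, noise-resistant, rotation-invariant texture descriptors
(MsNrRiTxP) for content-based retrieval of grayscale images, with the full
surrounding pipeline: neutrosophic image transform, extended-Canberra
ranking, retrieval metrics, a seeded synthetic texture benchmark with an
additive-white-Gaussian-noise corruption protocol, and a command-line
interface.

It is aimed at people building or studying content-based (medical) image
retrieval: given a query slice, rank a labeled database by texture
similarity, and know how much the ranking degrades when the query is noisy.

## The method in brief

An image `Z` is first decomposed into three neutrosophic membership images:

    T = minmax(boxmean_w(Z)),   I = minmax(|Z − boxmean_w(Z)|),   F = 1 − T

On each of T, I, F and at each scale `r`, `8r` points are sampled on the
circle of radius `r` around every pixel (bilinear interpolation) and
collapsed to 8 per-arc values, from which three per-pixel labels are
computed:

* **MsTrP** — sign of (arc **median** − center), read as an 8-bit pattern and
  mapped through the rotation-invariant uniform (riu2) rule: patterns with
  ≤ 2 circular transitions get their popcount (0–8), all others the label 9.
* **NrTxP** — sign of (arc **mean absolute difference** − ν_r), riu2-mapped,
  where ν_r is the mean of the mean-absolute-local-difference image over the
  square ring at Chebyshev distance `r`.
* **RiTxP** — one bit: center ≥ mean image value over the same ring.

Per scale and channel the descriptor is the 20-bin joint histogram
MsTrP × RiTxP concatenated with the 20-bin NrTxP × RiTxP — 40 bins, versus
200 for the rejected three-way joint histogram. Concatenating over scales
and the T, I, F channels gives `120·S` values per image. Database images are
ranked by the extended Canberra distance

    D(a, b) = Σ |a − b| / (a + mean(a) + b + mean(b))

and evaluated with avgP, avgR, Fscore and MavgP at depth η, plus the
coefficient of variation of a rate across the clean and noisy conditions.

The arc medians and arc-averaged differences are what buy noise
resistance: an isolated corrupted sample cannot flip an arc's bit. The riu2
mapping and the ring thresholds buy rotation invariance.

## Worked example

```r
library(neutrotex)

ds <- generate_texture_dataset(n_classes = 4, n_per_class = 10,
                               size = 48, seed = 42)
d <- extract_descriptor(ds$images[[1]], scales = 1:5)
length(d)
#> [1] 600

bm <- run_benchmark(ds, run_config(eta = 10, scales = 1:2),
                    noise = noise_spec(5, 50, seed = 43))
bm$clean
#> <metrics_report> omega = 40 queries, eta = 10
#>   avgP 100.00%  avgR 100.00%  Fscore 100.00%  MavgP 100.00%
bm$noisy
#> <metrics_report> omega = 40 queries, eta = 10
#>   avgP 67.00%  avgR 67.00%  Fscore 67.00%  MavgP 62.04%
round(bm$cv, 4)
#>   avgP   avgR Fscore  MavgP
#> 0.1976 0.1976 0.1976 0.2343
```

Reading the numbers: each of the 40 database images is used as a query; at
depth η = 10 every clean query retrieves only its own class (avgP 100%).
With heavy Gaussian noise (σ drawn from [5, 50]) on the queries and only
two scales, precision drops to 67% — and the coefficient of variation
(≈ 0.20) quantifies that instability. Running the same benchmark with the
default scale set (r = 1..5 at this image size) all but removes the drop: the
larger rings are exactly what absorbs the noise:

```r
run_benchmark(ds, run_config(eta = 10),
              noise = noise_spec(5, 50, seed = 43))$noisy
#> <metrics_report> omega = 40 queries, eta = 10
#>   avgP 99.25%  avgR 99.25%  Fscore 99.25%  MavgP 98.92%
```

A shell version of the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "neutrotex", package = "neutrotex"))')
Rscript $CLI simulate  --classes 4 --per-class 10 --size 48 --seed 42 --out db/
Rscript $CLI extract   --in db/ --out db/features.csv
Rscript $CLI query     --db db/features.csv --image db/img0001.png --eta 10
Rscript $CLI benchmark --in db/ --eta 10 --out report.json
```

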