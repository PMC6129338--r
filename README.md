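# dermatex

Recognition of three common skin conditions — **herpes**, **paederus
dermatitis** and **psoriasis** — from 2-D colour skin images, by combining
texture features with the lesion's pixel area.

Clinical triage of these conditions is usually visual and
experience-driven. Each of the three presents with a distinctive surface
texture (vesicular speckle, fine irritant grain, coarse plaques) and a
characteristically different lesion extent (psoriasis plaques are the
largest, paederus lesions the smallest). `dermatex` turns those two cues
into a quantitative classifier, and ships a synthetic-image generator with
exact ground truth so the whole chain can be tested and benchmarked
without clinical photographs.

## Method

The pipeline has three phases:

1. **Preprocessing.** Salt-and-pepper noise is removed with a median
   filter (each pixel replaced by the median of its window). The
   binarized epithelium's principal axis is estimated from second-order
   image moments and the image rotated so that axis is horizontal, on a
   canvas of `⌈w|cosθ| + h|sinθ|⌉ × ⌈h|cosθ| + w|sinθ|⌉` with
   nearest-neighbour sampling. The Euclidean distance transform
   `d(p, B) = min_b √((x−m)² + (y−n)²)` of the foreground yields the
   medial axis as the per-column ridge of the distance map, and the
   epithelium is split into ten vertical regions `L1..L10` of equal
   arclength along that axis.

2. **Feature extraction.** For each region, a gray-level co-occurrence
   matrix `G(i, j)` (64 levels, distance-1 offsets at 0°/45°/90°/135°,
   symmetric, normalized) is summarised by five statistics:

   | statistic | formula |
   |---|---|
   | contrast | `Σᵢⱼ (i−j)² G(i,j)` |
   | correlation | `Σᵢⱼ (i−x̄)(j−ȳ) G(i,j) / (σₓσᵧ)` |
   | entropy | `−Σᵢⱼ G(i,j) log G(i,j)` |
   | uniformity | `Σᵢⱼ G(i,j) / ((i−j)² + 1)` |
   | energy | `Σᵢⱼ G(i,j)²` |

   The texture part of the feature vector is the per-statistic (min, max)
   over the ten regions. In parallel, the lesion is segmented by a
   marker-controlled watershed of the chroma-gradient relief, k-means
   merging of the resulting zones into background / normal skin / lesion /
   mis-segmented roles, and morphological cleanup; its **area fraction**
   is the colour part of the vector.

3. **Classification.** One-vs-one soft-margin SVMs with the RBF kernel
   `k(u, v) = exp(−‖u−v‖² / 2σ²)`, penalty `C = 50` and median-heuristic
   `σ`, trained by an SMO-style dual solver on the 11-dimensional vector;
   prediction is `sgn(Σⱼ aⱼ yⱼ k(x, xⱼ) + b)` per class pair with a
   majority vote. A texture-only classifier (SVM1) and an area-only
   classifier (SVM2) are trained alongside as diagnostics; combining both
   cues is what resolves the classes that either cue alone confuses.

## Worked example

```r
library(dermatex)

# a synthetic herpes image: 256x256, lesion radius 40 px, 2% impulse noise
g  <- generate_image(synth_spec("herpes", lesion_radius_px = 40,
                                noise_fraction = 0.02,
                                orientation_deg = 20, seed = 7))
ex <- extract_image_features(g$image)
round(ex$features, 4)
#>    contrast_min    contrast_max correlation_min correlation_max
#>          0.2037         79.3102          0.6218          0.9527
#>     entropy_min     entropy_max  uniformity_min  uniformity_max
#>          2.6403          3.8722          0.8093          0.9030
#>      energy_min      energy_max   area_fraction
#>          0.1057          0.2722          0.0781
ex$lesion$lesion_area_px   # 5116 px; the painted ground truth is 5024 px
```

The high `contrast_max` (79.3, from the segments containing the vesicular
speckle) against the low `contrast_min` (0.20, plain skin) is the texture
signature; `area_fraction` 0.078 recovers the painted lesion disk to
within 2%.

The self-contained experiment generates 30 images per class, trains on 10
per class and evaluates on the remaining 20 per class:

```r
ex <- end_to_end_experiment(cfg = pipeline_config(seed = 42))
ex$table
#>                 class n_test n_recognized rate_pct
#> 1              herpes     20           20      100
#> 2 paederus_dermatitis     20           20      100
#> 3           psoriasis     20           20      100
```

On the generator's default, cleanly class-separable conditions the
integrated classifier recognises all 60 held-out images.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "dermatex", package = "dermatex"))')
Rscript $CLI synth --n 30 --seed 42 --out data/         # images + masks + manifest
Rscript $CLI preprocess data/img_001_herpes.png --out-dir pre/
Rscript $CLI segment data/img_001_herpes.png --out-mask mask.png --out-stats stats.csv
Rscript $CLI train data/manifest.csv --out model.json
Rscript $CLI predict model.json data/img_001_herpes.png
Rscript $CLI experiment --seed 42 --out table.csv
```

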