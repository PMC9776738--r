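# priorgrow

Automatic segmentation of lung tumors in single 2-D CT slices, for
image-analysis researchers and engineers who need a fully automatic,
deterministic, classical (non-learned) baseline segmenter with built-in
validation machinery.

Classical seeded region growing needs two manual inputs: a seed point
on the tumor and a gray tolerance.  `priorgrow` derives both from the
image and from prior knowledge of clinically relevant tumor sizes:

1. **Localization** — the slice is contrast-stretched, binarized with
   Otsu's threshold, and all 8-connected contours are extracted and
   measured physically (via the pixel spacing).  A contour is a tumor
   candidate iff its maximum Feret diameter is in (2, 5] cm (the TNM
   T1c–T2b window) *and* its area is in (1, 6.25π] cm² (the cap is the
   5 cm circle's area; the floor screens out vessel cross-sections).
   The surviving target contour D seeds the segmentation at its
   centroid C.
2. **Seed expansion** — three dividing lines through C at 60° split D
   into six sectors whose centroids give six further seeds p2…p7 (with
   an interior fallback for concave tumors).
3. **Ensemble growing** — breadth-first region growing from each seed
   on the original intensities, accepting neighbors within a gray
   tolerance of the seed's value.  p1 uses 20% of the whole-image
   intensity range; each later seed uses 20% of the range inside a
   circle around the previous seed's result (radius = farthest grown
   boundary point + 6 px).
4. **Growth restriction** — a grown region is credible iff it stays
   within the predicted maximum size (if supplied) or, by default,
   within the area of the circle around C through the farthest point
   of D.  The final mask is the union of credible regions; an
   all-abnormal ensemble fails loudly.

Evaluation uses the Dice coefficient `2|x∩y|/(|x|+|y|)` and the
Jaccard distance `1 − |x∩y|/|x∪y|`.  A synthetic lung-slice phantom
generator with exact ground truth supports all testing.

## Worked example

```r
library(priorgrow)

ph <- generate_phantom(phantom_spec(tumor_diameter_cm = 3.4,
                                    tumor_shape = "ellipse",
                                    noise_sd = 8, rng_seed = 42))
ph
#> <phantom> 512 x 512 px, ellipse tumor 3.40 cm, noise sd 8, seed 42

seg <- segment_tumor(ph$slice)
seg
#> <tumor_segmentation> 1 candidate(s), primary = 1
#>  [1]* <segmentation_result> 7/7 credible regions, combined 1331 px, circle-area mode, status ok

res <- primary_result(seg)
dice(ph$truth, res$combined_mask)
#> [1] 1
jaccard_distance(ph$truth, res$combined_mask)
#> [1] 0
sapply(res$regions, function(r) r$threshold)
#> [1] 51.0 39.4 39.4 39.4 39.6 39.6 39.4
```

All seven seeds grew credible regions; their union reproduces the
ground-truth mask exactly (Dice 1, Jaccard distance 0).  The first
tolerance (51.0) is 20% of the whole-slice intensity range; the later
ones (~39) are 20% of the range inside each update circle, which
contains only tumor and surrounding lung.  For real data, read a slice
with `read_ct_slice("slice.dcm")` (or a PNG/TIFF plus
`spacing_override =` mm/px) and pass it to `segment_tumor()`;
`build_report()`/`write_report()` produce a per-seed JSON audit trail.

A command-line interface covering the same workflow ships in
`exec/priorgrow`:

```sh
priorgrow phantom --seed 4 --diameter-cm 3 --out demo
priorgrow segment demo/phantom.png --spacing-mm 0.7 --truth demo/truth.png --out demo/seg
priorgrow eval demo/seg/mask.png demo/truth.png
```

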