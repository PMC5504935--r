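# spellerseg

Illumination-robust seeded color segmentation driven by a P300
brain-computer interface.

## The problem

Extracting an object of interest from a cluttered color image has two hard
parts: deciding *which* object the user means, and extracting it reliably
when the lighting changes.  `spellerseg` addresses both:

* **Selection** — a 3×3 P300 speller flashes the rows and columns of a grid
  of candidate objects.  Attending one cell makes the flashes covering it
  rare, attended events, which elicit a P300 deflection in the EEG; a
  Fisher linear discriminant decodes it and the selected object's seed
  pixel and fuzzy parameters are handed to the extractor.
* **Extraction** — a fuzzy color extractor whose similarity pattern is the
  *angle* between two pixel vectors in RGB space.  A pixel vector's length
  tracks illumination intensity while its direction tracks color, so the
  angle is invariant under global multiplicative illumination change and
  the same parameters work across lighting conditions.

The package is aimed at BCI and machine-vision researchers who want a
tested, fully synthetic-data-driven reference implementation of this
pipeline: every stage can be exercised end to end without hardware, using
the built-in scene and EEG generators.

## The model

**Color pattern.** For pixels $p$ and $q$ with 8-bit channels,

$$d(p,q) = \arccos\frac{p_R q_R + p_G q_G + p_B q_B}
{\sqrt{p_R^2+p_G^2+p_B^2}\,\sqrt{q_R^2+q_G^2+q_B^2}} \in [0, \pi/2].$$

**Fuzzy decision.** The angle is fuzzified by piecewise-linear memberships
$\mu_N,\mu_Z,\mu_P$ with breakpoints $\alpha_1<\alpha_2$; the rule weights
are $\omega_m=\mu_Z(d)$ ("matched") and $\omega_u=\max(\mu_N,\mu_P)(d)$
("unmatched").  They clip the output sets $\mu_M$ (triangle falling to 0 at
$\rho_U$) and $\mu_U$ (ramp rising from $\rho_M$), with
$\rho_M+\rho_U=\pi/2$, and the crisp output $\Delta\rho_F$ is the centroid
of the envelope $\max(\min(\omega_m,\mu_M),\min(\omega_u,\mu_U))$.  The
pixel is extracted iff $\Delta\rho_F<\sigma$.

**Subregion growing.** Starting from the unassigned pixel with minimal
angle to the seed, connected matched pixels are grown under a 4-adjacent,
4-diagonal or 8-neighbor pattern; new subregions are opened while the next
start candidate stays within a squared-RGB-distance gate
$\sum_i (p_i - q_i)^2 < r$ of the seed.  The largest subregion is the
object; runs of unextracted pixels strictly shorter than a threshold and
bounded on both sides are filled along rows, then columns.

**EEG chain.** 30 channels at 1000 Hz are band-pass filtered to 0.1–30 Hz
(zero-phase), epochs take the 50–800 ms post-onset window, remove the
window mean, reduce it 50-fold and concatenate channels head to tail into
450-sample features.  A shrinkage-regularized FLDA
($w \propto (S_w + \lambda I)^{-1}(\mu_+-\mu_-)$) scores each flash; the
attended cell is the crossing of the best row and best column, and online
selections vote over 3 repetitions (1.8 s each: six 200 ms flashes at
300 ms onset spacing).

## Worked example

```r
library(spellerseg)

ds <- read_seed_dataset()                    # seven objects O1..O7
sc <- make_scene(scene_spec(rng_seed = 7))   # cluttered 90 x 120 scene
om <- extract_object(sc$image, lookup_params(ds, "O1"))
om
#> object mask [O1]: 90 x 120, object 197 px (mask 197 px after gap fill), 1 subregion(s): 197
mask_iou(om$mask, sc$masks$O1)
#> [1] 1

# the angle pattern ignores a global halving of the channels
vector_angle(c(186, 69, 34), c(93, 35, 17))
#> [1] 0.004722536

# full loop: simulated EEG selects the object, the extractor segments it
run_end_to_end(n_selections = 18, rng_seed = 3,
               erp = erp_spec(amplitude = 8, noise_sd = 0.5))
#> end-to-end report (seed 3)
#>   online selection accuracy: 100.00% over 18 selections
#>   mask IoU vs ground truth: O1=1.000 O2=1.000 O3=1.000 O4=1.000 O5=1.000 O6=1.000 O7=1.000
```

The mask line says the extractor grew a single 197-pixel subregion for
O1, no gap needed filling, and the mask matches the scene's ground truth
exactly (IoU 1).  The report line says all 18 simulated high-SNR online
selections were decoded correctly and every object's mask matched its
ground truth.

A shell entry point wraps the same functions:

```sh
Rscript inst/cli/spellerseg.R extract --image scene.png --object O1 --out mask.png
Rscript inst/cli/spellerseg.R simulate --selections 18 --seed 3 --out report.tsv
```

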