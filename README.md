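# ivctrack

Semi-automatic estimation and tracking of the anterior–posterior (AP)
diameter of a vessel cross-section — typically the inferior vena cava
(IVC) — in B-mode ultrasound image sequences.  Emergency and critical-care
clinicians read the IVC's AP-diameter and its respirophasic collapse off
bedside ultrasound to guide fluid management; doing that manually on
450-frame clips is tedious, and free-form segmentation is fragile against
speckle, shadowing and boundary dropout.  `ivctrack` is for researchers
evaluating shape-constrained alternatives: the operator clicks one point
inside the vessel on the first frame and the rest is automatic.

## The models

All three trackers evolve a low-dimensional parametric shape under one
region-based force.  With *u* the mean intensity inside the shape, *v* the
mean over a band just outside it, and *I<sub>k</sub>* the image intensity
at the *k*-th contour sample, each sample is pushed along its outward
normal with force

> f<sub>k</sub> = α (u − v)(2 I<sub>k</sub> − u − v),

which vanishes where the contour intensity is halfway between the region
means, on either a dark-lumen or a bright-lumen vessel.

* **Active circle** (baseline) — center translated by the mean force
  vector, radius grown by the mean force; AP-diameter = 2R·spacing.
* **Active ellipse** — sampled points evolve individually, a conic
  a x² + b x y + c y² + d x + e y = 1 is refitted by closed-form least
  squares each iteration (validated with b² − 4ac < 0); AP-diameter =
  the ellipse's maximal *vertical chord*.
* **Active rectangle** — a thin vertical rectangle whose height models
  the AP-diameter directly; each side translates by its side-mean force
  while the width is annealed 15 → 3 px over a fixed 200-iteration
  budget, so partially missing boundaries cannot capture it.

A synthetic phantom generator (convex vessel sections with sinusoidal
collapse, unit-mean Rayleigh multiplicative speckle, optional shadow and
boundary dropout, exact ground truth) and an evaluation module (RMS
error, maximum absolute error, Pearson correlation, mean position error,
error PDFs) make the whole method testable without clinical data.

## A worked example

```r
library(ivctrack)
out <- run_demo(tempfile("demo"), rng_seed = 1, n_frames = 60)
subset(out$metrics, metric %in% c("rms_error", "correlation"))
#>                  metric       value     unit     model
#> circle.1      rms_error 0.095870651       cm    circle
#> circle.3    correlation 0.999161111 unitless    circle
#> ellipse.1     rms_error 0.024497586       cm   ellipse
#> ellipse.3   correlation 0.999804373 unitless   ellipse
#> rectangle.1   rms_error 0.049168395       cm rectangle
#> rectangle.3 correlation 0.997745908 unitless rectangle
```

The demo generates a 60-frame phantom clip (a 20°-rotated elliptical
vessel, ~2 cm AP-diameter at 0.04 cm/px, collapsing sinusoidally by 40%
over a 5-s cycle, speckle severity 0.3), tracks it with all three models
seeded at the vessel center, and compares each AP-diameter track against
the generator's ground truth.  Reading the panel: all three models follow
the collapse waveform almost perfectly (correlation > 0.997), but the
circle carries a ~0.1 cm RMS error — its diameter structurally
underestimates the maximal vertical chord of a rotated ellipse — while
the ellipse and rectangle stay at 0.02–0.05 cm.  Per-frame tracks, truth,
metric panel and the resolved configuration are written to the output
directory.

Lower-level entry points: `phantom_config()` / `generate_clip()` (frames
+ truth CSV on disk), `read_frames()`, `track_sequence()`,
`export_result()`, `evaluate_tracks()`, `error_distribution()`.  A thin
command-line wrapper with `synth`, `track`, `evaluate` and `demo`
subcommands lives at `inst/cli/ivctrack.R`:

```sh
Rscript inst/cli/ivctrack.R track --model rectangle --seed 64,64 \
    --input frames_dir --spacing 0.04 --out track.csv
```

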