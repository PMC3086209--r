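---
title: "Measuring erosion and demineralization by contact microradiography: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring erosion and demineralization by contact microradiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Contact x-ray microradiography images a thin, parallel-sided tooth section
placed directly on fine-grain film. X-ray attenuation by the mineral sets
the local exposure, so after development and transmitted-light digitization
the grayscale of the (negative) film encodes mineral density: more mineral,
more attenuation, less blackening, a *brighter* pixel. Comparing a "before"
radiograph with one taken after an acidic challenge distinguishes two
modes of mineral loss:

* **erosion** — bulk loss of surface; the density edge translates inward
  with its gradient preserved;
* **demineralization** — partial subsurface loss; density is depressed over
  a depth but the surface does not move.

`microrad` implements that comparison as a deterministic pipeline:
profile extraction → fiducial registration → two-point density
normalization → geometric measurement.

## Model and assumptions

1. **Affine film response in the working range.** Grayscale
   `G = intercept + slope · a` for attenuation fractions `a` within the
   film's linear region. Brightness and contrast act exactly as intercept
   and slope, so any two-point normalization cancels them. Outside the
   linear region (≈ below 10 % and above 90 % of scale) reciprocity failure
   bends the response; all anchors and fit bands are therefore kept
   interior to the scale.
2. **Constant section thickness.** Attenuation is then proportional to
   mineral density, and the normalized profile
   `D(x) = 100 (G(x) − Ḡ_bg) / (Ḡ_snd − Ḡ_bg)` reads directly in percent of
   sound mineral. Grid-fiducial samples exceed 100 % by design (metal).
3. **1-D geometry.** The lesion varies only with depth within the analysed
   ROI; averaging across the ROI width (default guidance: ~64 px) only
   suppresses grain noise.
4. **Rigid integer-pixel registration.** The before/after pair differs by a
   column translation (stage repositioning). Registration is integer-pixel
   by construction; sub-pixel precision enters later through interpolated
   threshold crossings, not through resampling.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| erosion threshold | 20 | % density | surface crossing read well above background noise and film toe |
| demineralization ceiling | 80 | % density | loss beyond 80 % of sound at the surface is erosion by definition |
| gradient fit band | 25–75 | % density | inside the 10–90 % linear film range with margin; widen to 10–90 at coarse pixel pitch so the edge still yields ≥ 3 samples |
| noise tolerance ε | max(2, 3·sd) | % density | sd is the sample sd of the normalized sound window; the floor keeps zero-calls well defined on near-noiseless data |
| zero-call distance | 2 × pixel pitch | µm | a distance below two pixels is not resolvable by the digitizer |
| peak min. separation | 0.5 × pitch/µm-per-px | px | half the 127 µm grid period |
| peak min. prominence | 0.1 × value range | gray | grid bars rise ≥ ~15 % of range above sound enamel; averaged grain noise sits far below |
| wedge anchors | explicit step indices | — | anchor choice is a calibration decision; defaults target the steps nearest 20 %/80 % of scale |
| linearity pass threshold | r² ≥ 0.9959 | — | configurable figure of merit for the pooled wedge fit |

## Numerical choices

* **Coordinates.** 0-based pixel indices, half-open ROIs, positions at
  pixel centers; µm positions are `index × µm-per-pixel`. Profiles run
  exterior → interior.
* **Threshold crossings** are linear interpolations between the bracketing
  samples; on exact ramps they are exact.
* **Lesion front.** The deficit `D_b(x − e) − D_a(x)` (before profile
  shifted by the measured erosion, so pure erosion leaves no deficit) is
  scanned interior → exterior; ε decides *which* crossing is the front, but
  the reported position is the zero-deficit interpolation of the bracketing
  segment. Reading the position at ε itself would understate the depth by
  `ε·L/(100·δ)` on a lesion of depth `L` and severity `δ` — about 3 µm at
  ε = 2 %, δ = 0.2, L = 30 µm — a bias the zero-interpolation removes on
  noiseless ramps.
* **Negative erosion** within `ε/slope` µm clamps to a zero-erosion call;
  anything more negative raises an error rather than silently reporting
  surface gain (remineralization metrics are out of scope).
* **Standard deviations.** Pixel-ROI statistics use the population sd
  (noise of a fixed region); across-wedge spread uses the sample sd
  (variability estimate).
* **Registration ties.** A periodic grid makes every whole-pitch offset an
  almost equally good peak match, and border-truncated peaks can even favor
  the wrong pitch. Candidates within 0.25 px² mean squared peak distance of
  the best are treated as ties and resolved toward the smallest absolute
  offset; the supported regime is therefore |true shift| < half the grid
  period (≈ 208 px at 0.305 µm/px).
* **TIFF dialect.** Uncompressed single-channel baseline TIFF; both byte
  orders, stripped or tiled layouts on read (the camera's exact layout is
  undocumented, so the reader is tolerant); always little-endian
  single-strip on write. 12-bit data live in 16-bit containers, values
  0–4095, no rescaling; the true depth travels in the ImageDescription tag.

## The phantom's stated world

No deposited microradiographs exist, so validation runs on synthetic
phantoms with known truth. The generator renders, per column at depth `x`:

* before density `d_b(x) = clamp((x − s)/w, 0, 1)` — a linear surface ramp
  of width `w` at surface position `s`;
* after density
  `d_a(x) = clamp((x − s − e)/w, 0, 1) · (1 − δ·clamp(1 − (x − s − e)/L, 0, 1))`
  — the ramp translated by the erosion `e` and depressed by up to the
  severity `δ` at the surface, recovering to sound at depth `s + e + L`;
* attenuation `= 0.8 · density` (sound enamel at 0.8, inside the linear
  film region), overridden to 10 (opaque) inside grid bars of 24 µm width
  at 127 µm pitch;
* grayscale via the film model — affine with intercept 300 and slope 3000
  on the 12-bit scale (background ≈ 470, sound ≈ 2700, grid ≈ 3150, well
  clear of both rails), with a smooth exponential roll-off (scale 0.05)
  outside the 10–90 % linear region standing in for reciprocity failure,
  whose true characteristic curve is unknown — plus optional per-radiograph
  uniform brightness/contrast jitter and additive Gaussian grain noise
  (1 % of full scale in the recovery experiments; 0.5 % in the wedge
  simulation), rounded and clamped to the bit depth.

Fixed geometry: first grid bar at 40 µm, surface at `s` = 210 µm inside a
grid hole; background window 194–207 µm, sound window 270–290 µm, so the
whole analysis span lies between two gridlines. The edge width is 2.5 µm
for experiments at 0.305 µm/px and 5.55 µm (5 px) at 1.11 µm/px — the
narrowest edge for which the gradient fit keeps ≥ 3 samples in its band at
that pitch, with the band widened to 10–90 % there.

What the phantom does **not** emulate: 2-D lesion shapes, film MTF or
spatially correlated grain, beam hardening, development gradients, and any
surface zone of preserved mineral in a demineralized lesion. A green
recovery test therefore establishes that the measurement chain inverts the
stated generative model — not that it reproduces every property of
physical films.

## A known geometric limitation

Because the generator applies the severity factor all the way to the
surface, the after edge is depressed by `(1 − δ)` and its 20 % density
crossing — the method's surface reference — moves inward. With `u*` the
root of `u (1 − δ (1 − u·w/L)) = d₀` (where `d₀` is the true density at the
normalized 20 % level), the method reports an apparent erosion
`w (u* − d₀)` and a depth short of truth by `u*·w`: at `δ = 0.5`, `L = 10 µm`,
`w = 5.55 µm` that is ≈ 0.9 µm of spurious erosion and ≈ 2.3 µm of depth
shortfall. A unit test verifies the implementation tracks this closed form.
The effect is a property of the 20 %-crossing surface definition applied to
surface-depressed lesions, not an implementation artifact; physical early
lesions typically retain a well-mineralized surface layer, which is exactly
the situation in which the definition is unbiased. Consequently the
high-severity pure-demineralization recovery experiment in the acceptance
suite does not meet its two-pixel criterion and is left failing rather than
redefined; depth-at-a-stated-percentage reporting (`report_depth_pct`) is
available when the surface reference is not trusted.

The depth percentage at which a lesion depth is quoted is a reporting
convention, not a measurement constant, so `report_depth_pct` has no
default.

## Limitations

* Relative density only; converting to mineral mass per volume would need a
  calibrated wedge model that is deliberately out of scope.
* No sub-pixel registration and no 2-D image alignment; shear or rotation
  between radiographs must be negligible.
* Apparent surface *gain* (remineralization) is reported as an error, not a
  measurement.
* Precision is digitizer-limited: standard errors below one pixel pitch
  should be read as "at the resolution limit", not as real precision.
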