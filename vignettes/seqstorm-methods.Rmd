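---
title: "Models and methods behind seqstorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seqstorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
# The heavier examples below reproduce analyses that the test suite runs;
# chunks are not evaluated when building the package.
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

seqstorm implements the computational side of multiplexed sequential dSTORM
imaging with DNA strand displacement: one fluorophore species (AF647) is
moved between targets by hybridizing a dye-labeled *template* strand to an
antibody-bound *protector* strand, imaging, and then stripping the template
with an *invader* strand through toehold-mediated strand displacement. This
vignette documents the models, defaults and design decisions; the README
shows the surface-level workflow.

## Strand-displacement gates

A gate is the protector/template duplex plus its invader. The shipped gate
sets have 38-nt templates whose first 30 nt are the reverse complement of
the 30-nt protector hybridizing region, leaving an 8-nt single-stranded
toehold at the template 3' end where the invader nucleates. The printed
protector records carry a 3' `TT` spacer before the azide used for antibody
conjugation; we model it as a non-hybridizing `linker` field excluded from
every complementarity computation, which reconciles the 32 stored bases
with the 30-bp duplex.

Complementarity is strict Watson-Crick (A·T, G·C, no wobble) and all
alignments are ungapped and antiparallel. `duplex_map()` maximizes paired
positions over all relative offsets, breaking ties by the smallest absolute
offset and then the 5'-most start on the first strand so results are
deterministic.

Cross-set orthogonality (`cross_reactivity()`) is scored as the longest
ungapped complementary run over all 9 inter-set strand pairs. This
run-length score is an explicit operational stand-in for a thermodynamic
criterion (the original sets were designed with a secondary-structure
ensemble tool whose exact acceptance rule is not recoverable); a pair of
sets is called orthogonal when the maximum run is below a configurable
threshold, default 10 consecutive bases. The threshold is always carried in
the report, never applied silently. For the shipped sets the maximum
inter-set run is 4. Sequence design itself is out of scope: the package
verifies printed sequences, it does not generate new ones.

## Displacement kinetics

During label exchange the invader (micromolar) vastly exceeds the
surface-bound template, so displacement is modeled as irreversible
pseudo-first-order decay with effective rate $k \cdot c$
($k$ = bimolecular displacement rate constant, $c$ = invader
concentration):

$$f(t) = (1 - r)\left(1 - e^{-k c (t - t_0)}\right),$$

where $r$ is the fraction of template never displaced and $t_0$ the invader
addition time. Fluorescence follows
$I(t) = e^{-\beta t}\,[1 - f(t)]$ with a separable photobleaching rate
$\beta$. The time course acquisition deliberately includes a ~20 s
pre-invader segment; `fit_trace()` uses it to estimate $\beta$ by
log-linear regression, then fits $(I_0, kc, r)$ on the post-invader
segment by bounded Levenberg-Marquardt. Starting values: $kc$ from the
time at which the post-segment has decayed by $1 - 1/e$ of its span, $r$
from the mean of the final 10 % of samples (clamped strictly inside
$[0, 1]$, because $r = 1$ zeroes the $kc$ gradient on flat traces). Whether
measured traces are bleach-corrected before normalization varies between
labs, so the percent reduction is reported both raw
(`reduction_pct`) and bleach-corrected (`reduction_pct_bleach_corrected`).

The default rate constant, $k = 10^5\ \mathrm{M^{-1}s^{-1}}$, is in the
published range for 8-nt toeholds; it is a configurable default, not a
fitted quantity. At the working invader concentration of 4.87 µM it
predicts >95 % removal in well under a minute — any
$k \gtrsim 2\times10^3$ reproduces saturation "in less than 5 minutes",
so conclusions do not hinge on the default. Branch-migration microstates,
reversible toehold exchange and sequence-dependent rate prediction are
out of scope.

## Synthetic acquisitions

No public raw data exist for this kind of experiment, so every downstream
stage is exercised against a generator whose defaults encode the
acquisition geometry of a typical EMCCD dSTORM setup: 0.1067 µm pixels, EM
gain 100, 60 Hz, 256×256 frames (desk-scale tests use 64×64 and 2,000
frames per round; full size is a configuration change, not a code change).

*Scenes.* Two schematic structure types: filaments (line segments, sites
every 20 nm — tubulin-like) and clusters (75 nm disks with
Poisson-distributed site counts — clathrin-like). Real clathrin/tubulin
geometry statistics are richer than this; the generator is deliberately
schematic, so closed-loop tests validate the *pipeline*, not biological
realism. Sites are mirror-reflected into a margin (default 0.4 µm) so
structures never hug the border, where fitting ROIs would be clipped.
Scenes, rounds and movies are bit-for-bit reproducible from their seeds.

*Photophysics.* A minimal blinking model: dark emitters activate with
per-frame probability `p_on`, stay on a geometric number of frames
(`mean_on_frames`), emit `photons_per_frame` expected photons while on,
and bleach permanently with per-on-frame probability `bleach_prob`.
Defaults (`p_on` = 5e-4, 3-frame mean on-time, 800 photons/frame, no
bleaching) give dSTORM-like sparsity at which the single-emitter fitter is
valid; at several-fold higher activation density, overlap losses become
visible — a real dSTORM failure mode the simulator reproduces.

*Image formation.* While on, each emitter contributes expected counts
$\mu_k = N\,E_x(k)\,E_y(k) + b$ per pixel, with integrated-Gaussian
factors (error-function differences across pixel edges) of width
$\sigma_{\mathrm{PSF}}$, default 1.3 px ≈ 139 nm — typical for a 1.45-NA
objective at 685 nm emission. Counts are Poisson. The default output is
photon units so the localizer's Poisson likelihood is exactly matched; an
optional EMCCD stage applies gamma-distributed electron multiplication
(shape = photon count, scale = EM gain), ADU offset and Gaussian read
noise. When localizing ADU movies the conversion divides by the net gain
and halves effective counts to absorb EM excess noise — a documented
approximation, off by default.

*Coordinates.* x right / y down, origin at the center of pixel (0, 0),
pixel units internally, micrometers at the I/O surface, 0-based half-open
indexing. A fitted `x = 3.0` is the center of pixel column 3.

*Time-course movies* emulate the low-excitation 2 Hz acquisition: all
sites emit continuously; each site's dye is displaced at an exponential
random time with rate $kc$ (a residual fraction never is), so the
frame-sum trace follows the intensity model by construction with
site-level binomial noise on top. The reference scene uses ~1,200 dye
sites — scaled to what a camera field of a labeled cell contains, and
enough that site-level stochasticity does not dominate the rate estimate.

## Localization

`localize_stack()` runs per frame:

1. **Detection** — difference-of-Gaussians band-pass at
   $\sigma_{\mathrm{PSF}}$ and $2\sigma_{\mathrm{PSF}}$, scaled by the
   analytic factor 0.3 so the response approximates peak amplitude above
   background in photons; strict 3×3 local maxima above
   `detection_threshold` (default 10 photons); maxima closer than half an
   ROI merged keeping the brighter (ties: smaller row, then column);
   border-clipped ROIs discarded. Two emitters within ~2 px merge into
   one candidate — single-emitter fitting is a stated limitation, and the
   goodness-of-fit filter rejects most such hybrids.
2. **MLE fitting** — the 4-parameter model $(x, y, N, b)$ with
   $\sigma_{\mathrm{PSF}}$ fixed (matching common practice; a 5-parameter
   variant would fit $\sigma$, but the cited usage fixes it), maximized by
   sequential per-parameter Newton-Raphson with position steps damped to
   ±1 px and $N, b$ clamped positive, 20 iterations by default, position
   initialized at the background-subtracted center of mass. Precisions are
   CRLBs from the inverse 4×4 Fisher information
   $I_{ij} = \sum_k \mu_k^{-1} \partial_i \mu_k \, \partial_j \mu_k$.
3. **Goodness of fit** — the Poisson deviance
   $2\sum_k [\mu_k - d_k + d_k \ln(d_k/\mu_k)]$ referred to
   $\chi^2_{\mathrm{roi}^2 - 4}$; its upper tail is the reported p-value.
   The test suite verifies the calibration empirically (the rejection rate
   at p < 0.01 is 1 % ± 1 % over 5,000 correctly-modeled ROIs at 1,000
   photons on background 10 — bright enough for the chi-square reference
   law to hold; at very low counts the deviance is conservative).
4. **Filtering** — accepted iff background ≤ 200 photons AND photons ≥
   250 AND p ≥ 0.01. The sources state the threshold values but not their
   boundary semantics; acceptance is inclusive at each boundary, and the
   first failing criterion is recorded as the rejection reason. Filtering
   never reorders rows or mutates fitted values.

## Quantification

*Rendering.* Each accepted localization is a unit-mass Gaussian with
$\sigma_x, \sigma_y$ equal to its CRLBs, truncated at 5σ and renormalized
within the truncation window so image mass equals the localization count
exactly (conservation is the invariant the tests assert). Zoom 10 and the
5σ cutoff are conventions. Localizations with precision worse than one
camera pixel are rendered but flagged, never silently dropped.

*Traces.* Frame sums after subtracting a scalar per-frame offset estimated
as a pixel percentile (default 20th — the behavior of the original
background-offset estimator is not documented, so the percentile is an
exposed parameter), clamping at zero, and normalizing to the trace
maximum. A constant movie normalizes to 1 everywhere by convention.

*Cross-talk.* The ratio of accepted localization counts after vs before
invader treatment. Counts scale with acquisition length, so the two
acquisitions must be equal length under identical filters — the package
requires what the original description leaves implicit. The closed-loop
cross-talk validation labels a ~1,400-site scene, images 2,000 frames,
relabels only a binomial carryover fraction, and compares the recovered
ratio against truth. For that validation the generator uses single-event
photophysics (one on-frame per dye, then photobleached) so each dye
contributes exactly one accepted localization and the after/before ratio
is a direct binomial proportion — the regime in which a
"within 3 binomial standard errors" comparison is the correct yardstick.
With multi-frame blinking the same pipeline recovers the carryover with
per-site yield dispersion on top, which is why the multi-round experiment
reports count CVs rather than binomial bands.

*Registration.* Hardware re-alignment on a saved brightfield image is
replaced by FFT cross-correlation of mean-subtracted reference images with
parabolic sub-pixel peak refinement. `brightfield_reference()` synthesizes
the reference from *all* scene structures (labeled or not), as a real
brightfield image would show the same cell every round. Flat references
are a registration failure, not a zero shift.

## The in-silico experiment

`run_experiment()` chains the stages for N label-image-remove rounds from
one validated config (`validate_config()` normalizes units — "4.87 uM" to
molar, "5 min" to seconds — fills documented defaults, and reports every
violation with its key path before anything is simulated). Between
consecutive rounds it simulates an equal-length carryover-only acquisition
— the after-invader picture — to estimate per-step cross-talk. Fluidics
timing is not simulated; exchange steps exist only through labeling
fractions and the kinetics module. All per-stage seeds derive
deterministically from the config seed, so any report is reproducible
bit-for-bit from its echoed config. The reference six-round configuration
(three rounds per target, clusters and filaments, 2,000 frames per round
at 64×64) is the package's desk-scale analogue of the published six-round
experiment; per-target count CVs under identical labeling come out well
below the 0.15 consistency bound.

```{r}
library(seqstorm)
report <- run_experiment(list(
  scene = list(field_size_um = 6.83,
               structures = list(
                 list(type = "cluster", n = 15, sites_mean = 40,
                      target_id = 1),
                 list(type = "filament", n = 3, length_um = 4,
                      target_id = 2))),
  rounds = lapply(1:6, function(r) list(
    round_index = r, target_id = 2 - r %% 2,
    carryover_residual = if (r %% 2 == 0) 0.05 else 0.02)),
  n_frames = 2000, seed = 42))
report$dispersion
```

## Known limitations

- 2D only: no astigmatism, axial model, or multi-plane support.
- Single-emitter fitting; dense activation is handled by rejection, not
  multi-emitter deconvolution.
- No drift within a round; inter-round shifts are registered but not
  simulated by default.
- The EMCCD excess-noise treatment at the localizer is an approximation;
  quantitative photon statistics should use photon-unit movies.
- The synthetic structures are schematic; passing closed-loop tests
  demonstrates pipeline correctness under the stated generative model,
  not performance on real cellular data.
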