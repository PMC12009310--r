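---
title: "Screen statistics and phenotype quantification in ciliascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screen statistics and phenotype quantification in ciliascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliascreen)
```

## The problem

High-content screens of ciliogenesis measure, per 96-well plate well, the
number of cells and the number of cells bearing a single primary cilium
("cilia incidence"). Compounds or siRNAs that *increase* cilia incidence
without killing cells are candidate therapeutics for ciliopathies such as
polycystic kidney disease. ciliascreen implements the statistical machinery
of such screens — robust z-scores against pooled plate controls, SSMD
quality metrics, per-batch normalised hit cutoffs with cytotoxicity
exclusion, and multi-tier confirmation rules — together with the
downstream phenotype quantifications used to characterise hits (basal body
docking, vesicle trafficking, Hedgehog signalling readouts, acto-myosin
fibre texture, and organoid morphometrics).

Because raw plate and image data of this kind are rarely redistributable,
the package includes a first-class generative simulator whose defaults
encode the study conditions such screens report, so every statistical
claim in the package is testable end to end.

## The plate model

Each 96-well plate carries 8 control roles duplicated in columns 1 and 12
(16 control wells) and 80 test wells in columns 2–11. The roles are three
negative controls (scrambled siRNA, an siRNA with no target in the assay
genome, and a mock transfection), three positive controls for cilia loss
(IFT88, RPGRIP1L and MKS1 knockdowns), a transfection-efficiency control
(PLK1 knockdown, which kills transfected cells), and a spare neutral slot
(`other`). A *batch* is four plates carrying the same test-condition set —
technical replicates — and the whole screen is run in (by default) two
experimental replicates.

## The generative model

For well $w$ on plate $p$ with condition multiplier $m_w$ and incidence
delta $\delta_w$ (percentage points):

$$
N_w \sim \mathrm{NB}\!\left(\mu = \mu_0\, m_w\, e^{\epsilon_p},\ \text{size} = \kappa\right),
\qquad \epsilon_p \sim \mathcal N(0, \sigma_p^2)
$$
$$
K_w \sim \mathrm{Binomial}\!\left(N_w,\ \mathrm{logit}^{-1}\!\big(\mathrm{logit}(\pi_0 + \delta_w/100) + \eta_w\big)\right),
\qquad \eta_w \sim \mathcal N(0, \sigma_w^2)
$$

* **Negative binomial cell counts** (gamma–Poisson): overdispersion is
  universal in imaging-derived cell counts; the dispersion is a
  configuration knob, not an assumption.
* **Logit-scale incidence noise** keeps probabilities in (0, 1) for any
  noise magnitude.
* **Plate factors are multiplicative on the cell mean only**; incidence is
  a within-well ratio and is far less sensitive to plating density, so the
  model leaves it without a plate effect. Batch structure arises from
  plates sharing a condition set, not from an explicit batch random
  effect.
* **One RNG stream per (replicate, plate)**, derived from the master seed,
  so individual plates can be regenerated independently and datasets are
  byte-identical under a fixed seed.

### Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `baseline_incidence` | 0.40 | Synthetic: a typical serum-starved negative-control incidence; the source screens do not publish their negative-control level. |
| `baseline_cells` | 2000 | Imaged cells per well for an 8000-cell seed after ~72 h and field sampling. |
| `cell_dispersion` | 200 | NB size giving a ~7% cell-count CV. Screens of this class report transfection-control cell z-scores of magnitude ≫ 10 for a ~78% kill, which requires a single-digit control CV. |
| `plate_sigma` | 0.05 | A 5% plate-to-plate multiplicative spread, typical of plating/staining drift. |
| `well_sigma` | 0.10 | Logit sd; combined with binomial noise this gives a ~2.6-point incidence sd, small enough that a −9.8-point positive control separates from negative controls by ~4 robust-z units, as a QC-passing assay requires. |
| control effects | −78.4% cells (PLK1), −9.8 (IFT88), −17.1 (RPGRIP1L) points | The screen magnitudes the assay is anchored to. The MKS1 (−12) and PLK1 (−10) incidence deltas are synthetic, chosen within the printed range. |

These defaults were fixed analytically from the constraints above, once,
and are the "study conditions" under which the acceptance checks run.

### What the simulator does not emulate

No pixel-level nuclei/cilia synthesis, no segmentation artefacts, no
spatial (edge/gradient) plate effects, no cross-contamination, no
batch-level incidence drift. Passing tests therefore demonstrate that the
*statistical pipeline* is correct and calibrated under its stated noise
model — not that the pipeline is robust to every failure mode of real
imaging data.

## Robust z-scores and pooling

For measurement $x$ and a pooled control vector $c$:

$$ z = \frac{x - \mathrm{median}(c)}{1.4826 \cdot \mathrm{MAD}(c)} $$

The 1.4826 consistency constant makes $z$ comparable to a classical
z-score under normality; it is exposed (`scale_constant`) with 1.0
available for the unscaled convention, because published screens are
often silent about which was used.

**Pool membership** is explicit: `negatives_only` (scrambled + no-target +
mock; the default) or `all_controls` (adding the positive and transfection
controls, as drug-screen descriptions state). The default is
`negatives_only` everywhere: with positive controls at their realistic
magnitudes, an all-controls pool is strongly bimodal, which makes the
pooled median unstable and the MAD inflate, compressing the z scale.
Both paths are implemented and tested; the choice is a config switch,
never inferred from the data.

**Pooling scope** is likewise explicit: per batch across replicates (a
drug-screen batch is its four plates within the two runs), per
(replicate, batch), or per replicate across all its plates (the siRNA
convention). Scale estimation error matters here: with a 48-well negative
pool per batch, median/MAD noise inflates the expected $|z|\ge 2$ null
tail from the normal 4.6% to ≈ 6.4%; pooling per replicate (hundreds of
negative wells) restores the normal approximation. The package's
calibration checks therefore use the per-replicate scope, and per-batch
pooling should be preferred only when batch effects on the *incidence*
scale are plausible.

**Degenerate controls** (zero MAD) raise a classed error carrying the
batch id rather than being patched with an epsilon: a zero-spread control
set means the assay failed, and silently continuing would fabricate
z-scores.

## QC, cutoffs and hit calling

* **SSMD** between control classes is the method-of-moments estimator
  $(\bar x_{neg} - \bar x_{pos})/\sqrt{s^2_{neg} + s^2_{pos}}$, with the
  conventional bands (2 ≤ SSMD < 3 is "strong").
* **Plate QC** passes a plate iff every positive-control record has
  $z_{cilia} \le -2$ and every negative-control record lies in
  $[-2, +2]$. The pipeline feeds this rule per-(plate, role) *mean*
  z-scores across replicate wells — the convention under which published
  per-plate control points are summarised. Applied to raw per-well
  z-scores the negative-control rule would fail a quarter of all plates
  by construction (negative z's have unit spread), which is not what the
  rule means.
* **Batch cutoffs**: $z_{cilia}$ cutoff = negative-control median + 2;
  $z_{cell}$ cutoff = negative-control median − 2. "Normalisation" is
  median-centring on batch negative controls; the margin of 2 is the
  printed rule.
* **Primary tier**: a condition is a hit iff its mean $z_{cilia}$ (over
  plates and runs) reaches the batch cutoff; it is excluded as cytotoxic
  iff $z_{cell}$ falls at or below the cell cutoff on **more than 2 of
  the 4 plates** of its batch. The plate count is evaluated per run and
  tripping in either run excludes the condition (the combination across
  runs is not specified by the source screens; this interpretation is
  the conservative one and is flagged as such).
* **Confirmation tiers**: hit iff mean $z_{cilia}$ minus the matched
  control's $z_{cilia}$ is ≥ +2 (secondary) or ≥ 1.5 (tertiary), with
  exclusion when $z_{cell} \le -2$.
* **Genome-screen re-filter**: candidate iff $z_{cilia} \ge 2$ in every
  replicate, $-2 \le z_{cell} \le 2$ in every replicate, the siRNA pool
  targets all annotated transcripts, and the gene has a human orthologue.
  Boundaries are encoded inclusively, following the operational
  definitions rather than the occasionally strict shorthand in prose.
  Annotation flags are required inputs for surviving conditions — never
  silently defaulted.
* Every non-hit and every exclusion carries machine-readable reason
  codes; a condition missing a required z value is reported as
  `not_evaluable`, distinct from `not_hit`.

## Phenotype quantifications

* **Basal body docking**: a basal body is docked iff the peak slice of
  the distal-appendage channel is within 2 slices (1 µm at 0.5 µm
  spacing) of the peak slice of the apical channel. Peak ties resolve to
  the lowest slice, deterministically. Peaks are taken per ROI (per
  profile pair), not per whole image.
* **RAB8A trafficking**: per-ROI maximum over the z stack, then the mean
  of per-ROI maxima as the image summary (the per-ROI-first reading of an
  ambiguous procedure; the whole-image mean is also available from the
  per-ROI maxima).
* **SMO occupancy**: total SMO-positive area divided by cilia count,
  which is invariant under splitting and pooling fields of view.
* **Gabor fibre score**: a bank of `n_angles` (default 8) quadrature
  Gabor pairs (Gaussian envelope sd = `scale` = 2 px, wavelength = 8 px,
  orientations uniform over $[0, \pi)$). The even kernel is DC-corrected;
  the image is mean-removed before filtering. Per pixel the magnitude
  $\sqrt{e^2 + o^2}$ is maximised over orientations; the score is the
  mean over the scored region divided by the mean regional intensity.
  Constant images score exactly 0; the unnormalised response is exactly
  offset-invariant, while the normalised score intentionally scales with
  regional intensity (it compensates staining brightness). Kernel phase,
  aspect and aggregation are not published for the proprietary
  implementation this mirrors; the choices here are declared, not claimed
  identical. The default scored region is the image interior at one
  kernel-radius margin, keeping circular-convolution wrap-around out of
  the score.
* **Tubule area**: the printed ellipse formula $\pi a b$, applied
  literally with axes as semi-axes; `axes_are_semi_axes = FALSE` divides
  by 4 for the diameters reading.
* **Cyst counting**: anomalies staged 0–3; stages ≥ 2 count as cysts;
  the per-organoid mean divides by all graded organoids.
* **Dual-luciferase**: per-well firefly:Renilla ratios divided by the
  vehicle-control reference ratio.
* **Dose–response**: per-dose robust z of incidence and cell count
  against the vehicle-well population, plus the fold-change in mean
  incidence relative to vehicle.

## Numerical choices and degenerate inputs

* Median/MAD come from `stats::median`/`stats::mad`; the test suite
  cross-checks them against an independent sort-based implementation to
  1e-12 over 1000 random vectors.
* Zero-cell wells have undefined incidence: they are excluded from
  z-scoring with a message, not imputed.
* All thresholds are compared exactly as written (`>=`, `<=`, strict
  `>`); each boundary has a dedicated test.
* Problem sizes in the shipped checks: the null-calibration run uses 48
  batches × 4 plates × 2 replicates (30,720 test wells); the recovery
  run uses 10 batches with 5% planted activators. These sizes make the
  Monte-Carlo error of the calibrated quantities small relative to their
  acceptance bands while keeping the default check run fast.

## Known limitations

* The simulator's noise cannot be calibrated to reproduce published
  control z magnitudes (e.g. a cell z of −57) because the source screens
  do not publish control MADs; defaults aim for qualitative plausibility.
* `all_controls` pooling is faithful to its description but statistically
  fragile under large control effect sizes (see above); it is provided
  for completeness.
* No spatial plate normalisation (B-score/median-polish/loess) is
  implemented — the screens this package mirrors did not use any.
* Annotation flags (transcript coverage, orthology) are inputs; there is
  no live database lookup.

## A worked run

```{r example}
cfg <- screen_config(n_batches = 2, seed = 7)
wells <- simulate_screen(cfg)
fit <- analyze_screen(wells)
summary(fit)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(fit)
```
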