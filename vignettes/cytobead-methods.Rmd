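---
title: "Models and methods behind cytobead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytobead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobead)
```

## The measurement problem

A single embryonic stem cell recruits a ligand-coated microbead with a
cytoneme, holds it on its membrane, repositions it, and eventually divides
— often with its spindle oriented towards the bead and with cell-fate
markers partitioned unequally between the daughters. The observable record
of this process is a manually tracked time-lapse: per-minute 2D coordinates
of the cell centre, the bead, and a membrane reference point, plus
end-point records (anaphase pole/bead geometry; daughter-cell mean
fluorescence). `cytobead` turns those records into the standard summary
quantities, and provides a generative stand-in for the tracking itself so
the whole chain is testable.

All times are integer minutes starting at 0 (matching 1-min acquisition),
all coordinates micrometres, all geometry 2D — tracked microscopy gives 2D
projections, and we deliberately do not attempt 3D reconstruction.

## The synthetic-data generator

The generator is not a mechanistic cell model; it reproduces the
*statistical structure the analysis assumes*, so that estimator recovery
and test calibration can be verified against known ground truth.

**Bead radial dynamics.** No generative model for bead relocation is
established in this field; what is observed is a "relocate then stabilise"
trajectory of the bead's radius fraction. The simplest process with that
shape is a clamped discrete Ornstein–Uhlenbeck recursion,

$$ r_{t+1} = r_t + k_{\mathrm{reloc}} (r_{\mathrm{eq}} - r_t)
   + \sigma_r \varepsilon_t, \qquad \varepsilon_t \sim N(0,1), $$

clamped to $(0, 1]$, started at the cytoneme-recruitment position $r_0$
(default 0.95, near the membrane). Its stationary mean is
$r_{\mathrm{eq}}$, so window means of the late series estimate
$r_{\mathrm{eq}}$ directly — the recovery property the tests check.

**Waiting times.** First cytoneme, first bead contact, post-uptake contact
loss, and division are geometric waiting times (constant per-minute hazard,
the memoryless discrete-time choice), supported on minutes $1, 2, \dots$,
so a hazard of 1 makes the whole population event-positive from minute 1.
One deliberate exception: within a *single-cell* track the uptake minute is
the waiting time minus one, so a contact hazard of 1 starts contact at
minute 0 and the full observation window lies inside the track.

**Cell motility.** An isotropic Gaussian random walk with per-axis,
per-step SD `cell_step_sigma`; its 1-min MSD is exactly $2\sigma^2$,
giving a closed-form target for the MSD estimator. The membrane reference
point sits on the ray from the centre through the bead at
`cell_radius_um`, making the simulated radius ratio exactly the simulated
radial state.

**Spindle angles.** A two-component mixture: with probability
`angle_mix_p` a bead-oriented component — normal centred at 90° truncated
to $[0°, 90°]$ — otherwise uniform on $[0°, 90°]$. Only angle histograms
are observable in practice, so a truncated normal is as defensible as any
circular family; we parameterise its spread as a concentration in the von
Mises convention, SD $= (180/\pi)/\sqrt{\kappa}$ degrees, so
$\kappa = 30$ (default) gives an SD of about 10.5°. Pole and bead
coordinates are constructed to realise the drawn angle *exactly* (random
location, orientation, spindle length, bead distance, and side of the
minor axis), which makes the geometry module verifiable to numerical
precision: the round-trip error in the tests is below $10^{-6}$ degrees.

**Doublets.** The proximal intensity fraction $p$ is
Beta(`partition_alpha`, `partition_beta`) (default Beta(3, 2): a
proximal-biased population, mean 0.6); intensities are
$I_p = B + pT + \epsilon$, $I_d = B + (1-p)T + \epsilon$ with background
$B$, total partitioned signal $T$ and Gaussian measurement noise. With a
known category mix instead, $p$ is drawn uniformly inside the requested
band, giving exact category ground truth for rate-recovery tests.

**Defaults as study conditions.** Cohorts of 50 cells over 180 min,
relocation rate 0.1/min, radial noise SD 0.02, cell step SD 0.7 µm (1-min
MSD ≈ 1 µm²/min, the magnitude typical of these weakly motile cells), cell
radius 10 µm, oriented-angle weight 0.8. These are fixed as the package's
reference conditions; per-genotype presets would merely move
$r_{\mathrm{eq}}$, hazards and `angle_mix_p`, and no measured per-genotype
relocation rate exists to fit them to — they are illustrative, not fitted.

**What the generator does not emulate:** tracking error and gaps, cell
shape (the membrane reference is one tracked point, not a boundary),
bead-bead interactions, crowding, non-stationary hazards, and any
pixel-level imagery. Passing tests therefore demonstrate that the
*estimators and tests* behave correctly under the assumed statistical
structure — not that real microscopy data satisfies that structure.

## Numerical and boundary conventions

These conventions are load-bearing; each is pinned by a test.

- **Windows** 0–30, 31–120, 121–180 min post-uptake are inclusive integer
  ranges; uptake is re-indexed to minute 0. A partially covered window is
  averaged over the minutes available and flagged, rather than dropping
  the cell; an empty window is `NA`, flagged.
- **Zones**: periphery $> 0.7$, intermediate $(0.3, 0.7]$, centre
  $[0, 0.3]$ — the published ranges overlap at the edges, so we fix the
  half-open convention "upper edge belongs to the inner zone". Ratios
  above 1 are legal (bead and membrane reference are tracked
  independently and need not be collinear) and are flagged, never
  clamped.
- **Retention**: loss at exactly $t_{\mathrm{uptake}}+180$ counts as
  *drops* (window inclusive), so *retains* means strictly beyond; the
  switch sits exactly between contact durations 180 and 181 min. A track
  that ends in contact before the window closes is censored (`NA` +
  flag), not guessed.
- **MSD** uses all overlapping lag-1 displacement pairs; no multi-lag
  diffusion fit, since the quantity of interest is "movement per minute".
  The bead MSD pairs only minutes where both ends of the lag are in
  contact.
- **Rose bins** are right-open with 90° assigned to the last bin; 5° width
  by default (the resolution at which a modal 85–90° class is reportable),
  configurable to any divisor of 90.
- **Randomised-null χ²** uses three 30° bins, expected $n/3$, df 2, no
  continuity correction; an exact multinomial p (enumeration,
  probability-mass ordering) is available for $n < 15$ where the
  asymptotic approximation is doubtful.
- **Fisher's exact** two-sided p follows probability-mass ordering (the sum
  of hypergeometric probabilities of all margin-preserving tables no more
  probable than the observed one) — stated explicitly because other
  two-sided definitions exist. The tests verify equality with independent
  brute-force enumeration, to $10^{-12}$, on every 2×2 table with total
  ≤ 40.
- **K–S p** is asymptotic by default; because angle samples are small and
  discrete, a seeded permutation p (10,000 shuffles by default) is the
  documented alternative.
- **CSV encoding**: absent values are empty fields ($ (0,0) $ is a legal
  coordinate and never means missing), booleans are lowercase
  `true`/`false`, and numerics are written at `%.17g` so a write/read
  cycle is bit-exact and repeated writes are byte-identical. Readers
  reject rather than coerce, naming the offending row, column or cell.

## Calibration and problem sizes

The test suite sizes its simulations to be decisive yet quick, and these
sizes are part of the package's reference conditions: parameter recovery
uses 50-cell cohorts over 180 min (late-window mean within ±0.05 of
$r_{\mathrm{eq}} \in \{0.5, 0.7\}$); MSD recovery uses 100 cells × 180
steps (within 3 SE of $2\sigma^2$); χ² type-I error uses 2000 uniform-angle
replicates at $n = 30$ (rejection rate required within $[0.035, 0.065]$ at
$\alpha = 0.05$); geometry round-trips use 1000 constructed divisions;
Fisher enumeration covers all 135,750 tables with total ≤ 40.

## Known limitations

- The membrane reference is a single tracked point, so the radius ratio
  inherits whatever convention the tracker used for choosing it; ratios
  above 1 are reported faithfully rather than reinterpreted.
- ANOVA/multiple-comparison machinery used for figure-level condition
  contrasts is deliberately not reimplemented; the package exports group
  means ± SEM for use with standard tools, and implements only the exact
  and distributional tests that are integral to the analysis (Fisher, χ²
  against the randomised null, K–S).
- The by-eye doublet allocation performed by independent observers in
  practice has no quantitative counterpart here; only the
  intensity-partition allocation is implemented.
- Whether background subtraction is per image or per slide is a protocol
  detail the data format cannot distinguish; one background value per
  doublet record is assumed.
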