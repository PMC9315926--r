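---
title: "Models and methods in nanodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nanodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nanodyn implements the quantitative chain used in single-molecule studies
of membrane receptor dynamics: single-particle tracking (SPT) of TIRF
movies, short time-lag diffusion analysis, receptor stoichiometry by
intensity calibration, raster image correlation spectroscopy (RICS),
chemotaxis track metrics, and the statistical stage of a lipidomics
workflow. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where a design was genuinely
open. Every stage has a seeded generator with known ground truth, so all
claims here are backed by the package's own tests rather than by numbers
asserted in prose.

## Single-particle tracking

### Image formation model

The SPT generator (`simulate_spt_movie()`) renders point emitters as 2D
Gaussians of width `psf_sigma` (default 0.16 um = 1 px at the default
0.16 um pixel size; the effective PSF of a camera-sampled TIRF system is
close to one pixel). A particle with `n` receptors carries `n`
fluorophores, each with a brightness drawn once from Normal(69.33, 3.26)
a.u. — the monomer calibration scale — and each surviving photobleaching
as an independent exponential (default rate 0.002/s, a slow-bleach
regime appropriate for low-power TIRF at 10 Hz). Noise is Poisson shot
noise on the photon signal plus Gaussian read noise (sd 2 a.u.) on top of
a noiseless electronic camera baseline (default 100 a.u.). The baseline
matters: without it, clipping negative read-noise excursions at zero
rectifies the noise and distorts faint-spot photometry, which real
cameras avoid by design.

Defaults mirror a receptor-imaging acquisition: 10 Hz (0.1 s frame
interval), 500 frames, density well below 4.5 particles/um2 (the
generator refuses higher densities: linking assumptions break down), a
mobile fraction of 0.82 with D = 0.017 um2/s, and an oligomer mix of
40/25/20/15% for sizes 1-4 (65% monomers+dimers, 35% larger). The
default density of 0.5 particles/um2 sits at the sparse end of the
allowed range because both tracking and stoichiometry degrade gracefully
but measurably as spots begin to overlap; stoichiometry fixtures in the
tests use 0.2 particles/um2, typical of sorted low-expression cells.

A note on timing: acquisitions described as "10 Hz" sometimes report
90 ms frames (the difference being readout overhead). The generator
takes the stated rate at face value (dt = 0.1 s) and leaves the interval
fully configurable.

### Detection and sub-pixel localization

`detect_spots()` band-passes each frame (Gaussian matched filter on a
median-filter background estimate of radius 5 PSF sigma — robust to
sparse bright spots), thresholds local maxima at `snr_threshold` times
the robust noise level, and refines each candidate with a
Levenberg-Marquardt 2D Gaussian fit (free amplitude, centre, widths,
baseline). Duplicates within one PSF sigma merge, keeping the brighter.

Integrated intensity is estimated separately from position, by a
split-pixel scheme: the window's checkerboard halves each yield an
independent centre estimate (Gauss-Newton at the nominal PSF width), and
the amplitude is read off each half at the centre fitted on the *other*
half. A centre fitted jointly with the amplitude on the same pixels
chases noise, inflating faint-spot intensities by several percent at
single-fluorophore SNR; splitting the pixels removes that correlation
exactly, and the residual mis-centring attenuation is corrected using
the disagreement between the two half-centres, an unbiased per-spot
estimate of the centring variance whose attenuation cost is computed
numerically for the actual window geometry. On noise-free data the
estimator is exact; at default noise the residual bias is about -1% for
monomers and vanishes for brighter spots (measured in the test suite).

Positions are 0-based pixel coordinates; `x` is the column (fast) axis
everywhere, including all CSV output.

### Linking

`link_trajectories()` solves, per frame pair, the optimal assignment on
squared displacements with birth/death entries at `max_disp`^2 (Hungarian
algorithm, compiled). A second assignment pass closes gaps up to
`max_gap` frames. This per-frame-pair linear assignment is simpler than
global multi-hypothesis trackers; at the densities this package targets
it recovers over 99% of ground-truth links (a property test), which is
the regime the original studies operate in by selecting low-expression
cells. Trajectories shorter than `min_length` (default 20, the
stoichiometry averaging window) are dropped.

## Trajectory dynamics (D1-4, mobility)

The time-averaged MSD uses overlapping windows and only displacement
pairs whose frame difference equals the lag, so gapped trajectories
contribute no spurious jumps. D1-4 is the slope/4 of an unweighted line
through lags 1-4 (2D lateral diffusion; MSD = 4Dt + 4*sigma_loc^2), the
intercept estimating four times the squared localization error. Negative
slopes are kept as-is — truncating them would bias the population median
that the downstream comparisons rest on.

The mobile/immobile cutoff is never hard-coded:
`calibrate_immobile_threshold()` simulates immobile particles at matched
localization noise and returns the 95th percentile of their apparent
D1-4, fixing the false-mobile rate at 5% by construction. Population
summaries report the median D1-4 *of the mobile subset only*; including
immobile particles would drag the median toward the noise floor and is a
regression-tested error mode. Group comparisons use a two-tailed
Mann-Whitney test on mobile D1-4 and a chi-square test (no continuity
correction) on mobility counts.

## Stoichiometry

Mean spot intensity (MSI) is the arithmetic mean of the first 20
background-subtracted integrated intensities of a trajectory — early
frames, before photobleaching has removed much signal. The monomer
reference can come from a monomer-control acquisition (a membrane
protein known to be monomeric) or from self-calibration on traces
showing exactly one downward photobleaching step
(`count_bleach_steps()`: greedy changepoint insertion, accepted while
the residual reduction exceeds a BIC-style penalty with the noise
variance estimated from first differences — robust to the trace's own
steps). `fit_monomer_reference()` fits a Gaussian to the MSI histogram
(Freedman-Diaconis bins) after discarding gross outliers beyond 5 robust
sds (overlapping particles produce a long right tail the Gaussian model
does not describe), and warns when a two-component Gaussian mixture is
clearly preferred by BIC — a contaminated reference.

Receptor number is `round(msi / monomer_mean)`, clamped at 1; rounding
rather than flooring keeps errors symmetric around integer
stoichiometries. Particles with three or more receptors count as
nanoclusters. Group comparisons use chi-square on class counts and
one-way ANOVA with Tukey's test on MSI.

Known limitation: no correction for immature/dark fluorophores, so
estimated receptor numbers are lower bounds on true stoichiometry in
real data; on synthetic data all fluorophores are bright, which is
exactly what lets the class-accuracy tests isolate measurement error.

## RICS

The raster simulator advances Brownian particles between scan lines
(per-pixel mode exists but at membrane diffusion a particle moves far
less than a pixel per 4 us dwell, so per-line is the default) under
periodic boundaries, preserving stationarity. Beam profile is
exp(-2 r^2 / w0^2); "particles per beam area" uses area pi w0^2, the
convention that makes the fluctuation amplitude G(0) = 1/N exactly.

The spatial autocorrelation (`compute_acf()`) is computed per frame by
zero-padded FFT with per-lag overlap normalization (no circular
wrap-around; verified against a direct double-loop oracle to 1e-10),
normalized by the squared mean intensity, and averaged over frames. The
zero lag carries the shot-noise spike and is excluded from fitting.

The fitted model is the 2D membrane form

G(xi, psi) = offset + G0 (1 + 4 D tau / w0^2)^-1
exp(-(dr^2 (xi^2 + psi^2) / w0^2) / (1 + 4 D tau / w0^2)),

with tau = tau_p |xi| + tau_l |psi|: the raster scan turns spatial lags
into time lags, slow along lines and fast along pixels. No axial term is
included (the reporter is membrane-bound); the beam waist defaults to
w0 = 0.25 um, typical for 488 nm excitation through a high-NA water
objective, and is echoed in every fit because results scale with w0^2.
Line time is rarely stored in image files; it defaults to row width x
dwell and is configurable (real scanners add flyback).

### Detrending and the moving-average transfer function

Cellular motion and immobile structure are removed by subtracting a
centred moving average of 10 frames (mean preserved for normalization).
This has a subtle cost at membrane diffusion: consecutive frames are
*not* independent (a particle moves about 9 px between frames at
D = 0.5 um2/s), so the subtracted average correlates with each frame and
the detrended ACF is distorted by a broad, frame-lag-coupled kernel. Fit
naively, this drives the diffusion estimate to zero. `fit_rics()`
therefore models the detrended ACF exactly:

G_det = G(tau) - (2/W) sum_j G(tau + |j| T) + (1/W^2) sum_jk G(tau + |k-j| T),

where W is the window, T the frame period, and each term is the
space-time correlation kernel at the appropriate extra time lag. The
inter-frame terms turn out to carry diffusion information of their own,
which is why the recovery tests pass even at D = 0.1 um2/s, where the
within-frame lag range alone is barely informative. `rics_analyze()`
applies this automatically, samples several random ROIs per stack
(mirroring the practice of analysing a few cytoplasmic areas per cell),
and averages the per-ROI fits.

Fits are nonlinear least squares (Levenberg-Marquardt) over lags within
a radius of 16, amplitude initialized from the smallest nonzero lags,
D from 0.5 um2/s; non-convergence or an amplitude indistinguishable from
zero is flagged in the result rather than raised. One caveat the tests
encode: G is monotone decreasing in D only near the beam centre — at
spatial lags beyond the waist, diffusive broadening can raise the
correlation — so sanity checks live at small lags.

## Chemotaxis metrics

Per cell, over positions sampled every 2 minutes: accumulated distance
d_acc, Euclidean end-to-end distance d_eu, net displacement along the
gradient axis (default +x, where the chemoattractant reservoir sits),
FMI_par = x_net / d_acc and FMI_perp = y_net / d_acc, and straightness =
d_eu / d_acc. This is the convention of the widely used chamber-assay
analysis tools, adopted because the assays the package addresses report
exactly these quantities. The gradient axis travels with the data (a
CSV column), so tracks recorded in other orientations are rotated, not
re-coded. Stationary tracks have undefined metrics and are flagged;
tracks shorter than 10 steps are excluded from group statistics by
default because ratio metrics explode in variance for short tracks.
Groups are compared by one-way ANOVA with Tukey's test on FMI_par and
straightness.

The track generator draws each step along +x with probability beta, and
otherwise turns from the previous heading by an angle uniform on
(-pi (1 - p), pi (1 - p)) with persistence p (p = 0 is isotropic);
step lengths get multiplicative lognormal jitter. beta = 0 yields an
unbiased walk (mean FMI consistent with zero, a property test);
beta = 1 with no jitter yields exactly straight +x tracks.

## Lipidomics statistics

The pipeline order is fixed and regression-tested: internal-standard
normalization, then the QC coefficient-of-variation filter *on
normalized values*, then group testing. Each species is divided by its
ion mode's internal standard in the same sample (positive and negative
modes have separate standards), which cancels per-sample multiplicative
drift — the generator plants such drift to prove it. Species with CV of
at least 10% across pooled QC injections are dropped and listed.

Testing: technical duplicates are averaged per biological replicate
first (five test units per group by default — testing duplicates as
independent samples would be pseudo-replication; configurable), then a
two-sided Mann-Whitney test per species, exact where sample size and
ties allow. Shapiro-Wilk normality p-values are reported per group but
do not gate the test — the nonparametric test is valid either way, and
gating on normality at n = 5 would be noise acting on noise.
Benjamini-Hochberg adjustment runs across all tested species at
alpha = 0.05; the significance flag requires both p and q at or below
alpha. Fold change is the ratio of arithmetic means of normalized
intensities (log2 also emitted).

A granularity fact worth knowing at this design size: with five units
per group the smallest exact Mann-Whitney p-value is 2/252 = 0.0079, so
a *single* changed species among 40 can never clear an FDR of 0.05 —
its best q is 0.0079 x 40 = 0.32. Detection at this sample size is only
possible for class-wide perturbations (several species moving together,
as lipase treatments produce), which is what the recovery tests and the
acceptance script simulate (10 of 40 species at 8-fold).

## What the generators do and do not emulate

The generators reproduce the acquisition geometry, counting statistics,
bleaching, drift, and planted effect sizes of each assay, which is what
validates estimator correctness. They do not emulate anomalous or hop
diffusion, axial motion, sCMOS pixel-dependent noise maps, dark
fluorophore fractions, cell-shape-dependent backgrounds, or
retention-time artefacts in the lipidomics stage. Passing tests
therefore demonstrate that the estimators recover known truth under the
stated model, not that the model captures every property of real data.

## Problem sizes

The test suite and acceptance script use: 1,000-2,000 direct-simulated
trajectories for diffusion and mobility recovery; six 96-px, 30-frame
movies each for monomer calibration and for classification (about 200
trajectories per arm); four full 256-px, 200-frame raster series for the
RICS grid; 500 cells for the chemotaxis null; and 100 simulated feature
tables for the FDR check. These sizes put sampling error comfortably
below the tolerances being tested while keeping any single stage to a
few minutes on one core.
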