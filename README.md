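# nanodyn

Quantitative analysis of membrane receptor dynamics from single-molecule
and fluctuation microscopy, plus the statistical stage of a lipidomics
workflow. The package is aimed at labs asking how a membrane
perturbation (for instance, enzymatic conversion of sphingomyelin to
ceramide) changes a receptor's lateral mobility, its nanoscale
oligomerization, the fluidity of the membrane around it, and the cell's
ability to migrate up a chemoattractant gradient.

Five analysis chains, each paired with a seeded synthetic-data generator
with known ground truth:

- **Single-particle tracking** — sub-pixel spot detection in TIRF movies
  (Gaussian fitting with a split-pixel intensity estimator that stays
  unbiased at single-fluorophore SNR) and optimal frame-to-frame linking
  (Hungarian assignment with gap closing).
- **Trajectory dynamics** — time-averaged MSD; the short time-lag
  diffusion coefficient `D1-4 = slope/4` of a line through the first
  four MSD lags (2D membrane diffusion, `MSD = 4Dt + 4σ_loc²`);
  mobile/immobile classification against a noise-calibrated threshold
  (95th percentile of apparent D on simulated immobile particles);
  Mann-Whitney and chi-square group comparisons.
- **Stoichiometry** — mean spot intensity over the first 20 frames of
  each trajectory, a monomer reference from Gaussian fitting of
  validated single-fluorophore intensities (single photobleaching step,
  or a monomer control), receptors per particle as
  `max(1, round(MSI / μ_mono))`, and the monomer+dimer (≤2) versus
  nanocluster (≥3) split.
- **RICS** — raster image correlation spectroscopy: the 2D spatial
  autocorrelation of a confocal scan carries a hidden time axis
  (`τ = τ_p|ξ| + τ_l|ψ|`), and fitting
  `G = G0 (1+4Dτ/w0²)^-1 exp(-δr²(ξ²+ψ²)/w0² / (1+4Dτ/w0²))`
  recovers membrane diffusion. The fit models the moving-average
  detrending transfer function exactly, which keeps slow diffusion
  identifiable.
- **Chemotaxis** — forward migration index (`FMI = x_net/d_acc` along
  the gradient), straightness (`d_eu/d_acc`), spider-plot data, and
  ANOVA/Tukey group comparison.
- **Lipidomics statistics** — per-ion-mode internal-standard
  normalization, a <10% CV filter on pooled QC injections, exact
  Mann-Whitney tests on n = 5 biological replicates (technical
  duplicates averaged first), and Benjamini-Hochberg FDR control.

## Worked example

Simulate a receptor movie, track it, and summarize mobility:

```r
library(nanodyn)
cfg  <- spt_sim_config(field_px = 96, n_frames = 40, density = 0.2, seed = 7)
sim  <- simulate_spt_movie(cfg)
trajs <- track_movie(sim$stack, psf_sigma = 1, min_length = 20)
print(trajs)
#> <trajectories> 39 trajectories, 1500 localizations
#>   pixel size 0.16 um, frame interval 0.1 s

set.seed(1)
dyn <- analyze_dynamics(trajs)          # calibrates the immobile cutoff itself
population_summary(dyn, "untreated")
#> <population_summary> untreated: n = 39
#>   mobile 89.7% / immobile 10.3%
#>   median D1-4 (mobile) = 0.0184 um2/s
```

The generator planted 82% mobile particles at D = 0.017 µm²/s; with 39
trajectories the summary lands within sampling error of both. The
lipidomics stage, on a table with two species planted at 8-fold:

```r
tab <- simulate_lipid_table(lipid_sim_config(n_species = 8,
         fold_changes = c(8, 8, rep(1, 6)), seed = 2))
head(as.data.frame(lipid_stats_pipeline(tab))[, c("species","fc","p","q","significant")], 4)
#>      species    fc       p      q significant
#> 1 species_01 8.720 0.00794 0.0317        TRUE
#> 2 species_02 6.469 0.00794 0.0317        TRUE
#> 3 species_03 1.030 1.00000 1.0000       FALSE
#> 4 species_04 0.989 1.00000 1.0000       FALSE
```

`p = 0.00794 = 2/252` is the smallest p an exact rank test can produce
at 5 vs 5 — complete separation of the groups.

An end-to-end run that writes every artifact (TIFF movies, trajectory
CSVs, dynamics/stoichiometry tables, a manifest with checksums) is
`run_pipeline(list(seed = 1, outdir = "out"))`, and
`nanodyn_demo(seed = 1)` reproduces a resting-versus-stimulated
comparison (mobile %, median D1-4, nanocluster fractions) from two
synthetic parameter sets. A thin command-line wrapper with a subcommand
per stage lives at `inst/cli/nanodyn.R`.

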