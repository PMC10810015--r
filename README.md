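# voxeldamage

Radiation-induced **clustered DNA damage** — two or more lesions within one
or two turns of the DNA helix — is the lesion class most strongly linked to
cell killing by high-LET particles, and the hardest to measure. This package
is a desk-scale, semi-empirical surrogate for the track-structure Monte-Carlo
pipeline that estimates it: it converts electron, proton and alpha-particle
tracks traversing 36 nm³ voxels of hydrated DNA (15 base pairs plus a
600-molecule hydration shell) into ionization counts, low-energy-electron
(LEE) spectra, water-radiolysis G-values and, through experimentally measured
yields and cross-sections, into single-strand-break (SSB), base-lesion and
double-strand-break (DSB) tallies. At the cell scale it scores **damage
sites** and **cluster size** for a 4 μm nucleus receiving a fixed 260 keV
(nominally 2 Gy), exposing the LET-fluence trade-off that governs the
biological effectiveness of particle beams.

It is aimed at radiation biophysicists and medical-physics researchers who
want calibrated, reproducible lesion-yield scaling with LET without running
event-by-event transport.

## The model in brief

Per voxel traversal at track-averaged LET `L` (keV/μm):

- deposited energy `E = L·ℓ` eV, `ℓ = 36^(1/3)` nm, split 50/50 between the
  DNA (direct) and its hydration water (indirect);
- mean ionizations `a_p + b_p·L` (slopes 0.10/0.11/0.14 for α/p/e⁻),
  Poisson-distributed;
- expected total lesions `λ_p(L) = max(0, aL² + bL + c)`, a per-particle
  quadratic anchored exactly on published cluster sizes and
  clustered-damage onsets; measured yields decompose `λ` into direct,
  indirect and LEE-mediated parts and give the SSB mean `s(L)`;
- expected DSBs `min(k_D·s(L)²/4, λ/2)`, with `k_D` anchored so one DSB is
  expected at the published minimum LETs (9.0/11.8/15.2 keV/μm for
  e⁻/p/α);
- LEE count `max(0, λ(L) − c_lin·L)/p_LEE`, spectrum a fixed mixture on
  [1, 25] eV peaking at 8–11 eV;
- G-values at 100 ns: piecewise-linear radical curves peaking at 66 (°OH),
  30 (e⁻aq) and 100 (H°) keV/μm; monotone H₂O₂ reaching 1.15 (proton) and
  1.44 (alpha) at each ion's maximum LET.

Per nucleus at fixed dose: `n = 260/(L·4)` tracks, each exposing four
candidate voxels; damage sites `n·4·(1 − e^{−4λ})` (per-track mode, the
convention that reproduces the published tallies) and cluster size `λ`.

Every constant carries a provenance tag (`printed`, `anchored`, `derived`,
`assumption`) in a serialisable calibration set; printed constants cannot be
overridden silently.

## Worked example

```r
library(voxeldamage)

cluster_report()         # benchmark scenarios, per-track site counting
#>    particle energy_mev   let range_um n_tracks cluster_size damage_sites
#>  1 alpha           2   162.4    11.2    0.4002     39.8            1.601
#>  2 alpha           4   103.4    27.1    0.6286     23.1            2.515
#>  3 alpha          50    15.2     1.8    4.276       2.734         17.10
#>  4 alpha         100     8.6     6.4    7.558       1.432         30.13
#>  5 proton          0.5  41.3     8.9    1.574      10.8            6.295
#>  6 proton          1    26.1    24.6    2.490       6.3            9.962
#>  ...
#> 10 electron        0.5   0.2     1.8  325           0.01726       86.7

min_let_for("alpha", "total_lesions", 2)  # clustered-damage onset
#> [1] 11.49995
min_let_for("alpha", "dsb", 1)            # one-DSB threshold
#> [1] 15.19974

decompose_lesions("alpha", 162.4)
#>   particle   let direct_linear indirect_linear   lee ssb_mean base_mean total
#> 1 alpha    162.4         5.630           6.864 27.31    20.91     18.89  39.8
```

Reading the output: a single 2 MeV alpha track (LET 162.4 keV/μm) leaves
39.8 lesions in one voxel — a very complex cluster — but only ~0.4 such
tracks fit into a 2 Gy delivery, so the nucleus contains fewer than two
damage sites. A 100 MeV alpha (LET 8.6) reverses the picture: ~7.6 tracks,
30 damage sites, but barely 1.4 lesions per voxel. Most lesions at high LET
are LEE-mediated (27.3 of 39.8), and about half of all lesions are strand
breaks. Stochastic counterparts (`sample_voxel_damage()`,
`simulate_nucleus()`) reproduce these means and are byte-reproducible by
seed; `plot_cluster_tradeoff()`, `plot_lesion_scan()`, `plot_g_curves()` and
`plot_lee_spectrum()` visualise the result tables, and `tidy()`/`glance()`
summarise fitted objects and the calibration set.

A thin command-line front end lives at `inst/cli/voxeldamage.R`
(`Rscript voxeldamage.R report`, `... thresholds`, `... simulate --particle
alpha --energy 4 --reps 1000 --seed 7`, etc.).

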