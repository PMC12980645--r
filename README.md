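# coilstaple

Staple-site evaluation for crosslinked coiled-coil peptides.

Peptide stapling — covalently bridging two anchor residues with a
macrocyclic linker — can pre-pay part of the entropic cost of folding, but
whether a given site/staple combination stabilizes or destabilizes depends
on geometry. On a parallel α-helical coiled-coil heterodimer A/B (two
34-residue chains tethered by a C-terminal Cys33–Cys33′ disulfide), two
quantities govern the outcome:

- **Unfolded-state constraint**, ΔCβ–Cβ: the stapled-minus-non-stapled mean
  Cβ–Cβ spacing of the anchor pair in the unfolded-temperature ensemble.
  Staples that collapse a wide unfolded separation remove more
  conformational freedom and stabilize more; stabilization is roughly linear
  in ΔCβ–Cβ, and sequence separation (the through-bond loop length the
  staple closes) is a simulation-free surrogate.
- **Folded-state compatibility**: the staple's maximum accessible span must
  cover the native folded Cβ–Cβ spacing of the site. The ~14 Å effective
  reach of the triazole/PEG staples (z4x, x4x) covers e/g′ pairs
  (9.4–11.6 Å) but not f/b′ pairs (16.0–16.3 Å); too-short staples compress
  the fold and destabilize.

The package implements the full evaluation pipeline as tidyverse-style
functions: heptad-register bookkeeping and anchor-pair classification
(`assign_register()`, `classify_pair()`, `loop_length()`), two-state melt
thermodynamics with Gibbs–Helmholtz ΔG and stapling ΔΔG
(`fit_two_state()`, `delta_G()`, `delta_delta_G()`), ensemble anchor-spacing
and per-atom fluctuation statistics (`cb_distance_series()`,
`summarize_series()`, `delta_cb()`, `rmsf()`, `delta_rmsf()`), linear
stabilization models, matched-pair contrasts, a compatibility classifier and
ranked site recommendations (`ddg_vs_dcb()`, `staple_contrast()`,
`classify_compatibility()`, `recommend_sites()`), seeded synthetic
generators with exact ground truth (`gen_melt()`, `gen_folded_ensemble()`,
`gen_unfolded_ensemble()`, `gen_design_dataset()`), and a packaged reference
table of melting and spacing measurements for 15 stapled variants with a
self-reproduction report (`load_table1()`, `reproduce_report()`).

## Worked example

Fit the pooled stabilization model on the reference table and rank candidate
sites for the x4x staple from the non-stapled folded/unfolded spacings:

```r
library(coilstaple)
library(dplyr)

tab <- load_table1()
st  <- filter(tab, stapled)

ddg_vs_dcb(st, "pooled", "sim")[, 1:6]
#>    slope intercept r_squared     n se_slope se_intercept
#> 1 0.0385   -0.0424     0.885    11  0.00463        0.136

staple_contrast(st, "sb_vs_nsb", "sim")[, c("contrast", "mean_diff", "se", "n_pairs")]
#>   contrast  mean_diff     se n_pairs
#> 1 sb_vs_nsb    -0.282 0.0252       5

cands <- tab |>
  filter(!stapled) |>
  group_by(index_a, index_b, pair_class) |>
  summarise(folded_mean = mean(cb310), unfolded_mean = mean(cb450),
            .groups = "drop")
recommend_sites(cands, "x4x", ddg_vs_dcb(st, "pooled", "sim")) |>
  select(index_a, index_b, pair_class, verdict, predicted_ddg, rank)
#>    index_a index_b pair_class verdict      predicted_ddg  rank
#>  1       6       1 sb_eg      compatible         -1.90       1
#>  2       6       8 nsb_eg     compatible         -1.79       2
#>  3      13       8 sb_eg      compatible         -1.57       3
#>  ...
#> 10       7      10 fb         incompatible       -1.39      NA
```

Reading this: stabilization per Å of unfolded-state constraint is
~0.04 kcal mol⁻¹ (slope), one line explains 88.5% of the variance in the
simulated impacts, salt-bridged sites average 0.28 kcal mol⁻¹ more
simulated stabilization than heptad-matched non-salt-bridged ones, and the
recommender ranks distal e/g′ sites (most negative predicted ΔΔG) first
while flagging every f/b′ site — native spacing beyond the ~14 Å reach —
as predicted destabilizing, unranked.

Melt fitting on a synthetic curve shaped like the non-stapled distal
variant (midpoint 39.5 °C, 1% noise):

```r
fit <- fit_two_state(gen_melt(tm = 312.65, dh = 40,
                              t_grid = seq(270, 360, 1),
                              noise_sd = 0.16, seed = 1))
fit
#> Two-state melt fit [synthetic]
#>   Tm  = 312.66 K (39.51 degC) +/- 0.108
#>   dH  = 40.24 kcal/mol +/- 0.713 (van't Hoff, at Tm)
#>   dCp = 0.000 kcal/mol/K (fixed)
```

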