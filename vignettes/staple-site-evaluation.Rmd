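---
title: "Evaluating staple sites on a disulfide-tethered coiled coil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating staple sites on a disulfide-tethered coiled coil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilstaple)
library(dplyr)
```

## The problem

Peptide stapling — covalently linking two anchor residues with a macrocyclic
crosslink — can stabilize a fold, but picking *where* to staple has mostly
been trial and error. A parallel α-helical coiled-coil heterodimer (chains A
and B, 34 residues each, tethered by a C-terminal Cys33–Cys33′ disulfide) is
an ideal test bed: its heptad repeat makes inter-residue spacings predictable,
its disulfide fixes the oligomeric state so folding is effectively
unimolecular, and its thermal unfolding is cleanly two-state. `coilstaple`
implements the quantitative site-evaluation framework this system supports:

1. **Heptad bookkeeping** (`assign_register()`, `classify_pair()`,
   `loop_length()`): cross-chain anchor pairs fall into geometric classes —
   salt-bridged e/g′ pairs (`sb_eg`, e(i) with g′(i−5)), non-salt-bridged
   e/g′ pairs (`nsb_eg`, e(i)/g′(i+2)), and the wider outward-facing f/b′
   pairs (`fb`, f(i)/b′(i+3)).
2. **Two-state melt thermodynamics** (`fit_two_state()`, `delta_G()`,
   `delta_delta_G()`): midpoints, van't Hoff enthalpies, and stapling
   free-energy impacts.
3. **Ensemble anchor-spacing metrics** (`cb_distance_series()`,
   `summarize_series()`, `delta_cb()`, `rmsf()`, `delta_rmsf()`): Cβ–Cβ
   spacing statistics and per-atom fluctuation maps from folded- (310 K) and
   unfolded-temperature (450 K) conformational ensembles.
4. **Stabilization models and site recommendation** (`ddg_vs_dcb()`,
   `ddg_vs_separation()`, `staple_contrast()`, `classify_compatibility()`,
   `recommend_sites()`).
5. **Synthetic generators** (`gen_melt()`, `gen_folded_ensemble()`,
   `gen_unfolded_ensemble()`, `gen_design_dataset()`) with exact ground
   truth, so every stage is testable without downloads or simulation
   engines.

The package ships a reference table (`load_table1()`) of observed and
simulated melting temperatures, stapling impacts ΔΔG, and anchor spacings
for 15 stapled variants and their non-stapled counterparts, and
`reproduce_report()` re-derives every downstream number from it.

## The two-state melt model

The fitted signal model is

$$y(T) = b_f(T)\,\theta(T) + b_u(T)\,[1 - \theta(T)], \qquad
\theta = \frac{1}{1 + K}, \qquad K = e^{-\Delta G/RT},$$

with linear baselines $b_f, b_u$ and the Gibbs–Helmholtz free energy

$$\Delta G(T) = \Delta H\!\left(1 - \frac{T}{T_m}\right)
 + \Delta C_p\!\left(T - T_m - T \ln \frac{T}{T_m}\right).$$

Sign conventions: $\Delta G$ is the free energy of unfolding, positive below
$T_m$; the stapling impact is evaluated at the *non-stapled* counterpart's
midpoint, $\Delta\Delta G = \Delta G_{\mathrm{ref}}(T_{m,\mathrm{ref}}) -
\Delta G_{\mathrm{stapled}}(T_{m,\mathrm{ref}}) =
-\Delta G_{\mathrm{stapled}}(T_{m,\mathrm{ref}})$, so stabilizing staples are
negative.

Choices worth knowing:

* **ΔCp defaults to 0** (fixed, not fitted). The melts this emulates were
  measured in 4 M GdnHCl over narrow transitions, where baseline curvature
  from ΔCp is not resolvable; `fit_dcp = TRUE` frees it.
* **Linear baselines** are standard CD practice and exactly match the
  synthetic generator, so noiseless self-consistency tests recover
  parameters to optimizer tolerance.
* **Units**: Kelvin internally; input below 200 is treated as Celsius and
  converted at the boundary.
* **Uncertainty of ΔΔG** comes from a seeded parametric bootstrap (default
  1000 draws) over both fits' parameter covariances, including the
  uncertainty of the reference midpoint. Whether error propagation or
  resampling is the "right" convention is under-determined by the data we
  emulate; the bootstrap is reproducible and makes no linearity assumption.
* Starting values: baselines from the outer 20% of points, $T_m$ from the
  half-transition crossing of the baseline-corrected signal, $\Delta H$ at
  40 kcal/mol. Fitting uses Levenberg–Marquardt least squares
  (`minpack.lm`).

```{r melt-example}
curve <- gen_melt(tm = 335, dh = 40, noise_sd = 0.2, seed = 1)
fit <- fit_two_state(curve)
glance(fit)
delta_G(fit, 330)   # ~0.60 kcal/mol, folded favored below Tm
```

## Ensemble metrics

Anchor spacing is defined on the side-chain β-carbons. A residue without a
CB atom is a hard, named error — the descriptor is not silently redefined on
CA. Summaries drop an equilibration leg (default cutoff 40 ns; when an
ensemble carries no frame times, frames are spaced uniformly over a nominal
2000 ns, so the cutoff removes the first 2% by frame fraction). The
moving-window smoother mirrors the usual trajectory plot: a 50-point window
is widened to 51 so it is centered, and edge windows truncate.

`rmsf()` superposes every frame onto the ensemble mean structure with an
in-package Kabsch (SVD) rotation, iterating align → mean → realign to
1e−6 Å; the iteration is needed because the mean structure itself depends on
the alignment. Alignment defaults to backbone atoms, which automatically
excludes staple/linker atoms that exist only in stapled variants.
`delta_rmsf()` classifies stapled-minus-non-stapled differences on a ±5 Å
scale and flags atoms without a partner (e.g. a bis-azido PEG linker) as
`uncomparable` rather than guessing a mapping.

The key derived quantity is the **unfolded-state constraint**
$\Delta C\beta$–$C\beta$: the stapled-minus-non-stapled mean anchor spacing
at the unfolded temperature (`delta_cb()`). Distal pairs separate widely
without a staple (the spacing grows with loop length), so a staple removes
more conformational freedom there — more negative values, more
stabilization.

**Staple spans.** `staple_specs()` bundles three span estimates per
chemistry: extended (DFT-style idealized maximum, an overestimate), relaxed
(unconstrained staple in solution), and effective (mean spacing of stapled
pairs in unfolded-temperature ensembles, where the chain pulls the staple
taut — the estimate the compatibility classifier uses). The bundled
effective spans are 13.83 Å (z4x) and 14.20 Å (x4x), following the
source text's assignment; the same data's per-variant values would support
the reverse assignment of those two numbers, and since both round to the
~14 Å working reach, nothing downstream distinguishes them. Treat the
third decimal as decoration, not information.

## Design rules

`classify_compatibility()` is a thresholded comparison of native folded
spacing against effective span, with a +10% `marginal` band. The band is our
choice: a site ~1.4 Å past the nominal span has been observed to remain
weakly stabilizing, so a hard cutoff at the span would be overconfident.

`ddg_vs_dcb()` fits unweighted OLS (weighting by reported standard errors is
deliberately not done — the modeled fits are plain least squares, and the
se values are tiny relative to scatter). Pooled over the 11 e/g′ stapled
records of the reference table it gives $R^2 = 0.885$ (simulated impacts)
and $0.525$ (observed); by class, the observed fits have markedly different
intercepts (sb sites are intrinsically extra-stabilizing in experiment)
while the simulated fits nearly share one line.

`ddg_vs_separation()` swaps the simulation-derived constraint for plain
sequence separation: the through-bond loop length computed by
`loop_length()` as a shortest path over backbones plus existing crosslinks
(the C-terminal disulfide contributes one covalent link, so the A/B loop
closed by stapling (i, j′) is $(33-i) + (33-j) + 1$ residues). For the
dimer, "sequence separation" has no unique definition; the through-disulfide
path is this package's documented one, chosen because it is the physical
cycle the staple closes. Any fixed convention shifts all loop lengths by a
constant and leaves slopes and orderings unchanged.

`staple_contrast()` compares matched variant pairs only: the two dual-staple
sites for x4x vs z4x, and five heptad-matched sb/nsb pairs (matching by
staple where a heptad offers both chemistries). The corresponding
experimental sb-vs-nsb figure published elsewhere used an unstated pairing
and is not reproduced here.

`recommend_sites()` is the prospective workflow: filter candidates by
compatibility, predict ΔΔG from a fitted constraint model using
`span_effective − unfolded mean` as the constraint the staple would impose,
rank ascending. Incompatible sites are never ranked, only flagged
`predicted destabilizing`; marginal sites rank after all compatible ones.

```{r recommend}
tab <- load_table1()
cands <- tab |>
  filter(!stapled) |>
  group_by(index_a, index_b, pair_class) |>
  summarise(folded_mean = mean(cb310), unfolded_mean = mean(cb450),
            .groups = "drop")
model <- ddg_vs_dcb(filter(tab, stapled), "pooled", "sim")
recommend_sites(cands, "x4x", model) |>
  select(index_a, index_b, pair_class, verdict, predicted_ddg, rank)
```

## The synthetic generators

The generators define the study conditions for every property test; their
defaults are fixed once and are not tuned to outcomes.

**Melts** (`gen_melt()`): the exact fitted model plus i.i.d. Gaussian noise.
Default baselines give a ~16-unit transition amplitude, so "1% noise" is
sd ≈ 0.16 signal units. Recovery under those conditions is comfortably
inside the 0.5 K median-error budget (measured ~0.07 K over 100 melts).

**Folded ensembles** (`gen_folded_ensemble()`): an idealized parallel
in-register two-helix dimer — 1.5 Å rise per residue, exactly 3.5 residues
per turn (so the heptad repeats geometrically), helix radius 2.26 Å, CB
placed 1.53 Å radially outward of CA. The axis separation, two helical
phases and an axial offset are tuned by Nelder–Mead from a grid of starts so
the class-mean e/g′ and f/b′ CB–CB spacings hit configurable targets
(defaults 9.9 / 10.9 / 16.1 Å, the folded-temperature class means of the
reference table); unreachable targets are an error, not a silent
approximation. Frames add isotropic per-coordinate Gaussian jitter
(default sd 0.2 Å, giving spacing sds of ~0.3 Å, the order seen in folded
trajectories).

**Unfolded ensembles** (`gen_unfolded_ensemble()`): freely-jointed chains
with a fixed 3.8 Å CA step, grown outward from the tether residues, the two
tether CAs joined by one covalent step. Excluded volume is enforced during
growth — each step resamples its direction until the new CA clears 3.0 Å
from every CA already placed, restarting a dead-ended chain. (Rejecting
whole conformations against the same criterion is hopeless at this size:
near-neighbour i/i+2 pairs alone collide in essentially every freely-jointed
conformation.) A staple cap, by contrast, *is* enforced by exact whole-frame
rejection: frames where the capped pair's CB–CB distance exceeds the span
are regenerated, so the constraint holds by construction. This model
reproduces the one property the analysis depends on — anchor separation
growing as roughly the square root of loop length, collapsing to the span
when capped. It is not a physical model of any real unfolded state: no
temperature dependence, no secondary structure, no realistic local geometry,
and its absolute separations are smaller than simulated 450 K values. Tests
passing on it demonstrate correct *bookkeeping and statistics*, not
force-field fidelity.

**Design datasets** (`gen_design_dataset()`): site records drawn from a
known linear law `ddG = intercept[class] + slope·dcb + noise`, for exact
regression- and ranking-recovery tests.

All generators are bit-reproducible given `seed` (`withr::with_seed`).

## Numerical choices and degenerate inputs

* Comparisons against the packaged reference values use *one unit in the
  last printed decimal* as tolerance wherever the inputs are themselves
  printed rounded values (the recomputed unfolded-constraint column can
  differ from its printed counterpart by up to 0.07 Å on 1-decimal rows for
  exactly this reason, and the pooled simulated $R^2$ computes to 0.885
  against a printed 0.89).
* `fit_linear()` refuses n < 3, non-finite input, and zero-variance x;
  `moving_window_mean()` refuses windows longer than the series; empty
  averaging windows and sub-2-frame RMSF inputs are errors.
* Kabsch superposition guards against collinear alignment selections
  (rank-deficient cross-covariance) and applies the proper-rotation
  determinant correction.
* The reference table is validated on load by row count and a frozen
  cell-sum checksum, so silent edits fail loudly.
* Test problem sizes are chosen for fast, deterministic runs: 100-melt
  recovery batches, 30–300-frame ensembles, 40–120-frame unfolded walks.
  These sizes keep sampling error well inside the asserted tolerances.

## Limitations

* Parallel, in-register dimers only; antiparallel or staggered registers
  and higher-order oligomers are rejected, and register must be supplied,
  not predicted.
* The melt model is unimolecular two-state with linear baselines; chemical
  denaturation (m-values), multi-state coupling, and spectral deconvolution
  are out of scope.
* Molecular dynamics itself is out of scope: the package analyzes ensembles,
  it does not produce them (beyond the idealized synthetic generators).
* The class-specific extra stabilization of salt-bridged sites seen in
  observed data is *described* by the class intercepts, not explained; no
  solvation modeling is attempted.
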