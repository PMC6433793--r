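---
title: "Methods: small-world analysis of functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-world analysis of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

`fcnet` implements the standard graph-theoretic pipeline for resting-state
functional connectivity: each subject's brain is represented by N regional
BOLD time series (N = 90 for the AAL cerebral parcellation), the edge
between two regions is their Pearson correlation, and the weighted matrix is
binarized by keeping the strongest `round(S * N(N-1)/2)` connections by
absolute correlation at each sparsity S of a grid (default 0.10–0.34, step
0.01). At every sparsity the package computes clustering coefficient (Cp),
characteristic path length (Lp), their normalized forms against
degree-preserving random nulls (γ = Cp/Cp_rand, λ = Lp/Lp_rand,
σ = γ/λ), global and local efficiency, and nodal degree / efficiency /
betweenness. Each metric's curve is collapsed to a single
threshold-independent scalar by the composite trapezoid
AUC = (ΔS/2) Σ [Y(S_k) + Y(S_{k+1})]. Group inference residualizes the AUCs
on nuisance covariates (age, sex) by OLS, permutes group labels
(sizes preserved; two-tailed add-one p), and controls the false discovery
rate across nodes with Benjamini–Hochberg, separately per nodal metric
family. Associations with clinical variables use partial correlation with
age and sex partialed out, with p from the t distribution on n − K − 2
degrees of freedom.

## Sparsity range

Two standard criteria bound the usable cost range: the mean degree of every
thresholded network should be at least 2 log(N) (natural log here — the
convention of the small-world literature; base-10 would give an implausibly
low bound of 3.9 edges, and the base is exposed as an argument), and every
network should remain small-world (σ > 1.1). For N = 90 the degree
criterion honestly yields s_min = 0.11 (0.10·89 = 8.91 < 2 ln 90 = 9.00),
yet the conventional published grid starts at 0.10; `select_sparsity_range`
computes the criteria honestly, and the default grid
`sparsity_grid(0.10, 0.34, 0.01)` remains a deliberate, overridable
convention rather than the output of the selector.

## Conventions where the literature splits

* Nodes with degree < 2 contribute clustering 0; nodes with < 2 neighbours
  contribute local efficiency 0.
* Lp on a fragmented network averages over reachable ordered pairs only and
  raises a `disconnected` attribute; efficiency-type metrics give
  unreachable pairs 0 contribution, so they need no special casing.
* Betweenness uses the unnormalized pair-count convention (the star centre
  on 10 nodes scores (n−1)(n−2)/2 = 36); normalization is an option, and
  group comparisons are invariant to the constant factor.
* Binarization rounds the target edge count half-up and breaks |r| ties by
  ascending lexicographic node-pair order, making networks reproducible
  across platforms; thresholded networks are exactly nested across the grid.
* The null model is Maslov–Sneppen double-edge swapping (10 successful
  swaps per edge targeted, attempt budget 20×), which preserves the degree
  sequence exactly and does not enforce connectivity; rigid graphs (e.g.
  complete graphs) are returned unchanged with a warning. Defaults
  n_null = 100 for production use; the bundled acceptance computations use
  10–20 nulls per network, which adds ~3–5% Monte-Carlo noise to γ and λ —
  immaterial against bounds like "γ > 1".
* The permutation p-value uses the add-one correction
  (#{|null| ≥ |obs|} + 1)/(n_perm + 1), so p is never 0; an `exhaustive`
  mode enumerates all label assignments for small cohorts, where p is the
  exact enumeration fraction.
* The trapezoid formula as printed in some papers carries an off-by-one
  summation index; the implementation is the standard composite rule over
  consecutive grid points, the only reading consistent with the usual
  illustration.
* The gender comparison uses the two-sided exact (Fisher) test by default:
  on the canonical 35/20 vs 21/26 table it gives p = 0.0728, matching the
  conventionally printed 0.073, whereas uncorrected Pearson chi-squared
  gives ≈ 0.055. Both chi-squared variants are exposed.

## The synthetic cohort: what it states and what it omits

Because subject-level fMRI from the motivating study design is not
deposited, the package carries a first-class generator whose defaults *are*
the stated world: two groups of 55 patients and 47 controls, 200 retained
timepoints at TR = 2 s (210 acquired minus 10 discarded), signals
band-limited to 0.01–0.08 Hz, ground-truth connectivity a Watts–Strogatz
small-world graph (n = 90, lattice degree 8, rewiring probability 0.1 —
chosen because that regime reproduces γ > 1, λ ≈ 1). Demographics mirror a
typical type-2-diabetes table: age ~ Normal(53.3, 8.5) truncated to
[40, 75], sex Bernoulli with the 35/55 and 21/47 male fractions, and
clinical marginals (BMI, HbA1c, glucose, lipids, MoCA, disease duration)
drawn per group from the published-style means and SDs; control values for
patient-only quantities (HbA1c 5.4 ± 0.4, glucose 5.1 ± 0.5, duration 0)
are normal-range choices made once.

Signals are a Gaussian graphical model: precision P = I + c·A with coupling
c (default 0.25) on the true edges, covariance P⁻¹, then an exactly
zero-phase FFT band-pass. One mathematical correction was required: an
adjacency matrix has negative eigenvalues (λ_min ≈ −4.2 for the default
ground truth), so I + cA is *not* automatically positive definite. The
generator therefore applies the standard ridge shift used by GGM simulators
(P ← P + (0.1 − λ_min)I when λ_min < 0.1), which leaves the off-diagonal
coupling pattern untouched and merely rescales variances; Cholesky still
asserts positive definiteness. Group effects are injected as an additive
coupling increment (default scenario +0.15) on edges incident to designated
nodes — raising those nodes' empirical |r| with their neighbours and hence
their thresholded degree and efficiency, the mechanism behind nodal
case/control differences. A per-subject truncated-normal multiplier
(sd 0.15) on those same incident couplings provides subject-level variation,
and a clinical variable can be generated to correlate with that latent at an
exact target r.

What the generator does **not** emulate: hemodynamic response convolution,
head motion, physiological noise spectra, spatial autocorrelation of
parcels, site/scanner effects, or any image-space artefact. A green test
therefore establishes that the *pipeline* recovers the statistical
structure it assumes — not that the assumptions hold for real BOLD data.

## Numerical choices

* All-pairs distances by BFS and betweenness by Brandes accumulation run in
  compiled code; both are verified exactly (tolerance 1e−12/1e−9) against
  independent pure-R Floyd–Warshall and shortest-path-counting oracles on
  200 random graphs per run, and against igraph on larger graphs.
* Band-pass is brick-wall in the DFT domain: exactly zero-phase (no
  inter-column lag, which matters because correlations are computed across
  columns) and trivially meeting the ≥0.9 pass / ≤0.1 stop contract;
  the 0 Hz bin is removed, so filtered series are mean-free.
* Residualization uses QR; rank-deficient design matrices fall back to an
  SVD pseudo-inverse with a warning rather than failing.
* All cohort-level randomness flows from one integer seed through named
  substreams (simulation, metrics/nulls, permutation), so repeated runs are
  byte-identical.

## Known limitations

* Weighted and directed network variants, modularity, and rich-club metrics
  are out of scope, as are probabilistic (FDR-based) edge thresholds.
* The sigma-criterion upper bound in `select_sparsity_range` is Monte-Carlo
  (it depends on the rewired nulls), so near-threshold grids can move by one
  step between seeds; production analyses should fix the grid explicitly.
* Effect sizes in the simulator are free parameters of the stated world,
  not estimates of any real clinical effect.
* Nuisance regression of demographic covariates is applied once, at the
  inference stage, not also at the time-series stage, to avoid double
  adjustment.
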