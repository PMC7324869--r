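---
title: "Methods: S100A1 gating metrics, WHAM free energies and the calcium-dependent competition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S100A1 gating metrics, WHAM free energies and the calcium-dependent competition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s100gate)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic generators do
and do not emulate, and the numerical and design choices that were
genuinely open.

## The system

S100A1 is a homodimeric EF-hand Ca²⁺ sensor.  Each subunit carries a
high-affinity canonical hand (cEF) and a low-affinity pseudo hand (pEF);
loading both exposes a hydrophobic patch between helices H3 and H4 that
binds regulatory peptides (TRTK12 serves as the model target, standing in
for the PEVK segment of titin).  Because the pEF affinity is far above
cytosolic Ca²⁺, wild-type S100A1 is mostly closed in vivo; redox
modification of Cys85 on H4 can shift the protein toward the open,
binding-competent state.  The package quantifies this chain from three
directions: geometric gating metrics on structures, free-energy profiles
of peptide unbinding, and a macroscopic competition model that converts
binding free energies into physiological dose-response predictions.

## Structural gating metrics

**Opening angle.**  The H3/H4 opening is measured as the angle at the
hinge between two rays: from the geometric centroid of the Cα atoms of
the hinge residues (L61–D62 and Q72–E73) to the Cα of A53 (helix 3) and
of C85 (helix 4), per chain.  The centroid uses Cα atoms only: the ray
endpoints are Cα, so a Cα-only vertex is the consistent reading, and on
Cα sets this is numerically indistinguishable from mass weighting.  Typical
closed-state values sit near 27° and open-state values near 54°.

**Helicity.**  The H4 C-terminal segment C85–S93 reports on activation.
Assignment is the Kabsch–Sander electrostatic model: the hydrogen bond
donated by NH(i) to CO(j) has energy
$E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol and
exists when $E < -0.5$ kcal/mol; a residue is α-helical when it lies in a
stretch supported by two consecutive i→i+4 bonds.  Only the H state is
implemented — the rest of the secondary-structure alphabet is out of
scope.  Missing amide hydrogens are rebuilt 1.01 Å from N opposite the
bisector of the N–C(prev) and N–Cα bonds; residue 1 has no donor.

**Contacts.**  Two residues are in contact when their minimum heavy-atom
distance is ≤ 7 Å; only pairs at least 6 residues apart in sequence are
counted, and inter-chain pairs are always eligible.  The boundary is
closed (exactly 7.0 Å counts) and the atom rule is minimum distance, the
common trajectory-analysis default; neither convention changes any of the
qualitative results but both are fixed here for reproducibility.

**RMSF, superposition, clustering.**  Superposition is least-squares
Kabsch.  RMSF uses one alignment pass: frames are fitted to frame 1, a
mean structure is formed, frames are refitted to the mean, and the
per-residue root mean square deviation over backbone atoms (N, Cα, C, O)
is reported.  Frame clustering is agglomerative with average linkage on
the pairwise best-fit RMSD matrix; representatives are medoids, ties
break toward the lower frame index, and a helper returns the
representatives of the k least-populated clusters (the convention for
seeding further sampling cycles).

**SASA.**  Shrake–Rupley with a deterministic Fibonacci mesh (960 points
per atom by default, probe 1.4 Å).  A mesh point lying exactly on several
expanded surfaces is shared equally among them, so coincident atoms split
their common surface instead of double-counting it; unknown elements fall
back to a configurable default radius with a warning.

**Energy decomposition.**  Per-residue interaction energies arrive as
tables of electrostatic, van der Waals and solvation terms per frame (the
solvation evaluation itself is upstream and out of scope).  The package
computes the ensemble average of the residue totals in the dimer minus
the monomer containing that residue; bonded terms are excluded upstream
because they cancel between dimer and monomer.  Summed over residues this
reproduces the total ⟨G_dimer⟩ − ⟨G_monomer⟩ of the same tables.

## PMF reconstruction by WHAM

Umbrella windows restrain the reaction coordinate — the distance between
the mass-weighted Cα centre of mass of the peptide and that of the
binding cleft (H3 C-terminus K30–T39 plus H4 N-terminus E73–A84) — with a
harmonic bias.  The default layout is 49 windows from 9.5 to 33.5 Å at
0.5 Å spacing with force constant 18 kcal/mol/Å².  Two bias conventions
exist in the wild; the default here is $U_i(z) = \tfrac{K}{2}(z-z_i)^2$
(the colvars convention of the engine such simulations are typically run
with), with `bias_convention = "full"` switching to $K(z-z_i)^2$.

The weighted histogram equations are solved by fixed-point iteration on
the window free energies $f_i$ (gauge $f_1 = 0$), with bin width 0.1 Å,
convergence tolerance $10^{-10}$ kcal/mol on $\max_i |\Delta f_i|$ and an
iteration cap of $10^5$; non-convergence is an error that reports the
residual, and bins never visited are returned as `NA` rather than
extrapolated.  The profile is anchored so $\min G = 0$; all comparisons
between profiles should treat the additive constant as a gauge freedom.
WHAM uses RT = 0.596 kcal/mol (300 K, the simulation temperature), which
is deliberately distinct from the calibration RT below.

**Error estimators.**  Two independent routes:

1. *Monte-Carlo bootstrap* (30 trials by default): every window's samples
   are resampled with replacement, WHAM is re-solved on the same grid,
   and the per-bin standard deviation over trials is reported.  Each
   trial must be re-anchored; the default anchors at the minimum, and the
   `"tail"` option anchors on the unbound plateau — defined as the mean
   over the occupied bins in the last 2 Å of the sampled range, because
   the single outermost bin holds only a handful of samples and its shot
   noise would otherwise dominate every bin's spread.
2. *Block-averaging / mean-force propagation*: the variance of each
   window's mean coordinate is estimated by block averaging (block size
   200, trailing partial block dropped, variance of block means divided
   by the number of blocks).  In window i the mean restraint force is
   $\kappa(z_i - \bar x_i)$ with $\kappa = K$ under the half convention,
   so $\sigma(\bar x_i)$ maps to a mean-force uncertainty
   $\kappa\sigma$.  The free-energy difference from the reference window
   to window m is the trapezoid integral of the mean force over window
   centres, and its variance is the quadrature sum of the per-window
   contributions with trapezoid weights — monotone non-decreasing away
   from the reference end.  This is the standard mean-force reading of
   block-averaged window statistics; the two estimators agree in
   magnitude on well-sampled fixtures (the test suite checks a factor of
   3) without being interchangeable pointwise, since they anchor
   differently.

**Binding free energy.**  ΔG is the profile value at the bound-state
minimum (searched inside a user-given bound region, typically around the
14 Å well) minus the mean over an unbound plateau region; errors
propagate in quadrature from the two locations.  No standard-state volume
correction is applied.

## The competition model and its calibration

At clamped (buffered) free Ca²⁺ — concentration $10^{6-\mathrm{pCa}}$ µM,
never depleted by binding — S100A1 distributes over apo, half-saturated
and fully saturated states with sequential two-site weights
$1 : [\mathrm{Ca}]/K_{cEF} : [\mathrm{Ca}]^2/(K_{cEF}K_{pEF})$
(defaults 27 and 250 µM, the tight ends of the reported ranges).  Actin
and PEVK associate with dissociation constant $K_{AP}$, while each free
S100A1 state competes for PEVK with its own constant ($K_{d1}, K_{d2},
K_{d2'}$; fitted reference values 0.52, 0.13, 0.03 µM).  Two variants
mirror the competing mechanistic readings: in variant 1 the
half-saturated state does not bind, in variant 2 (default) all three
states bind.

Because calcium is buffered, the free-S100A1 pool keeps fixed state
fractions and the whole scheme collapses to one monotone conservation
equation in free PEVK, solved by bracketing plus Newton polish;
conservation of S, A and P and every reported mass-action quotient hold
to better than $10^{-9}$ relative, and an independent bisection oracle in
the test suite confirms the solution on random parameter draws.
Parameterising only the independent constants closes all thermodynamic
cycles automatically (peptide binding shifts the apparent Ca²⁺ affinity
by the corresponding Kd ratios; no separate constants can be set
inconsistently).  Two prominent conventions: concentrations are *site*
concentrations (one peptide site per subunit of the dimer), and the
governing scheme treats the S100A1 states as competing for free PEVK —
thermodynamically equivalent to reading the states as engaging the
actin-bound complex and displacing actin.

**Calibration.**  Free-energy methods rank states well but overestimate
absolute binding; computed dissociation constants are therefore mapped
onto the experimental scale by
$\lambda = e^{(\Delta G_{expt} - \Delta G_{calc})/RT}$, applied as
$K_{D,expt} = \lambda K_{D,calc}$.  The calibration uses RT = 0.593
kcal/mol (≈ 298 K): this is the value consistent with the reference
factor λ ≈ 157.4 from the (−6.5, −9.5) kcal/mol pair, and it is kept
separate from the 300 K WHAM temperature; both are configurable.  A
post-translational modification with computed free energies
$\Delta G_{mod}$ vs $\Delta G_{WT}$ then scales the Ca²⁺-activated
constants by $\lambda e^{(\Delta G_{mod} - \Delta G_{WT})/RT}$ — with
(−12.9, −7.6) this gives ≈ 0.021, a ~48-fold affinity gain, applied to
$K_{d2}$ and $K_{d2'}$ (the apo constant is left untouched).

**Fitting.**  Nonlinear least squares on $\log_{10} K_d$ with bounds
$[10^{-4}, 10^3]$ µM, fitted jointly across curves at different pCa;
confidence intervals come from seeded residual-resampling bootstrap (200
replicates by default).  Identifiability is checked directly: a parameter
whose ±0.3-decade perturbation leaves the residual sum of squares
essentially unchanged is flagged, which is exactly what happens to
$K_{d2'}$ when no curve populates the fully saturated state.

An identifiability point worth stating explicitly: at clamped calcium the
three states enter each curve only through the single combination
$\sum_s f_s/K_{d,s}$, so one pCa condition determines one effective
affinity.  Resolving all three constants requires at least three
conditions with distinct state mixtures; resolving them *precisely* at
realistic noise requires conditions where each state dominates somewhere.
The packaged simulation study therefore spans pCa 7, 5, 4 and 3 (resting
to saturating calcium — the mixtures are approximately apo-dominated,
apo/half, half/full and full-dominated respectively) with 24 doses per
curve across 0.03–31.6 µM S100A1 at 2% Gaussian noise on the bound
fraction.  This design came from a power analysis of the estimator: with
fewer conditions or sparser doses the anticorrelated $K_{d2}/K_{d2'}$
errors exceed ±25% at the same noise, while the packaged design keeps
every parameter's sampling error within ±15% across surveyed seeds.

## Synthetic data: what it does and does not emulate

The generators exist so each analysis stage can be tested against known
ground truth, at desk scale, with no downloads; every generator is a pure
function of its mandatory seed and attaches its ground truth to the
output.

* `sample_umbrella_windows()` draws from the *exact* biased Boltzmann
  density of a known 1-D potential by Metropolis sampling — equilibrium
  statistics are all WHAM consumes, so no dynamics are simulated.  The
  proposal standard deviation (0.45 Å ≈ 2.4 times the biased-density
  width at the default force constant, the classic 1-D random-walk
  optimum) and the thinning stride of 8 (measured lag-8 autocorrelation
  ≈ 0.02, so retained samples are effectively independent, as the
  frame-saving stride of a long MD window would make them) are sampler
  quality settings, not physical parameters.  The default double-well
  potential places a 9.5 kcal/mol bound well at 14 Å and a 2 kcal/mol
  intermediate at 20 Å on a flat plateau — a scale choice mirroring a
  realistic peptide-dissociation profile, not a claim about any
  particular system's curve shape.
* `build_helix_coords()` builds ideal polyalanine backbones (standard
  bond geometry, uniform φ/ψ, trans peptide bonds, amide H included) —
  enough to exercise secondary-structure assignment and geometry metrics,
  with none of a real protein's side chains or disorder.
* `generate_binding_curves()` adds i.i.d. Gaussian noise to model-exact
  dose-response curves and clips to [0, 1]; real assay noise is neither
  homoscedastic nor independent of the mean.
* `generate_energy_tables()` plants known per-residue interaction
  offsets over noisy baselines.

Passing tests on these fixtures demonstrates that the estimators are
correct and well-calibrated *for data matching their assumptions*; they
say nothing about force-field accuracy, sampling convergence of real
trajectories, or experimental systematics.

## Numerical choices and degenerate inputs

* WHAM: bin width 0.1 Å, tolerance $10^{-10}$, cap $10^5$ iterations;
  empty bins `NA`; a histogram gap between adjacent windows warns.
* Multi-model structures default to model 1 (a deterministic choice where
  the convention is unstated); altloc records keep the highest occupancy,
  first on ties; hydrogens are retained when present.
* Hydrogen-bond counting defaults: donor–acceptor cutoff 3.5 Å, D–H···A
  angle ≥ 135°.
* Block averaging requires at least two complete blocks and drops the
  trailing partial block rather than padding it.
* Equilibrium solver: bracketed root plus Newton polish; a residual above
  $10^{-9}$ relative is an error, never a silent result.  Degenerate
  inputs (zero totals, disabled states, infinite Kd) reduce to the
  correct closed forms.
* Angle definition: coincident ray and vertex positions are an error; the
  arccosine argument is clamped to [−1, 1] against roundoff.

## Problem sizes used by the test suite

The quantitative checks run at: 49 windows × 10⁴ retained samples for the
WHAM accuracy and error-estimator comparisons (reconstruction RMS below
0.15 kcal/mol against the generating potential; well depth within 0.2
kcal/mol; bootstrap with 30 trials); 100 random parameter draws for the
equilibrium solver against the bisection oracle; and the four-condition,
24-dose design above for affinity recovery.  These sizes were chosen so
the statistical power matches the assertions being made, and they keep
the full suite in the minutes range on a single core.

## Known limitations

* WHAM is strictly 1-D; the angular restraints used in real umbrella
  setups are not modelled, and no multidimensional or MBAR estimator is
  provided.
* The DSSP implementation assigns only the α-helix state.
* The competition model is equilibrium-only — no kinetics, no sarcomere
  mechanics, no titin-isoform detail — and buffered calcium is assumed
  throughout (appropriate for chelator-buffered assays, not for
  unbuffered transients).
* Whether fitted constants are per monomer or per dimer is a convention;
  this package fixes site concentrations per subunit and all reported
  constants inherit that convention.
* The SASA and DSSP routines are validated on constructed geometry; for
  crystallographic edge cases (alternate conformers, chain breaks,
  unusual residues) they apply the documented fallbacks rather than
  attempting chemistry-aware repair.
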