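---
title: "Multi-site Cu(II) binding analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site Cu(II) binding analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuepr)
```

# The scientific problem

Serum albumin is the dominant copper carrier and buffer in plasma. Beyond
the well-known high-affinity N-terminal ATCUN motif (the free amine, two
deprotonated backbone amides and the His-3 imidazole nitrogen in a
square-planar arrangement), albumin binds Cu^2+^ at several secondary
sites built from histidine and carboxylate side chains: the established
sites A (His67/His246/Asp248) and B (His9/Asp13) and further sites at
His287, His317 and His509. Whether several of those sites are occupied
*simultaneously* is not decidable from a crystal structure alone, because
crystallographic occupancy averages over the lattice. Pulsed dipolar EPR
(here RIDME) measures the distribution of Cu--Cu distances within single
molecules in frozen solution, and comparing that distribution with the
pairwise distances between the crystallographic Cu positions turns the
structure into a testable multi-site occupancy model.

`cuepr` implements that complete analysis chain on synthetic and real
inputs: structure geometry, the occupancy forward model, CW EPR powder
simulation for the titration argument, ESEEM/HYSCORE processing for the
ligand-identity argument, and RIDME simulation plus regularized inversion
for the distance argument.

# Structure geometry

`parse_structure()` reads PDB or mmCIF coordinates through `bio3d`,
keeping heteroatoms and waters, resolving alternate locations (highest
occupancy wins; ties go to altloc A; first model only) and recording the
unit cell and Hermann--Mauguin symbol. `detect_metal_sites()` treats
every Cu atom as a site and collects N/O/S donors within a cutoff.

* **Donor cutoff, 3.0 Å (default, configurable).** Cu--N and Cu--O
  coordination bonds cluster near 1.9--2.3 Å; 3.0 Å admits thermally
  smeared donors without picking up second-sphere atoms. Hydrogens are
  never donors; water oxygens are (site A coordinates two waters).
* **Canonical labels.** Detected sites are mapped to
  ATCUN/siteA/siteB/H287/H317/H509 through the donor residue numbers
  listed above, so occupancy configurations are nameable; unmatched
  sites get `siteN` labels. Sites are ordered by their first donor
  residue number.
* **Distances.** `pairwise_distances()` returns the symmetric Cu--Cu
  table in nm (Å × 0.1 exactly). `count_disulfides()` pairs CYS SG atoms
  greedily from the shortest distance up (each SG used once), which is
  exact for the well-separated bridges of a folded protein.
* **Symmetry contacts.** `min_symmetry_contact()` applies the embedded
  general-position operators (P1, P61, P212121) plus lattice
  translations in a ±1 cell shell, using the standard a-along-x
  orthogonalisation. The N-terminus of an albumin crystal is often
  ordered only because a symmetry mate packs against it, so the minimum
  selected-atom-to-image distance is a quantity of direct interest.

# The occupancy forward model

A configuration is a subset of at least two occupied sites. Its
predicted distance distribution is a Gaussian mixture with one component
per unordered pair: mean = crystallographic Cu--Cu distance, common
standard deviation σ = 0.1 nm, equal amplitudes (the model deliberately
refuses to fit per-site occupancies — with six sites and broad peaks the
data cannot constrain them). `enumerate_configs()` generates subsets of
size 2--6 by default: pairs up to the full six-site configuration, 57 in
all for six sites.

Configurations are compared with an experimental distribution by the
histogram overlap coefficient `∫ min(P_sim, P_exp) dr`, restricted to a
detectability window of 1.5--8.0 nm: below ~1.5 nm dipolar oscillations
are too fast for reliable pulsed-dipolar detection, and beyond ~8 nm they
are too slow for the achievable trace length. The overlap score is
symmetric, unit-free and bounded in [0, 1], which is all that a
qualitative ranking argument needs; `rank_configs()` orders
configurations by score with deterministic tie-breaks (smaller
configuration first, then lexicographic).

# CW EPR powder engine

Axial Cu^2+^ (S = 1/2, one effective I = 3/2 nucleus, no ^63^Cu/^65^Cu
splitting) at orientation θ has effective values
g(θ) = √(g∥²cos²θ + g⊥²sin²θ) and likewise A(θ). The four ΔmS = 1 lines
sit at

B(m_I) = B₀ − m_I·a − a²·[I(I+1) − m_I²] / (2B₀),

with B₀ = hν/(g(θ)μB) and a the coupling in field units. The
second-order term *lowers* every resonance field; against numerical
diagonalization of the full 8×8 spin Hamiltonian the expression is
accurate to ~0.3 G at g∥ = 2.198, A∥ = 607 MHz and 9.5 GHz (the ATCUN
parameter regime, where a ≈ 197 G is far from negligible). We
deliberately evaluate the denominator at B₀ rather than self-consistently:
iterating happens to *worsen* the agreement in this regime because the
resummed third-order term enters with the wrong sign for these m_I.

The powder average integrates in cosθ with Gauss--Legendre nodes (301 by
default; the sinθ weight is absorbed by the substitution), deposits
stick intensity on the field grid with linear splitting between
neighbouring points, convolves with a Gaussian of configurable FWHM and
differentiates numerically (field modulation detection). There is no
1/g intensity correction and no A/g-strain; both affect relative
amplitudes only and none of the analyses here depend on them.

**Double integration.** The derivative trace is offset-corrected by the
mean of its first and last 2% of points; the absorption obtained by one
trapezoidal integration is then corrected by the straight line through
the means of *its* first and last 2% of points before the second
integration. The absorption-level correction matters: a residual offset
in the derivative becomes a ramp after one integration, and anchoring
the absorption edges also suppresses the random-walk accumulation of
white noise, which would otherwise dominate the double integral of a
2667-point spectrum. With it, a synthetic titration with 1% noise keeps
the double-integral-vs-equivalents fit above R² = 0.99.

The synthetic titration (`make_cw_titration()`) mixes an ATCUN-like
species (g∥ = 2.198, A∥ = 607 MHz) whose weight saturates at 1 molar
equivalent with a secondary His/O-type species (g∥ = 2.30,
A∥ = 480 MHz) taking up the remainder, so the total double integral is
exactly proportional to added Cu^2+^ — the construction mirrors the
experimental argument that all added copper stays EPR-active while the
high-affinity site fills first. The perpendicular tensor components are
not printed in the main-text parameter set; the generator uses typical
type-2 Cu values (g⊥ ≈ 2.05, A⊥ tens of MHz), which affect line shapes
but none of the tested quantities.

# ESEEM and HYSCORE processing

Three-pulse ESEEM traces are divided by their fitted exponential
background — `(data − b)/b` with `b(T) = c·exp(−T/τ_d)` — which
preserves modulation amplitudes through the FFT; a failed fit falls back
to a first-order fit in the log domain with a warning. Phase correction
is assumed upstream: the processors accept real-valued traces. The
spectrum is mean-subtracted, Hamming-windowed, zero-filled to twice the
next power of two and returned as a magnitude spectrum (8 ns dwell →
62.5 MHz Nyquist).

Blind spots are handled where they physically live: `blind_spot_tau()`
returns τ = k/ν (sin(πντ) = 0), and the *generator* scales each line's
depth by sin²(πντ); the processing chain itself is τ-agnostic. The
default synthetic line list (0.7, 1.4, 2.0 MHz plus a 4 MHz
double-quantum line on an exponential decay) emulates remote imidazole
^14^N modulation. With 512 points at 8 ns dwell the full
simulate→preprocess→FFT chain localises each line within one frequency
bin, and simulating at a line's blind spot suppresses its peak by well
over an order of magnitude.

HYSCORE matrices get a 3rd-order polynomial baseline subtraction along
each time dimension (rows then columns), 2-D Hamming apodisation,
zero-filled 2-D FFT magnitude, folding of the (+,+) and (−,+) quadrants
(the anti-diagonal symmetrisation) and diagonal symmetrisation
(S + Sᵀ)/2, which is idempotent. Quantum-mechanical simulation from
nuclear Hamiltonians is out of scope; the separable-tone generator
provides known-answer inputs.

# RIDME simulation and inversion

The powder dipolar kernel is
K(t, r) = ∫₀¹ cos(2π·ν_dd(r)·(1 − 3x²)·t) dx with ν_dd = 52.04/r³ MHz
(r in nm) — the g = 2 point-dipole scale, configurable for other g
values; Cu g-anisotropy is deliberately ignored in the kernel because
the multi-field summation (`combine_field_positions()`) averages
orientation selection, which is exactly why the experiment records
several field offsets. The integral is evaluated with 512-node
Gauss--Legendre quadrature, which agrees with a 10⁵-point Riemann sum to
better than 10⁻⁸ on the grids used here.

Traces follow V(t) = [(1 − λ) + λ·K·P]·exp(−k·t^d): a dipolar form
factor with modulation depth λ times a stretched-exponential background.
`invert_tikhonov()` recovers P by non-negative least squares with a
second-derivative (curvature) penalty α²‖L₂P‖², and treats (k, d, λ) by
variable projection: a bounded Levenberg--Marquardt refinement in which
every residual evaluation re-solves the non-negative linear subproblem.
Numerical choices that matter:

* **Tail anchoring.** The initial background is fitted to the later half
  of the trace, where dipolar oscillations have dephased, so
  λ ≈ 1 − (tail amplitude). This breaks the near-degeneracy between the
  background level and unresolvable long-distance density; without it
  the optimisation can converge to an inflated λ compensated by a
  spurious plateau at the long-r edge.
* **Multistart.** The (k, d) surface has local minima with d railing at
  its bound, so the refinement also starts from two interior stretch
  exponents (1.5, 2.5) and keeps the best fit.
* **α selection.** Generalized cross-validation over a log-spaced grid
  by default, using the active-set linear smoother for the effective
  degrees of freedom; an L-curve variant and fixed values are available,
  and a failed search falls back to α = 1 with a warning.
* **Grids.** Default r-grid 1.5--8 nm (the detectability window) at
  0.02 nm; t up to τ₂ minus dead time (≈2.2 µs for the 2500 ns τ₂ used
  here).

`uncertainty_band()` is a residual-resampling bootstrap at fixed α with
warm-started background refits; the 2.5/97.5 percentile envelope is
expanded to contain the point estimate (the convention of
DeerAnalysis-class software). The point estimate is fully converged
before residuals are taken, otherwise the band reports optimiser noise
rather than data noise.

The relaxation utilities fit the 2-pulse echo decay with a stretched
exponential (Tm, β) and inversion recovery with a biexponential, both by
bounded Levenberg--Marquardt with data-driven starts, and recommend the
RIDME mixing time as 0.7 × the amplitude-weighted mean T1.

# The synthetic decoy and what passing tests show

`make_decoy_structure()` places six Cu ions at explicit coordinates that
realise the published distance anchors exactly — ATCUN--siteB 1.8 nm,
ATCUN--H287 3.5 nm, every H317 pair within 4.0--4.9 nm, every H509 pair
within 4.5--7.6 nm — then applies a seeded rigid rotation and
translation (distance-preserving) and surrounds each Cu with 2--4
donor atoms carrying the canonical residue names and numbers at
2.0--2.3 Å. Unconstrained pairs are whatever the construction produces:
no full distance table is invented beyond the printed anchors. The file
is written as P1 with a 20 Å box margin; symmetry tests use separate
small fixtures so the two concerns stay decoupled. Every generator is a
pure function of (spec, seed) down to the file bytes.

What the decoy does *not* emulate: a protein backbone, realistic
B-factors or disorder, anomalous scattering, crystal packing. Passing
the pipeline on the decoy demonstrates that the geometry, labelling,
enumeration, simulation and inversion machinery is correct — not that
real albumin data will be as clean. Two real-data features deliberately
absent from the synthetic RIDME traces are orientation selection
(averaged experimentally by multi-field summation) and ESEEM
contamination of the RIDME background.

A known resolution limitation worth stating: with t ≤ 2.2 µs a 4.5 nm
distance completes only ~1.25 dipolar periods, so in the two-component
round trip the second mode's recovered position scatters by up to
~0.2 nm across noise realizations even at SNR 50. The 3.5 nm mode, with
~2.7 periods, is stable to ±0.05 nm. This mirrors the usual
trace-length-dependent reliability ranges quoted for pulsed dipolar
distance distributions.

# Problem sizes used in tests

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as sensible defaults for synthetic verification: 140-point
time traces, a 0.05 nm inversion grid (the package default stays at
0.02 nm), 20--30 bootstrap replicates, 256--512 powder orientations and
5 seeds per stochastic round trip. All tolerances quoted above are
asserted by the test suite at exactly these sizes.

# A worked example

```{r example, eval = FALSE}
library(cuepr)

# 1. structure -> labelled sites -> distance table (nm)
decoy <- make_decoy_structure(decoy_spec(seed = 1))
sites <- detect_metal_sites(decoy)
tab <- pairwise_distances(sites)
round(tab["ATCUN", c("siteB", "H287")], 2)  # 1.80, 3.50

# 2. occupancy model vs a synthetic "experimental" distribution
expr <- simulate_distribution(c("ATCUN", "siteB", "H287"), tab)
expr$source <- "experimental"
rk <- rank_configs(enumerate_configs(rownames(tab), 2, 6), tab, expr)
head(rk, 3)

# 3. RIDME round trip at SNR 50
P <- distance_distribution(seq(1, 10, 0.02),
                           dnorm(seq(1, 10, 0.02), 3.5, 0.1))
tr <- simulate_ridme(P, background_model(0.08, 1.6, 0.3),
                     noise_sigma = 0.02, seed = 1)
fit <- invert_tikhonov(tr, seq(1.5, 8, 0.05))
fit$P$r[which.max(fit$P$density)]  # 3.5
```
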