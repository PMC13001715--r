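# cuepr

Multi-site Cu(II) binding analysis for serum albumin (and similar
proteins) from crystal-structure geometry and EPR spectroscopy.

Serum albumin binds Cu²⁺ at a high-affinity N-terminal ATCUN motif and
at several secondary histidine/carboxylate sites (sites A and B, His287,
His317, His509). A crystal structure gives the positions of all bound
copper ions but cannot say whether several sites are occupied in the
*same* molecule. Pulsed dipolar EPR (RIDME) measures the intramolecular
Cu–Cu distance distribution in frozen solution; comparing it with the
pairwise distances between the crystallographic copper sites turns the
structure into a testable multi-site occupancy model. `cuepr` implements
that analysis chain end to end, for people who work with metalloprotein
EPR and crystallography:

- **Structure geometry** — `parse_structure()` (PDB/mmCIF via bio3d),
  `detect_metal_sites()` with canonical albumin site labels,
  `pairwise_distances()` (Cu–Cu table in nm), `count_disulfides()`,
  `min_symmetry_contact()` with embedded P1/P61/P212121 operators.
- **Occupancy model** — configurations are subsets of occupied sites;
  each pair contributes a Gaussian *N*(r_ij, σ = 0.1 nm) with equal
  amplitudes; `rank_configs()` scores them against an experimental P(r)
  by windowed histogram overlap, `∫ min(P_sim, P_exp) dr` on
  1.5–8 nm.
- **CW EPR** — axial Cu²⁺ powder spectra (S = 1/2, I = 3/2) with
  resonance fields `B = B₀ − m_I a − a²[I(I+1) − m_I²]/(2B₀)` accurate
  to ~0.3 G against full diagonalization; `double_integral()` and
  `titration_linearity()` for the "all added Cu²⁺ stays EPR-active"
  argument.
- **ESEEM / HYSCORE** — exponential background division `(V − b)/b`,
  Hamming window, zero-filled FFT magnitude spectra; blind-spot τ
  calculator (τ = k/ν); HYSCORE polynomial baseline, quadrant folding
  and symmetrisation.
- **RIDME** — powder dipolar kernel
  `K(t,r) = ∫₀¹ cos(2π·(52.04/r³)·(1 − 3x²)·t) dx`, trace simulation
  `V = [(1−λ) + λKP]·exp(−kt^d)`, non-negative Tikhonov inversion with
  GCV/L-curve α selection and a variable-projection background fit,
  bootstrap 95% confidence bands, multi-field trace combination, and
  the Tm (stretched-exponential) / T1 (biexponential, T_mix = 0.7·T1)
  relaxation fits.
- **Synthetic data** — a seeded decoy structure whose six Cu sites
  honour the published distance envelopes (ATCUN–siteB 1.8 nm,
  ATCUN–His287 3.5 nm, His317 pairs 4.0–4.9 nm, His509 pairs
  4.5–7.6 nm) plus CW/ESEEM/HYSCORE/RIDME fixture generators, so the
  whole pipeline runs without downloading anything.

## Worked example

```r
library(cuepr)

decoy <- make_decoy_structure(decoy_spec(seed = 1))
sites <- detect_metal_sites(decoy)          # 6 sites: ATCUN ... H509
tab   <- pairwise_distances(sites)
round(unclass(tab)[1:4, 1:4], 2)
#>       ATCUN siteB siteA H287
#> ATCUN   0.0  1.80  2.00 3.50
#> siteB   1.8  0.00  2.69 2.33
#> siteA   2.0  2.69  0.00 2.80
#> H287    3.5  2.33  2.80 0.00

# which occupancy configuration explains a measured P(r)?
expr <- simulate_distribution(c("ATCUN", "siteB", "H287"), tab)
expr$source <- "experimental"
rk <- rank_configs(enumerate_configs(rownames(tab), 2, 6), tab, expr)
head(rk, 3)
#>                   config size score
#> 1       ATCUN,siteB,H287    3 1.000
#> 2 ATCUN,siteB,siteA,H287    4 0.582
#> 3  ATCUN,siteB,H287,H317    4 0.500

# RIDME round trip at SNR 50: simulate, invert, read off the mode
rg <- seq(1, 10, 0.02)
P  <- distance_distribution(rg, dnorm(rg, 3.5, 0.1))
tr  <- simulate_ridme(P, background_model(0.08, 1.6, 0.3),
                      noise_sigma = 0.02, seed = 1)
fit <- invert_tikhonov(tr, seq(1.5, 8, 0.05))
fit
#> <ridme_fit> mode 3.5 nm; lambda 0.332 ; alpha 0.1 ; rmsd 0.0176
```

The distance table reproduces the constrained anchors (1.80 and
3.50 nm); the generating configuration ranks first with a perfect
overlap score; and the inversion recovers the 3.5 nm mode with a
modulation depth estimate near the simulated λ = 0.3.

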