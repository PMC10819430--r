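# quenchbind

Fluorescence-quenching analysis of protein–ligand binding, built around the
serum-albumin titration assays used to characterise per- and polyfluoroalkyl
substances (PFAS). Given emission spectra recorded at a ladder of ligand
concentrations and several temperatures, the package answers the standard
questions of such a study: *how* is the fluorescence quenched (static complex
formation vs. collisional), *how strongly* does the ligand bind, *what forces*
drive the association, *where* on the protein the ligand sits, and whether
independent energy decompositions and molecular descriptors are consistent
with the measured affinities.

## Who it is for

Biophysical and environmental chemists running ligand-binding titrations
(HSA–PFAS and similar systems), and anyone who needs the downstream
arithmetic of such papers — Stern–Volmer tables, Van't Hoff thermodynamics,
site-marker competition percentages, MM/GBSA bookkeeping, descriptor
correlations — as tested, reusable code. A forward simulator with known
ground truth stands in for raw spectra, which binding studies rarely deposit.

## The models

* **Inner-filter correction** — F_corr = F_obs · 10^((A_ex + A_em)/2), applied
  before any fit whenever matched absorbances are available.
* **Stern–Volmer quenching** — F0/F = 1 + K_SV·[Q]; the bimolecular rate
  constant K_q = K_SV/τ0 (τ0 ≈ 1e-8 s) is compared against the diffusion
  limit (~2×10¹⁰ L·mol⁻¹·s⁻¹) and the temperature trend of K_SV to classify
  the mechanism as static, dynamic or mixed.
* **Double-logarithmic binding** — log₁₀((F0−F)/F) = log₁₀K_b + n·log₁₀[Q],
  giving the binding constant K_b and the apparent site number n.
* **Van't Hoff thermodynamics** — ln K_b = −ΔH/(RT) + ΔS/R; ΔG = −RT·ln K_b;
  the (ΔH, ΔS) sign pattern classifies the dominant interaction force
  (hydrophobic / H-bond–van der Waals / electrostatic).
* **Site-marker competition** — φ = (K_b − K_b′)/K_b × 100 for probes with
  known subdomains (warfarin → IIA, ibuprofen → IIIA, lidocaine → IB); the
  strongest displacer assigns the binding site.
* **MM/GBSA validation and correlation** — checks ΔG_bind = ΔE_VDW + ΔE_ELE +
  ΔG_GB + ΔG_SA row-wise, ranks systems by affinity, and computes Pearson
  correlations between per-compound metrics.
* **Titration simulator** — F(Q) = f0/(1 + K_b·Qⁿ) Gaussian emission bands
  whose centre blue-shifts with the bound fraction, optional inner-filter
  attenuation, Van't Hoff temperature dependence, and seeded multiplicative
  noise; every fit is tested against this forward model.

## Worked example

Simulate a three-temperature study with known thermodynamics
(ΔH = −106.57 kJ/mol, ΔS = −259.2 J/mol/K, 1% detector noise), then run the
affinity and thermodynamic stages:

```r
library(quenchbind)

cfg <- sim_config(delta_h_kj_mol = -106.57, delta_s_j_mol_k = -259.2,
                  noise_sd_rel = 0.01, seed = 42)
study <- simulate_study(cfg)

(fits <- binding_table(study, policy = "per_spectrum_max"))
#> # A tibble: 3 × 7
#>   series_id temperature_K      kb n_sites kb_stderr_log10 n_stderr r_squared
#>   <chr>             <dbl>   <dbl>   <dbl>           <dbl>    <dbl>     <dbl>
#> 1 sim_298K            298 172044.   1.02           0.0242  0.00479     1.000
#> 2 sim_304K            304  50126.   0.983          0.0194  0.00385     1.000
#> 3 sim_310K            310  38286.   1.03           0.0780  0.0154      0.999

classify_mechanism(sv_table(study, policy = "per_spectrum_max"))
#> # A tibble: 1 × 4
#>   mechanism trend      kq_exceeds_diffusion_limit evidence
#>   <chr>     <chr>      <lgl>                      <chr>
#> 1 static    decreasing TRUE                       Ksv decreasing over 298-310 K…

thermo_table(fits[, c("temperature_K", "kb")])
#> # A tibble: 1 × 5
#>   delta_h_kj_mol delta_s_j_mol_k r_squared force_class delta_g
#>            <dbl>           <dbl>     <dbl> <chr>       <list>
#> 1          -96.6           -225.     0.887 hbond_vdw   <tibble [3 × 3]>
```

The fitted K_b falls from ~1.7×10⁵ to ~3.8×10⁴ L/mol between 298 K and
310 K, so quenching is called static; the Van't Hoff fit recovers the
generating exothermic, entropy-opposed thermodynamics (hydrogen-bond /
van der Waals signature), with three-temperature noise accounting for the
residual deviation. Each per-temperature ΔG (−29.9, −27.4, −27.2 kJ/mol
here) comes from −RT ln K_b.

Bundled reference tables (`hsa_pfas_binding()`, `hsa_pfas_competition()`,
`hsa_pfas_gbsa()`, `hsa_pfas_docking()`) provide real multi-temperature
HSA–PFAS measurements for the same workflow, and
`run_full_analysis(<config.yaml>)` chains every stage over CSV inputs.

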