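# tammsensor

Dispersive transfer-matrix simulation of an asymmetric Tamm-plasmon/cavity
photonic refractive-index sensor, written for photonics researchers who
want a scriptable, fully tested model of metal-coated Bragg-mirror stacks
with a central analyte cavity — the geometry proposed for non-invasive
urinary-glucose monitoring, where the glucose concentration modulates the
real refractive index n_a of urine (1.335 for normal urine up to 1.341 at
5 g/dL).

## The model

The structure is glass | DBR1 | Ag | analyte | Ag | DBR2 | glass. Spectra
follow from a product of 2×2 interface-plus-layer matrices

```
T(n-1,n) = 1/2 [ (1+h) e^{-i kz γ}   (1−h) e^{+i kz γ} ]
               [ (1−h) e^{-i kz γ}   (1+h) e^{+i kz γ} ]
```

with h the TE/TM impedance-step ratio, giving R = |M21/M11|²,
T = |1/M11|² × (admittance ratio) and A = 1 − R − T. Three reflectance dips
live in the bandgap: two Tamm plasmon polaritons (TPP1, TPP2) pinned at the
metal/mirror interfaces and a cavity mode that redshifts with n_a. The
sensing metrics are

* Q = λ₀/FWHM and G = (1−R₀)/FWHM (μm⁻¹) for resonance quality,
* S = (Δλ_cavity − Δλ_TPP)/(n_a − 1.335) in nm·RIU⁻¹ (TPP-referenced
  sensitivity) and FoM = S/FWHM in RIU⁻¹.

The cavity eigenmode is independently solved from the round-trip phase
condition φ₁ + φ₂ + 4π n_a d_A k = 2π m, cross-validating the dip finder
within half a linewidth. Dielectrics use Cauchy dispersion fits
(0.30–1.25 μm); Ag/Au/Cu use the vendored Johnson & Christy (1972) n/κ
tables with monotone-cubic interpolation. See the vignette
(`vignettes/tamm-cavity-sensing.Rmd`) for conventions, design decisions and
known limitations.

## Worked example

```r
library(tammsensor)
st <- build_baseline(n_a = 1.335, metal = "Ag")
sp <- stack_spectrum(st, seq(750, 1100, by = 0.25))
modes <- classify_resonances(find_resonances(sp))
modes[, c("lambda0_nm", "fwhm_nm", "R0", "Q", "G_per_um", "label", "f_A")]
```

```
  lambda0_nm  fwhm_nm         R0        Q G_per_um  label        f_A
1   796.4371 3.141923 0.03562226 253.4871 306.9387   TPP1 0.12857215
2   930.7307 1.380535 0.02612152 674.1812 705.4356 cavity 0.95955572
3  1026.2943 4.883407 0.81462733 210.1595  37.9597   TPP2 0.06516987
```

Reading: three dips inside the bandgap. The 930.7-nm mode keeps 96% of its
field intensity in the analyte (`f_A`) — the cavity probe, with Q ≈ 674 and
G ≈ 705 μm⁻¹; the 796.4-nm and 1026.3-nm modes localize at the first and
second metal films (TPP1/TPP2). Sweeping the glucose range:

```r
sw <- ri_sweep("baseline", glucose_map()$n_a)
sensitivity(sw, reference = "TPP1", n_a = 1.336)   # 604.6 nm/RIU
solve_phase_condition(st, m = 2)$lambda_nm         # 930.705 nm
```

The cavity dip shifts ~0.64 nm per 0.001 RIU (conventional
Δλ/Δn ≈ 642 nm·RIU⁻¹; the TPP-referenced value is lower because a few
percent of the Tamm field reaches the analyte through the 30-nm films),
and the phase-condition eigenmode lands 0.03 nm from the dip.

A thin command-line layer wraps the same functions:

```sh
Rscript inst/cli/sensor.R metrics --config run.yml --out metrics.tsv
Rscript inst/cli/sensor.R sweep --na 1.335:1.341:0.001 --out sweep.tsv
Rscript inst/cli/sensor.R reproduce-tables --outdir tables/
```

Subcommands: `spectrum`, `fields`, `angular`, `sweep`, `metrics`,
`reproduce-tables`; all outputs are delimited text with `#` metadata
headers recording the metal-table provenance and interpolation scheme.

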