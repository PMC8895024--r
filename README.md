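# padftex

Fluctuation X-ray scattering (FXS) analysis with explicit treatment of
preferred orientation (texture), built around the pair-angle distribution
function (PADF).

## The problem

FXS measures many diffraction snapshots from different microscopic regions
of a sample and analyses the angular intensity fluctuations around the
scattering rings.  The mean-subtracted angular correlation

    C(q, q', Δφ) = (1/N_d) Σ_k (1/n) Σ_φ Ĩ_k(q, φ) Ĩ_k(q', φ + Δφ)

is expanded in even Legendre polynomials, C = Σ_l B_l(q,q') P_l(cos θ),
and each B_l(q,q') is carried to real space by an order-l spherical Bessel
transform; the Legendre resummation of the real-space matrices is the PADF
Θ(r, r', θ) — a map of two pair distances and their mutual angle.

The inversion assumes uniformly oriented scatterers.  For a polycrystal
with N_c domains in the beam the correlation has two parts: a
nanostructure (self) term scaling as N_c and a preferred-orientation
(cross) term scaling as N_c², so even a slight texture dominates when the
beam is large.  `padftex` implements the full chain — detector geometry
and silver-behenate calibration, polar remapping, mask-aware correlations,
SVD harmonic inversion, Bessel transforms and PADF assembly, the ensemble
curation pipeline (hexagonal phase identification, 5% lattice filtering,
R_k profile agreement, sixth-order-polynomial orientation fitting,
orientation maps) — plus a synthetic textured-diffraction simulator
(uniform / twofold-sinusoidal / periodic-Lorentzian pole distributions, in
smooth-ring or sparse-domain rendering) and the texture-balance
diagnostics built on it.  The model system is a 2D hexagonal (H1)
mesophase with ring ratios 1 : √3 : 2, as formed by CTAB–water.

## Worked example

A peaked (periodic-Lorentzian) pole distribution with the half-width that
puts the l = 4 power at ~6% of l = 2, processed through the whole chain:

```r
library(padftex)
lat  <- hex_lattice()                              # a = 5.6 nm, q10 = 1.295 nm^-1
grid <- polar_grid(seq(0.5, 4, length.out = 40), 360)
mod  <- orientation_model("lorentzian", gamma = 0.4336)
ens  <- simulate_ensemble(sim_config(n_patterns = 100, mode = "rings",
                                     seed = 1), lat, mod, grid)
vol  <- correlate_stack(ens$patterns)
bl   <- correlation_to_bl(vol, l_max = 8)
bl_power(bl)
#>   l        power     fraction
#> 1 0 2.331392e-02           NA
#> 2 2 2.763249e-01 1.0000000000
#> 3 4 1.657330e-02 0.0599775758
#> 4 6 7.684447e-04 0.0027809467
#> 5 8 3.811948e-05 0.0001379517
```

The power table says the twofold (l = 2) texture term dominates, with
l = 4 at 6.0% — the signature of a sharply peaked pole distribution.  In
real space that l = 4 content shows up as secondary features near 45° and
135° in the diagonal PADF slice:

```r
padf <- assemble_padf(bl_qq_to_rr(bl, seq(1, 10, length.out = 64)))
padf_secondary_peak(padf)
#> $theta
#> [1] 48      # degrees: the ~45-degree feature (mirror at ~132)
#> $r
#> [1] 4.571429
#> $value
#> [1] 0.02424576
```

(With a plain sinusoidal modulation the same call returns `NULL`: the PADF
is pure l = 2, maximal at 0° and 180° only.)

Geometry utilities reproduce beamline arithmetic:

```r
calibrate_distance(7.9675, d_spacing = 58.380, wavelength = 0.6702)
#> [1] 0.6940013   # metres, from the silver behenate (001) ring radius in mm
beam_area_ratio(c(25, 250), c(2, 2))
#> [1] 1562.5      # SAXS beam vs 2x2 um microfocus: the ~1500x area ratio
```

The last number is why the two beamline configurations sit on opposite
sides of the texture balance: ~1500× more illuminated area means ~1500×
more domains N_c, and the texture term grows as N_c² against the
nanostructure's N_c.

## Command line

```sh
Rscript inst/cli/padftex.R simulate --out stack.rds --mode rings \
    --model sinusoidal --epsilon 0.1 --nd 100 --seed 1
Rscript inst/cli/padftex.R correlate --input stack.rds --out corr.rds
Rscript inst/cli/padftex.R padf --input corr.rds --out padf.rds --lmax 8
Rscript inst/cli/padftex.R texture-scan --out scan.csv --nc 8,32,128,512 \
    --eps 0.05 --reps 200 --seed 1
```

Every stage writes a `.prov` provenance file (full config, seed, package
version) next to its output.

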