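# vancoelute

Finite-difference simulation of local vancomycin release from polymer-coated
bone implants and its distribution through adjacent tissue and layered bone.

## The problem

Implant-associated infections (chiefly *S. aureus*) are hard to treat
systemically; antibiotic-eluting coatings such as a vancomycin-loaded
poly-L-lactic acid (PLLA) layer on a bone plate deliver high local
concentrations instead. Whether such a delivery system works depends on the
concentration field it creates: everywhere relevant it should exceed the
minimum inhibitory concentration (MIC, 2 µg/mL for *S. aureus*) while staying
below the host-cell toxicity threshold (1,000 µg/mL). `vancoelute` is for
modellers and implant designers who want to predict that field — and its
sensitivity to uncertain pharmacokinetic inputs — without animal experiments.

## The model

Transport is Fickian diffusion with first-order elimination. On a 1-D grid of
cells of size Δx (index 0 at the release surface), the explicit update per
time step Δt is

    C_i(t+Δt) = C_i(t) + (D Δt/Δx²) (C_{i−1} − 2C_i + C_{i+1})
                + Δt (ln 0.5 / t_1/2) C_i(t) 0.5^(Δt/t_1/2)

with a one-sided stencil at sealed (no-flux) walls, a flux cell gaining
(Δt/Δx)·J_in(t) at the release surface, and sink cells pinned to zero after
each update. The release flux J_in(t) comes from differentiating a cumulative
release profile (measured, or a synthetic Korsmeyer–Peppas power law
M_t/M_∞ = k tⁿ) over the coating footprint. In porous bone the diffusivity is
the effective value

    D_eff = D0 · δ · φ / τ

(D0 free-water diffusivity 2.83×10⁻⁶ cm²/s; constrictivity δ, porosity φ,
tortuosity τ: 0.84/0.05/1.10 cortical, 0.96/0.95/1.10 cancellous). Stability
of the explicit scheme is enforced through Δt ≤ Δx²/(6D), and every run keeps
a mass ledger (influx = cleared + stored) that must close.

Four scenarios are packaged: the in vitro slab release into a sink, the 2-D
agar inhibition-zone assay, a rat-tibia bolus with clearance, and the human
bone-plate delivery system (3 mm tissue on one side; a 3.5 + 14 + 3.5 mm
cortical–cancellous–cortical stack on the other, 1×1 mm² cross-section). A
sensitivity workflow perturbs diffusivities, porosities and the half-life
with seeded log-normal factors reduced to 11 percentile points, and reports
sensitivity indices (output %-change / input %-change) with a regression
adequacy check.

## Worked example

```r
library(vancoelute)

bp <- run_human_bone_plate(default_config("human_bone_plate"))
print(bp$tissue)
#> Simulation result (1-D): 49 snapshots to t = 24 h, dt = 0.002003205 h
#>   mass ledger (ug): influx 10.36744, cleared 8.867108, stored 1.500334, closure 2.122473e-14
sprintf("tissue peak: %.0f ug/mL at %.1f h",
        bp$summary$peak_concentration, bp$summary$peak_time)
#> "tissue peak: 956 ug/mL at 5.0 h"
print(bp$zones[[length(bp$zones)]])   # bone side at 24 h
#> Zone map (MIC 2, toxicity 1000 ug/mL): sub_MIC=35, effective=6, toxic=1 cells
```

The tissue-side average rises while the coating's release rate outpaces
clearance, peaks near 950 µg/mL a few hours after implantation (below the
1,000 µg/mL toxicity threshold, far above the 2 µg/mL MIC), then declines as
the 4-h half-life dominates. On the bone side only the cortical cells next to
the plate reach effective levels — the dense cortical shell throttles
diffusion into the cancellous core.

Comparing a measured inhibition area with a simulated one:

```r
print(one_sample_t_test(mean = 12.97, sd = 1.30, n = 3, mu0 = 15.43))
#> One-sample t test: t = -3.2776, df = 2, two-sided p = 0.0818
```

so a measured 12.97 ± 1.30 cm² (three replicates) is statistically compatible
with a simulated 15.43 cm² at the 0.05 level.

A command-line front end is included at `inst/cli/vancoelute.R`
(`run`, `sensitivity`, `synth` subcommands).

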