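# lfnmr — low-field NMR relaxometry of oil-in-water emulsions

`lfnmr` analyses time-domain proton NMR relaxation data from two-phase
oil-in-water emulsions, the measurement used to probe water and oil
molecular dynamics in starch-stabilized food colloids. It is aimed at
people working with low-field (here 15 MHz) relaxometers on emulsions,
gels and pastes who want a reproducible path from raw pulse-sequence
traces to per-phase activation energies.

The chain it implements:

1. **Component extraction.** Inversion-recovery (180–τ–90) and CPMG
   (90–τ–180ₙ) traces are fitted with discrete multiexponential models
   by variable projection (amplitudes solved linearly, time constants
   optimized from a deterministic log-grid start). An emulsion gives two
   components per time: fractions sum to 1 by construction.
2. **Phase assignment.** Short T1/T2 components → oil, long → water.
3. **Correlation times.** Each phase's T1/T2 pair is converted to a mean
   rotational correlation time τc through the Bloembergen–Purcell–Pound
   (BPP) dipolar relaxation model. The default route inverts the
   prefactor-free ratio
   R2/R1 = ½·[3 + 5/(1+x²) + 2/(1+4x²)] / [1/(1+x²) + 4/(1+4x²)],
   x = ωτc, which needs no internuclear distance; an alternative mode
   inverts the absolute R1 given r0 and a fast/slow branch choice.
4. **Activation energies.** ln τc is regressed on 1/T (Arrhenius law
   τc = τ0·exp(ΔEa/RT)); the slope times the gas constant is the energy
   barrier ΔEa of rotational motion per phase, in kJ/mol with its OLS
   standard error.

Because raw datasets of this kind are not publicly deposited, the
package includes a first-class simulator (`emulsion_preset()`,
`generate_dataset()`) producing seeded, bit-reproducible temperature
series with known ground truth, which the whole pipeline is validated
against. Fatty-acid profiles of the beef and pork oil phases ship as a
fixture with a group-summary utility.

## Worked example

Simulate a two-phase emulsion (oil barrier 25 kJ/mol, water 15 kJ/mol,
ten temperatures from 0 to 90 °C at SNR 200) and recover both barriers:

```r
library(lfnmr)
spec <- emulsion_preset(snr = 200, seed = 42)
res <- run_pipeline(list(sim_spec = spec))
res
#> emulsion pipeline result
#>   starch       conc fat    phase   delta_Ea (kJ/mol)
#>   synthetic    0.12 synthetic oil     24.6 ± 0.5
#>   synthetic    0.12 synthetic water   15.0 ± 0.1
res$arrhenius$water
#> Arrhenius fit (water phase): delta_Ea = 15.0 +/- 0.1 kJ/mol
#>   tau_0 = 1.081e-11 s, R^2 = 0.9998, n = 10
```

The oil estimate (24.6 ± 0.5) and water estimate (15.0 ± 0.1) bracket
the generator's true barriers; the water phase is tighter because its
long relaxation times are measured with better relative precision and
its ratio sits further from the degenerate R2/R1 → 1 limit at most
temperatures. `res$tau_c` holds the per-temperature correlation times
and flags any ratio clamped at the physical minimum.

Fatty-acid group sums from the packaged profiles:

```r
summarize_fatty_acids(fatty_acid_profile("beef"),
                      list(saturated   = c("C16:0", "C18:0"),
                           unsaturated = c("C18:1", "C18:2")))
#>   saturated unsaturated
#>        47.9        43.0
```

Pre-fitted component tables (CSV, one row per condition × temperature
with t11/t12/t21/t22 and the oil fraction) can be analysed directly via
`run_pipeline(list(component_table = "table.csv"))`. A thin CLI with
`simulate` / `fit` / `analyze` / `fattyacids` verbs lives in
`inst/cli/lfnmr.R`.

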