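# hlsim

`hlsim` simulates the interaction between a Hodgkin-lymphoma tumor and its
micro-environment. In this disease the malignant cells are a small
minority of the tumor mass; growth is sustained by recruited bystander
cells. The package is aimed at modellers and immunotherapy researchers who
want to experiment with therapy timing, intensity and toxicity in a small,
fully specified dynamical model — every constant, equation and solver
setting is part of the package, so any published-style experiment can be
re-run and varied from a few lines of R or from the command line.

## The model

Six stocks evolve in days: cancer stem cells (CSC), cancer transit
amplifying cells (CTAC), mature tumor cells (MTC), and helper, killer and
regulatory bystander cells. Gains are logistic, e.g. for stem cells

    CSC_prol = max(0, g·C − c·C²),

and losses balance death, killer-mediated killing and pulse-scheduled
therapy against helper-derived rescue inside a hard clamp,

    CSC_loss = max(0, d·C + (1+A)·k·K − h·H) + δ·C + θ(t)·C,

with analogous expressions for the other compartments. Bystander
proliferation is gated by tumor-derived stimulation; regulatory cells
suppress helper and killer growth. Integration is fixed-step Euler
(dt = 0.007812) with a guarded update that keeps every stock
non-negative — the scheme is part of the model's definition. Two
immunotherapy extensions are built in: adoptive transfer of killer cells
(an additive pulse, `ImmunoTHx1`) and vaccination-like amplification of
killer cytotoxicity per tumor compartment (the `(1+A)` factor,
`ImmunoTHx2`). See the methods vignette (`vignettes/hlsim-methods.Rmd`)
for the full account.

## Worked example

Simulate cytotoxic therapy that hits the bulk tumor hard but barely
touches the stem cells (therapy days 400–500, kill rates 0.9/day for
MTC/CTAC versus 0.035/day for CSC), then classify the outcome:

```r
library(hlsim)
traj <- run_scenario("fig7_relapse")
classify_outcome(traj)
#> outcome: relapse
#>   burden: initial 30, final 9.92607e+06, min 7.9854 at day 500
#>   regrowth crossed threshold at day 682
```

The tumor grows from 30 cells to ~10⁹ before therapy, collapses to 8
cells at the end of therapy (day 500) — deep remission, but not
elimination — and the surviving stem cells regrow the tumor past the
relapse threshold by day 682, reaching ~10⁷ cells at day 2000. Raising
the stem-cell kill rate to 0.9 (`run_scenario("s7_thx_all_tumor")`)
changes the label to `eliminated`.

Higher-level experiments are one call each:

```r
# minimal curative adoptive-transfer dose at day 500 (~3e12 cells)
find_min_intensity(default_parameters(), 500, c(1e10, 1e17))

# smallest integer CSC-killing amplification achieving control (53)
find_threshold_integer(default_parameters(), "ImmunoTHx2CSC intens", 1:100)

# immune-escape window of a 1e6-cell transfer (fails on days 202–243)
scan_pulse_window(default_parameters(), 1e6, c(1, 300))
```

The same operations are available from a shell via the thin CLI wrapper
`inst/scripts/hlsim` (`run`, `list-scenarios`, `scan-window`, `find-dose`,
`find-threshold`, `report`); `list_scenarios()` enumerates all presets of
the published figures.

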