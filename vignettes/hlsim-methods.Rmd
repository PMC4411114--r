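---
title: "Methods: a stock-and-flow model of the Hodgkin-lymphoma micro-environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stock-and-flow model of the Hodgkin-lymphoma micro-environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlsim)
```

## The model

Hodgkin lymphoma is unusual among tumors in that the malignant cells are a
small minority of the tumor mass; most of it is reactive bystander tissue
that the tumor recruits and that in turn regulates tumor growth. `hlsim`
implements a deterministic stock-and-flow model of this system with six
interacting cell populations:

* three tumor sub-compartments — slow-cycling, self-renewing **cancer stem
  cells** (CSC), fast-dividing **cancer transit amplifying cells** (CTAC)
  that differentiate into non-proliferating **mature tumor cells** (MTC,
  the Hodgkin/Reed–Sternberg analogue);
* three bystander compartments — **helper cells** delivering anti-apoptotic
  rescue to tumor cells and co-stimulation to killers, **killer cells**
  removing tumor cells at compartment-specific rates, and **regulatory
  cells** suppressing both helper and killer proliferation.

Each stock $X$ evolves by a gain flow and a loss flow. Gains are logistic
("proliferation" for CSC and the bystanders, "increase" for CTAC/MTC which
are also fed by differentiation from their progenitor compartment), e.g.

$$\mathrm{CSC_{prol}} = \max\bigl(0,\; g_{csc}\,C - c_{csc}\,C^2\bigr),$$

with growth rate $g$ and capacity coefficient $c$ (carrying capacity
$g/c$). Losses combine natural death, killer-mediated killing and therapy,
with helper-derived rescue subtracted **inside** an outer $\max(0,\cdot)$:

$$\mathrm{CSC_{loss}} = \max\bigl(0,\; d\,C + (1+A)\,k\,K - h\,H\bigr)
  + \delta\,C + \theta(t)\,C,$$

so helpers can cancel death and killing but never convert a loss into a
gain. $A$ is the killing-amplification factor (vaccination-like
immunotherapy, see below), $\delta$ the differentiation rate and
$\theta(t)$ the pulse-scheduled therapy rate. Bystander proliferation is
additionally *gated*: it is exactly zero unless the compartment's
activation product (stock × tumor-derived stimulation, for killers also ×
helper help) is strictly positive. These hard clamps and gates, not smooth
saturation, are what produce the model's characteristic all-or-nothing
outcomes.

All 71 constants, their conventional display names and defaults are in
`param_table()`; `default_parameters()` reproduces the published default
set exactly. Defaults describe a growing tumor: a mostly-bystander mass
whose engine is the stem-cell compartment.

## Update rule and integrator

The model is defined, not approximated, as a fixed-step Euler scheme with
a guarded update. With net per-day rate $r = \text{gain} - \text{loss}
(+\,\text{transfer})$ the stock moves at rate $r$ if $X + r > 0$ and at
rate $-X$ otherwise (`net_change()`). Two deliberate literalisms:

* the guard compares the stock against the **per-day** rate, not the
  per-step increment $\Delta t\,r$. After a fallback step a residue
  $X(1-\Delta t)$ remains rather than an exact zero; non-negativity still
  holds everywhere and is property-tested under parameter fuzzing.
* therapy pulses are half-open windows $[t_0, t_0+\mathrm{dur})$ evaluated
  at the left endpoint of each step, so duration 1 delivers exactly one
  day of effect and duration 0 none.

All flows are evaluated from the pre-step state and the six stocks advance
simultaneously (synchronous update; no ordering artifacts among
compartments). `euler_step()` is the interpreted reference; `simulate_model()`
runs the same arithmetic in compiled code and the two paths are tested to
agree to round-off, as is an independent line-by-line transcription of the
published equation table and, in the bystander-free limit, the exact
logistic recurrence of the stem-cell stock.

**Time step.** The default is `dt = 0.007812` days, the published value,
with states recorded at `saveper = 1` day (the last step at or below each
save time). The neighbouring power of two $2^{-7} = 0.0078125$ gives
identical results for every quantitative experiment below (window
boundaries, dose bounds, the amplification threshold) and hits every save
time exactly; it is available through `sim_settings()`. We keep the
literal value as the default because the knife-edge amplification
experiments (next section) are *not* step-insensitive: at $2^{-7}$ the
all-compartment amplification run collapses to elimination instead of
losing control, and at $2^{-8}$ the just-sufficient threshold itself moves
off 53. Those runs sit on a genuine separatrix of the model — helper
rescue and amplified killing track each other to within about a percent
for thousands of days — and reproduce as published only at the step they
were produced with.

Halving the step changes the daily-sampled tumor burden of the default run
by less than 0.5%. The same is *not* true of every individual stock: the
killer stock passes through a gated proliferation onset around day 300
whose timing shifts slightly with the step, giving transient differences
of tens of percent for a few days. Outcome labels, window boundaries and
thresholds are step-halving stable (tested), which is the stability that
matters for the conclusions.

## Outcome classification

The published experiments describe outcomes verbally (progressive disease,
early/late relapse, continuous remission). `classify_outcome()` formalises
them:

* **eliminated** — final burden (CSC+CTAC+MTC) below 0.5 cells;
* **relapse** — burden dropped below 10% of its *running peak* and later
  exceeded 10× the initial burden;
* **suppressed** — final burden at most the initial burden;
* **progression** — otherwise.

Remission is measured against the running peak rather than the initial
burden by design: therapy in these experiments begins after the tumor has
grown by orders of magnitude, so a post-therapy nadir of, say, $10^5$
cells is deep remission relative to the $10^9$-cell pre-therapy peak while
still far above the 30-cell inoculum. An initial-burden criterion would
misread every relapse run as plain progression. The regrowth threshold
stays relative to the initial burden, which is unambiguous because the
dynamics are strongly bistable. Boundaries reported below are insensitive
to the 10%/10× choices within a factor of a few; the escape-window edges
move by at most ±2 days under such variation.

One caveat discovered while testing: with no initial stem cells the burden
*transiently* rises (differentiation pushes CTAC into the slower-dying MTC
pool, 20 → 24 cells) before collapsing, so "no growth" claims are asserted
on the final state, not pointwise.

## The immunotherapy experiments

**Adoptive transfer** (`ImmunoTHx1`) adds killer cells at a per-day rate
during its pulse window; a one-day pulse of intensity $I$ adds $I$ cells.
`scan_pulse_window()` classifies every integer start day. With $10^6$
cells and defaults, suppression succeeds through day 201, fails on days
202–243, succeeds again through day 291 and fails permanently from 292 —
the immune-escape window, caused by the early dip of the MTC/CTAC pools
(and hence of killer stimulation); setting the initial MTC and CTAC stocks
to zero removes the window (tested). `find_min_intensity()` brackets the
minimal curative dose by decade scan plus geometric bisection to two
significant figures, asserting monotonicity along the way: roughly
$3\times10^{12}$ cells at day 500, $2\times10^{14}$ at day 1000,
$7\times10^{15}$ at day 1500.

**Killing amplification** (`ImmunoTHx2`) multiplies the killer-mediated
killing of a chosen tumor compartment by $1+A$ from day 1000 for 3000
days. Control here cannot mean "burden back to the inoculum": the
controlled attractor retains a stroma-protected MTC remnant of order
$10^5$–$10^6$ cells whose death and killing are fully cancelled by helper
rescue. What distinguishes control is eradication of the self-renewing
compartment, which is also how the published experiments describe it; so
`find_threshold_integer()` uses CSC elimination as its default criterion.
The smallest integer CSC-only amplification achieving control is **53**
(at 52 the CSC stock stays at $8\times10^6$; the margin is enormous).

**Paradox enhancement.** At the just-sufficient $A = 53$, *additionally*
amplifying the killing of CTAC and MTC destroys control: removing the
immune-stimulating tumor mass starves killer proliferation of its
stimulus. An adoptive transfer of order $10^{10}$–$10^{11}$ killer cells
at day 1000 restores control. Within the chaotic band around the
separatrix the outcome map is fractal in the transfer intensity —
neighbouring values a few percent apart can differ in outcome, and the
single published intensity $3.5\times10^{10}$ falls on the failing side
under this implementation's floating-point arithmetic while $10^{10}$,
$3.6\times10^{10}$ and everything from $6\times10^{10}$ up rescue. The
differential test therefore asserts the mechanism at the published order
of magnitude ($10^{11}$) rather than chasing bit-level agreement with the
original solver.

## Scenario registry

`list_scenarios()` enumerates presets for each published simulation (main
and supplementary); the registry is a human-readable YAML manifest shipped
with the package (`inst/extdata/scenarios.yaml`) whose overrides use the
conventional display names, so each preset can be diffed against its
figure legend. Legends that leave a value open (the adoptive-transfer
start day; the killer-pulse intensity of the S19-type experiment) become
required arguments rather than guesses. Where the published chain of
"same values as before" references is ambiguous, each preset stores its
fully resolved override set inline.

```{r scenario-labels}
sapply(c("fig4_default", "fig6b_reg_low", "fig7_relapse"), function(nm) {
  sc <- get_scenario(nm)
  classify_outcome(simulate_model(sc$params, sc$settings))$label
})
```

## Problem sizes and performance

A 2000-day run at the default step is ~256,000 Euler steps and takes a few
milliseconds to ~0.1 s in compiled code (runs that traverse subnormal
stock values are slower). The full escape-window scan is 300 such runs;
the amplification threshold scan is ≤ 100 runs of 4000 days. The test
suite and the acceptance script each complete in about a minute on one
core.

## Known limitations

* Mean-field, well-mixed populations: no spatial structure, no stochastic
  extinction — a stock can fall to $10^{-300}$ "cells" and later regrow;
  interpretation below ~1 cell is by the elimination threshold only.
* Euler-with-guards is the model's definition; the trajectories are not
  solutions of a smooth ODE system, and no stiff or adaptive solver can
  reproduce them exactly.
* The bystander compartments aggregate heterogeneous cell types (T-cell
  subsets, NK cells, macrophages) into single stocks with lumped rate
  constants; parameters are phenomenological, not measured per-patient.
* Outcomes near separatrices are chaotic in the least significant digits
  of the inputs; only order-of-magnitude statements are robust there.
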