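---
title: "Quantifying B-vitamin auxotrophy and particle cross-feeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying B-vitamin auxotrophy and particle cross-feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vitacross)
library(dplyr)
```

Marine organic-matter particles are colonized by polysaccharide-degrading
bacteria whose by-products feed a second wave of cross-feeders. Many of
those cross-feeders cannot synthesize one or more B vitamins — cofactors
needed only in trace amounts, but absolutely — and ambient seawater
concentrations sit at or below the half-saturation constants of bacterial
uptake. `vitacross` implements the quantitative chain used to study this
situation: a serial growth-dilution screen that flags auxotrophs, Monod
kinetics that measure how much vitamin an auxotroph needs, genome rules
that explain *why* it is an auxotroph, and a reaction–diffusion model that
asks whether cross-feeding on a particle can actually sustain it.

## The serial-dilution screen

Isolates are grown in a defined marine minimal medium with (`+V`) and
without (`-V`) a thirteen-component vitamin mix, transferred 1:40 daily.
Carried-over vitamins therefore dilute by a factor of
$40^3 = 64{,}000$ across three transfers — no consumption or production is
modelled in this bookkeeping — which takes the stocks to roughly 13 pM
down to 0.1 pM:

```{r}
residual_concentration(vitamin_stocks()) |>
  arrange(desc(residual_pM)) |>
  head(3)
```

At the third transfer, growth is summarized per isolate by the median OD
across replicates in each condition, and the *growth deficit*

$$d = \frac{\mathrm{OD}_{-V} - \mathrm{OD}_{+V}}
           {\mathrm{OD}_{-V} + \mathrm{OD}_{+V}} \in [-1, 1]$$

flags putative auxotrophs below a cutoff (default $-0.4$, a configurable
choice made on the empirical distribution of deficits, not a constant of
nature). Isolates that fail to grow even with vitamins are *dropped*, never
scored: a deficit of 0 would silently misclassify them as prototrophs.

Specific requirements are then resolved from two confirmation designs:
growth with each vitamin alone, and growth in mixes of all vitamins but
one. We treat the dropout design as decisive — vitamin $v$ is required
when the mix lacking $v$ consistently fails — because an isolate that
requires two vitamins grows in *no* single-supplement condition; the
single-supplement design corroborates (a single requirement must grow on
`+v` alone, a multi-vitamin requirement must fail every single
supplement), and disagreement between the designs yields an `unresolved`
flag rather than a call. Growth/no-growth is called against
`blank_od + 3 * blank_sd` with an absolute floor of 0.05 OD — a
conventional plate-reader detection rule; the assay itself does not
prescribe a threshold, so both pieces are arguments, not constants.

## Growth rates and Monod half-saturation constants

Kinetic runs measure OD continuously for 24–36 h across a zero-vitamin
condition plus seven ten-fold dilutions. The growth rate of each curve is
the slope of the best log-linear window (natural log, so rate is in
h$^{-1}$ and doublings are rate$/\ln 2$). Window selection matters more
than it looks:

* windows must span at least 4 points and reach $r^2 \ge 0.98$;
* the longest qualifying window anchors the exponential region, and the
  steepest qualifying window at least 0.6 of that length wins, ties going
  to the earliest, then longest, window.

The length guard exists because the *raw* maximal slope over all windows
is an extreme-value statistic: with 5% multiplicative OD noise and ~10³
candidate windows, short lucky windows overestimate the rate by several
standard errors (we measured ~30% inflation at mid-range concentrations),
which propagates into a systematic underestimate of $K_S$. Anchoring to
the longest log-linear stretch removes that winner's curse while leaving
noiseless curves — where every sub-window has the same slope — untouched.
Slopes below 0.02 h$^{-1}$ are clamped to 0 and flagged `no_growth`;
fitting noise-level slopes on flat traces is how spurious "growth" enters
dose-response fits.

Per-concentration rates then go into a two-parameter Monod fit
$r(S) = r_{\max} S / (K_S + S)$ by Levenberg–Marquardt least squares on
the untransformed response, with the zero-vitamin condition entering as
$S = 0$ and standard errors from the parameter covariance. We deliberately
fix the lower asymptote at zero rather than fitting a four-parameter
dose-response: the half-saturation constant is the quantity consumed
downstream by the particle model, and the Monod form is what that model
assumes.

```{r}
sim <- gen_growth_curves(seed = 7, r_max = 0.5, half_saturation = 2.8e-11)
rates <- estimate_growth_rates(sim$curves) |>
  group_by(concentration_molar) |>
  summarise(rate = median(rate))
fit <- fit_monod(rates)
tidy(fit)
```

The design is scale-equivariant — multiplying all concentrations by $c$
multiplies $\hat K_S$ by $c$ — so recovery quality is identical across the
five orders of magnitude the measured constants span (~28 pM for the
cobalamin auxotroph to ~4.6 µM for the weakest niacin auxotroph), provided
the tested concentrations bracket $K_S$. When they do not, the fit is
still returned but with an honest, very wide standard error; the test
suite demonstrates both regimes.

Supernatant and lysate vitamer content is estimated *untargeted*, from the
growth they support: a power-law calibration $y = aC^b$ (least squares in
log-log) is inverted at the observed yield and multiplied by the mixing
factor (default 2, for samples mixed 1:1 with fresh medium). Estimates
outside the calibration range are flagged rather than refused, because
percent-of-maximum yields routinely exceed calibration.

## Genome rules

Auxotrophy is predicted from gene presence/absence with per-vitamin
marker lists (shipped as an editable YAML): a vitamin is called
auxotrophic when any essential marker is absent, `total_loss` when all
are. For a partial loss of a single mapped gene the usable vitamer is
reported — losing only *thiC* leaves the thiamine pathway able to run on
the pyrimidine precursor HMP. Cobalamin needs three states, because it is
not universally essential: `producer` (pathway completeness at or above a
threshold, default 0.8), `dependent_auxotroph` (no pathway and only the
B12-dependent methionine synthase *metH*), and `flexible_nonproducer`
(*metE* present — the organism can scavenge B12 or do without). The
completeness score is always reported because completeness-based
classification can misread near-complete genomes that lost single genes.
The B1 marker set (*thiC*/*thiE*/*thiG*) is well grounded; the B3/B7/B9
lists are conventional stand-ins from the prediction literature and should
be replaced by study-specific tables — B9 calls are flagged
low-confidence in the output for exactly this reason.

Co-culture predictions follow from the calls: a pair grows if every
requirement of either member is producible by the partner, and the
optional methionine bypass lets a *metE*-carrying partner satisfy a B12
requirement by supplying methionine instead of the vitamin.

## The particle cross-feeding model

The model asks: can a population of $N_{deg}$ vitamin-producing degraders
on a spherical particle (radius $R$, default 50 µm) sustain
surface-attached auxotrophs against diffusive loss? Degraders settle at a
logistic steady state with mortality,

$$N^*_{deg} = K\left(1 - \frac{\mu + m}{r_{deg}(1 - c\,s)}\right)_+,$$

and release vitamins either by secretion ($Q = s N^*$) or by lysis
($Q = \mu N^* q_{deg}$, each lysed cell freeing its full quota). The
surface concentration solves the steady mass balance

$$\underbrace{4\pi D R\,(C_s - C_\infty)}_{\text{diffusive loss}}
  + \underbrace{N_{auxo}\, r_{\max}\frac{C_s}{K_S + C_s}\, q}_{\text{uptake}}
  = Q,$$

whose left side is strictly increasing in $C_s$: the root is unique and is
found by bisection to a relative tolerance of $10^{-10}$ on
$[0, C_\infty + Q/4\pi DR]$. Auxotroph growth is Monod in $C_s$, with an
optional second Monod factor for carbon co-limitation (off by default —
the phase diagrams describe vitamin-limited growth). Internally everything
is SI (seconds, metres, molecules); molar and hours appear only at the
interface.

An independent check integrates the radial diffusion PDE
$\partial_t C = D r^{-2}\partial_r(r^2 \partial_r C)$ by finite volumes on
400 logarithmically spaced shells out to $100R$, injecting the net source
through the inner face, with the far-field value held at the outer shell.
Because the simulated domain is finite, the algebraic solver is compared
on the same shell via the transfer coefficient
$4\pi D / (1/R - 1/R_{out})$; the two routes agree to well under 2%
across log-uniform random parameter sets, and the balance
source = diffusive loss + consumption closes to $10^{-8}$ at every solved
state.

Two release channels, two phase-diagram geometries over the
$(K_S, Y_{vit}^{-1})$ trait plane:

* **Secretion** produces an "L": growth at a fraction $\theta$ of maximum
  requires $K_S \le C_{s0}(1-\theta)/\theta$ (affinity must beat the
  concentration diffusion allows) *and*
  $q \le s N^*/(N_{auxo}\,\theta\,r_{\max})$ (consumption cannot outrun
  supply). Costless secretion helps monotonically; with a linear rate cost
  *and* non-recycled mortality ($m > 0$), an interior secretion optimum
  appears — under pure logistic dynamics with $m = 0$ the steady state is
  cost-insensitive, which is why both ingredients are needed.
* **Lysis** couples release to the quota, so
  $Q(\mu) = \mu K (1 - \mu/r_{deg})\, q$: in the sub-saturated regime the
  optimum sits at $\mu^* = r_{deg}/2$ — the auxotrophs do best when the
  degraders give up half their growth rate — and past it the degrader
  population collapses toward $\mu = r_{deg}$. Growth scales as
  $q/K_S$ where uptake is sub-saturated and consumption light, and joint
  scaling of $q$ and $K_S$ leaves growth exactly invariant (both supply
  and demand scale with $q$), which is the diagonal contour structure.

```{r, fig.width = 6, fig.height = 4}
p <- particle_params(secretion_rate = 0)
sweep <- sweep_release_rate(p, auxotroph_traits(1e-9, 20), mode = "lysis")
sweep
autoplot(sweep)
```

### Parameterization

Geometry and transport are physical: $R = 50$ µm,
$D = 5\times10^{-10}$ m²/s, $C_\infty = 0$. The population and release
defaults are this package's own calibration, chosen once so that the
default diagrams reproduce the qualitative trait-plane structure described
above with the measured traits in sensible positions: degrader and
auxotroph maximal rates 0.5 h$^{-1}$ (a fast marine copiotroph),
$K = 10^5$ degraders and $N_{auxo} = 10^5$ auxotrophs per particle (a
densely colonized 50-µm particle), secretion rate 56.8 molecules
cell$^{-1}$ s$^{-1}$ (placing the consumption-free surface concentration
at $3\times10^{-8}$ M), and the phase-diagram lysis rate at the optimal
$r_{deg}/2$. Default quotas are anchored to reported intracellular
contents: ~20 molecules/cell (biotin), $2\times10^3$ (cobalamin),
$2\times10^4$ (thiamine), $1.4\times10^5$ (niacin). Under these defaults
the two measured biotin auxotrophs ($K_S$ of 130 and 310 pM, quota ~20)
grow above 90% of maximum via secretion and below 10% via lysis, while
the low-affinity niacin auxotroph is slow through either channel; these
placements are parameterization-dependent regression anchors, not
measurements.

## What the synthetic generators emulate — and what they do not

Every consuming stage has a seeded generator with attached ground truth:
Monod-limited exponential curves truncated at a carrying OD; screen plates
in which planted auxotrophs lose growth without vitamins as a per-transfer
attenuation; genomes built by rule-consistent partial/total pathway loss
plus cobalamin states; log-uniform model parameter samples. Noise is
multiplicative log-normal (OD is positive and plate noise roughly
proportional; 5% CV by default). Deliberate simplifications: the `-V`
decay of an auxotroph is phenomenological (attenuation per transfer), not
a mechanistic intracellular quota-dilution model; annotation errors are
planted as status-toggling flips per genome and vitamin, so the planted
flip rate *is* the expected concordance error — convenient for
calibration, but real annotation errors hit genes, not phenotypes, and
only sometimes change a call; no lag phases, diauxie, plate-position
effects, or phylogenetic correlation among genomes. Passing closed-loop
tests therefore demonstrates the estimators are correct and calibrated on
their own assumptions, not that real plates and genomes satisfy those
assumptions.

## Numerical choices and limitations

Tolerances: bisection $10^{-10}$ relative; PDE integration `lsoda` with
banded Jacobian, continuing in chunks of five outer-domain diffusion times
until the surface derivative falls below $10^{-6}$ of scale (flagged,
with the residual, if four chunks do not suffice). Degenerate inputs are
typed errors: all-equal rates make $K_S$ unidentifiable; zero OD in both
screen conditions is a drop, not a deficit; a genome with neither *metE*
nor *metH* warns (methionine synthesis impossible under the rule set).
Tie-breaks in the window search are deterministic by construction.

Problem sizes used in the shipped tests — 150-isolate plates, 150-genome
cohorts, 100 Monte-Carlo kinetic replicates, 30×30 phase grids, 10-sample
PDE cross-checks — were chosen as the smallest sizes at which the
statistical assertions are stable.

The model deliberately omits particle colonization dynamics, multi-particle
exchange, flow, stochastic demography, and auxotroph population feedback
($N_{auxo}$ is fixed; the model reports growth-rate surfaces, not
trajectories). The rule engine does no ortholog inference: it consumes
pre-annotated presence/absence tables, and its calls are only as good as
the annotations and marker lists behind them.
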