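---
title: "Methods: a coupled bioeconomic size-spectrum model of open-access fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coupled bioeconomic size-spectrum model of open-access fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfish)
```

## The model

`openfish` simulates commercially harvested marine consumers ("fish",
including invertebrates) as biomass size spectra driven by net primary
production (NPP) and temperature, coupled in every grid cell to a
prognostic, open-access fishing fleet. The community is a small number of
"super-organisms" distinguished only by asymptotic mass $m_\infty$ — by
default small (30 g), medium (1 kg) and large (100 kg) groups — because
asymptotic size is the one trait that organises growth, mortality,
maturation and gear selectivity at this level of aggregation. There are no
explicit feeding links between the spectra, no movement of fish or vessels
between cells, and no management: each cell is an independent open-access
fishery.

### Ecology

The biomass density $f_k(m)$ (g wB m$^{-2}$ g$^{-1}$) of group $k$ evolves
under the McKendrick–von Foerster equation

$$\frac{\partial f_k}{\partial t} =
 -\frac{\partial}{\partial m}(\gamma_k f_k) + \frac{\gamma_k f_k}{m}
 - \Lambda_k f_k,$$

with individual growth $\gamma_k$ (g s$^{-1}$) and mortality $\Lambda_k$
(s$^{-1}$).

**Energy supply.** Trophic transfer from primary production makes the flux
density

$$\pi(m) = \frac{\mathrm{NPP_{wB}}}{m\,\ln\beta}
  \left(\frac{m}{m_\phi}\right)^{\tau},\qquad
  \tau = \frac{\ln\alpha}{\ln\beta} < 0,$$

available to consumers, where $\alpha$ is the trophic efficiency, $\beta$
the predator-to-prey mass ratio and $m_\phi$ a representative phytoplankton
mass. Each group receives a fraction $\phi_k$ of this flux (equal shares
$1/K$ by default), partitioned equally among the individuals present, so
the per-capita production-limited rate is $\xi_P = \phi\,\pi\,m/f$. This is
the only dimensionally consistent reading of the per-capita supply: an
area flux density divided by a number density. Because $\xi_P$ rises as $f$
falls, growth is *anti*-density-dependent: a thinned population feeds its
survivors faster.

**Physiological ceiling.** Realised intake cannot exceed the allometric
(von Bertalanffy) rate $\xi_{VB} = A m^b - k_a m$ with
$A = A_0\,a_A(T)$. The activity coefficient is closed as
$k_a = A\,m_\infty^{b-1}$, the unique choice for which growth stops exactly
at the asymptotic mass — the trait that defines the group. Realised intake
is $\xi_I = \min(\xi_P, \xi_{VB})$; a maturity sigmoid $\Psi(m)$ in log
mass, centred at the maturity mass $m_\alpha = 0.25\,m_\infty$ with the
same slope family as the gear selectivity, splits it into somatic growth
$\gamma = (1-\Psi)\,\xi_I$ and reproduction $\Psi\,\xi_I$.

**Temperature.** Growth and mortality each carry a van't Hoff–Arrhenius
factor $\exp[(\omega/k_B)(1/T_{\rm ref} - 1/T)]$ with separate activation
energies $\omega_{a,A}$ and $\omega_{a,\lambda}$ (both 0.45 eV centrally).
The family is normalised to 1 at $T_{\rm ref} = 283.15$ K (10 °C) so that
$A_0$ and the mortality factor are interpretable at a mid-latitude
reference; the reference is configurable.

**Mortality.** The empirical allometric form
$\Lambda = \lambda\, m^{-h} m_\infty^{h+b-1}$ is first order in biomass,
with the mass-independent factor proportional to
$e^{\zeta_1} A_0\, a_\lambda(T)$. The literature fixes only the
proportionality; `openfish` makes the constant explicit as
`mortalityScale`. Its default, 0.025, was fixed once by a demographic
viability analysis: with ceiling growth, the egg-production loop gain (egg
biomass surviving to recruitment per unit recruit biomass, over a lifetime)
must exceed 1 for a population to establish, and 0.025 gives all three
default groups gains comfortably above 1 at the central parameter values
while a one-prior-SD increase of $\zeta_1$ collapses the large group. That
knife-edge is a feature, not an accident: it is what lets harvest
observations discriminate mortality parameters in the calibration.

**Recruitment.** The boundary condition at the recruit mass
($m_0 = 10$ mg) is the harmonic mean — the smooth limiting-factor
combination — of two potential fluxes: $R_P = \phi\,\pi(m_0)\,m_0$, the
primary production flux available to juveniles, and
$R_e = \tfrac{s_e}{2}\int \Psi\,\xi_I\,(f/m)\,dm$, egg production
surviving to recruit size ($s_e$ the egg survival fraction; the factor
$1/2$ is the female share of spawning biomass). Recruitment is therefore
productivity-limited when stocks are healthy and stock-limited when
spawners are fished out.

**Phytoplankton partition.** $m_\phi$ interpolates geometrically between a
small-cell ($10^{-10}$ g) and a large-cell ($10^{-6}$ g) anchor with the
large-cell weight $x_L = \Pi^* (\mathrm{NPP}/\mathrm{NPP_{ref}})
/ e^{k_E T}$ clipped to $[0,1]$ — an Eppley-type closure in which warm,
oligotrophic water is dominated by small cells (longer food chains, less
energy to fish) and cold, productive water by large cells. The exact
partition used upstream of this package is not published with it; this
stand-in preserves the stated dependencies and is configurable
(`PiStar`, `kE`, `nppRef`, anchor masses).

### Economics

Harvest is linear in biomass and effort through the sigmoidal gear
selectivity $\sigma_k(m) = [1+(m/m_{\Theta,k})^{-c_\sigma/\delta_2}]^{-1}$
(sigmoidal in length — the physics of towed nets — converted to mass by the
cube law $m=\delta_1 l^{\delta_2}$). The threshold mass is
$m_\Theta = d_\Theta e_\Theta m_\alpha$, with $d_\Theta = (1, 0.5, 0.25)$
pushing the threshold of larger groups below maturity (juvenile bycatch of
large species). The harvest spectrum is $h_k = q\,\sigma_k E_k f_k$, with
catchability $q$ (technology) and nominal effort $E_k$ (W m$^{-2}$).

Effort follows average profit (open access, fishers chase their own mean
return, not the marginal one):

$$\frac{dE_k}{dt} = \kappa_e\,
 \frac{\mathrm{revenue}_k - \mathrm{cost}_k}{E_k},\qquad
 \mathrm{revenue}_k = q E_k p \int \sigma_k f_k\,dm,\quad
 \mathrm{cost}_k = c\,E_k,$$

with globally constant ex-vessel price $p$ and cost per unit effort $c$.
$\kappa_e$ carries the units demanded by this equation
(W$^2$ m$^{-2}$ \$$^{-1}$); its value $10^{-6}$ makes effort adjust to
profit changes on a roughly decadal timescale. At equilibrium revenue
equals cost, which pins the *selectable* biomass at the critical value

$$F^{\rm crit} = \frac{c}{p\,q},$$

a purely economic quantity: cells whose pristine selectable biomass falls
short of $F^{\rm crit}$ are never profitably fishable; richer cells are
fished down to it.

Default economic forcings are design choices of this package (the
originals derive from proprietary-scale databases): $p = 1.1\times10^{-3}$
\$ g$^{-1}$ (≈1100 \$/tonne), $c = 10^{-7}$ \$ W$^{-1}$ s$^{-1}$, initial
catchability $q_0 = 10^{-5}$ m$^2$ W$^{-1}$ s$^{-1}$. With these, the most
productive cells of the synthetic domain sit near the profitability margin
during the spin-up — as in the real ocean, where fishing predates the
technology ramp — while poor cells only become profitable as $q$ grows.

### Experiment protocol

The standard transient experiment spins the ecosystem up for 100 years at
constant $q_0$, then compounds catchability by 5 % yr$^{-1}$ for 200
years. Harvest rises to an interior peak and falls as more and more cells
are driven into stock-limited recruitment; biomass declines monotonically;
effort follows harvest with a lag set by $\kappa_e$.

## Numerics

* **Units and time base.** All internal computation is SI-like (g wet
  biomass, m$^2$, s). The model year is 360 days — 24 of the default
  15-day steps — and all "per year" conversions use it consistently.
* **Mass grid.** Each group has its own log-spaced grid from $m_0$ to
  $m_\infty$, 50 bins by default; bin centres are geometric means of the
  edges.
* **Advection and sinks.** The transport-decay cascade is discretised as a
  first-order upwind finite volume in mass (growth always transports
  biomass toward larger mass), with the recruitment flux entering the
  lowest edge and zero outflow at $m_\infty$ (growth vanishes there by
  construction). Within a step, all rates are frozen and each bin's
  balance $df/dt = a - b f$ — upwind inflow against outflow, dilation,
  mortality and harvest — is integrated *exactly*, the time-averaged
  biomass of each bin feeding the upwind inflow of the next. This
  exponential upwind sweep is conservative to round-off (asserted at
  $10^{-10}$ in the tests), unconditionally stable and
  positivity-preserving, with no CFL restriction from the stiff smallest
  bins, where mortality rates reach several per year times the timestep.
  Halving the timestep changes annual aggregates by well under the 1 %
  the test suite asserts.
* **Empty bins.** Where $f = 0$ the per-capita supply $\xi_P$ is formally
  unbounded; it is capped (at $10^3$ times the ceiling by default, and in
  the stepper simply by the $\min$ with $\xi_{VB}$), which is the correct
  physiology-limited limit.
* **Effort stiffness.** The average-profit equation is singular as
  $E \to 0$. Effort is floored at $10^{-15}$ W m$^{-2}$ so fisheries can
  re-enter when profitability returns, and the per-step update is limited
  to a doubling or halving — entry from the floor is then a fast
  exponential rather than an unbounded jump, entry and exit are treated
  symmetrically, and the limiter never binds near equilibrium where
  revenue ≈ cost.
* **Forcing in time.** A 12-row forcing is treated as a cyclic monthly
  climatology and linearly interpolated to step midpoints; a single row is
  constant forcing.

## Monte Carlo calibration

The calibration pipeline re-estimates uncertain ecological parameters from
peak-harvest observations aggregated at the scale of Large Marine
Ecosystems (LMEs):

1. **Priors** (`priorTable()`, `samplePriors()`): normal or uniform per
   parameter, parameterised by mean and SD; uniform bounds are
   $\mu \pm \sqrt{3}\sigma$ so the stated moments are matched exactly;
   positivity-constrained normals are resampled until positive; the
   trophic scaling $\tau$ is derived per draw, never sampled. The growth
   constant prior is N(4.46, 0.50) on the g$^{1-b}$ yr$^{-1}$ scale of the
   reported ensemble means (the same table prints an inconsistent mean of
   0.46 for it; the package treats the reported-ensemble scale as
   authoritative and leaves the prior overridable).
2. **Ensemble runs** (`runEnsemble()`): one spin-up + ramp experiment per
   draw; at the year of peak global harvest the per-LME harvests, H:B
   ratios and size-group harvests are recorded.
3. **Constraints** (`scoreEnsemble()`): (i) peak global harvest inside a
   window — the real-data window is 70–150 × 10$^{12}$ g wB yr$^{-1}$; in
   synthetic mode the window is 0.7–1.5 times the total observed peak,
   the same relative generosity transported to the synthetic domain;
   (ii) size structure: medium ≥ 30 % of small, large in [10 %, 80 %) of
   small; (iii) H:B ≤ 0.4 yr$^{-1}$ at every reference LME. Interval
   closures: the harvest window and the H:B cap are inclusive, the 80 %
   size bound exclusive, as printed.
4. **Ranking** (`selectEnsemble()`): survivors are ranked by the Pearson
   $r^2$ of area-specific per-LME peak harvests against observations
   (Spearman and log10-Pearson are reported alongside), and the best
   `fraction` of the *total* draw count is kept, ties broken by earlier
   draw id. Plain $r^2$ is the default ranking because the upstream
   selection rule is quoted in those terms; the selected count is
   configurable because the upstream report is ambiguous between "100"
   and "105" members.
5. **Shift report** (`calibrationReport()`, `ksCompare()`): per-parameter
   optimised vs non-optimised means, SDs and two-sample
   Kolmogorov–Smirnov p-values (via `stats::ks.test`).

In real-data mode, `readObservedHarvest()` ingests reconstruction-style
long CSVs (LME, year, size group, tonnes), applies the top-ten-year peak
estimator, reallocates the "other" size class proportionally, and flags
the 11 standard exclusions (10 high-latitude LMEs with biased satellite
NPP, plus the Black Sea inland system) and the 8 well-assessed reference
LMEs from packaged metadata.

## The synthetic data

`syntheticForcing()` emulates the *environmental contrast* of the LME
system: NPP log-spaced over 500–3000 mg C m$^{-2}$ d$^{-1}$, temperatures
spanning 0–30 °C in a seeded pairing that decorrelates the two gradients,
cell areas of 5 × 10$^{12}$ m$^2$ so a 16-cell grid has the combined area
scale of the real LME system (~10$^{14}$ m$^2$), and a round-robin
pseudo-LME partition. `generateSyntheticObservations()` runs a known-truth
model and perturbs its per-LME peak harvests with lognormal noise (0.3 in
log10 units, i.e. factor-of-two scale errors, emulating catch
reconstruction uncertainty).

What the synthetic data do *not* emulate: spatial autocorrelation and
coastline geometry, seasonality (optional and idealised), fishing before
the experiment begins, reporting biases that are structured rather than
lognormal, and the species-level heterogeneity inside each size group.
Tests passing on synthetic data therefore demonstrate the *internal*
consistency of the method — the dynamics behave as described and the
calibration recovers known truths under its own noise model — not skill
against real oceans.

## Problem sizes used by the tests

The shipped tests and the reproduction script choose desk-scale problem
sizes: 12–25 mass bins per group, 15–45-day steps, single cells for
equilibrium oracles (hundreds of model years), a 16-cell grid for the
transient-ramp and calibration experiments, and a 200-member mini-ensemble
at 16 bins and 30-day steps for parameter recovery. The monotone-decline
check on ramp biomass uses a tolerance of 0.1 % of the ramp-start biomass
per year: deep in depletion (biomass below ~0.1 % of pristine) the
open-access equations support genuine small-amplitude boom-bust cycles as
effort collapses and re-enters, and the tolerance separates that
end-state flutter from the monotone depletion signal.

## Known limitations

* The phytoplankton partition, reproductive allocation and recruitment
  closures are documented stand-ins for unpublished upstream forms; all
  are parameter-swappable.
* First-order upwind advection is diffusive in mass; spectra near sharp
  selectivity edges are smoothed. Halving the timestep changes annual
  aggregates by well under 1 % (asserted in the tests), but bin counts
  below ~12 per group visibly smear the spectrum.
* The open-access equilibrium is approached on the $\kappa_e$ timescale;
  runs shorter than a few hundred years at constant forcing retain
  percent-level offsets from $F^{\rm crit}$.
* Forcing I/O is CSV-based (site and grid layouts); gridded binary
  climatology formats are out of scope.
* No fish or vessel movement, no management, no subsidies, no
  size-dependent price: these are structural assumptions of the model
  family, not omissions of the implementation.
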