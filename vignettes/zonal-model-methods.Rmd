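---
title: "Zonal rate modeling of membrane chromatography modules: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal rate modeling of membrane chromatography modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memchrom)
```

## The problem

Membrane adsorbers are convection-dominated chromatographic media: ligands
sit on a macroporous membrane, mass transfer is fast, and modules can be
operated at several column volumes (CV) per minute.  Their drawback is a
low binding capacity compared with packed beds, which makes semi-continuous
operating modes — sequential counter-current loading, or two-column cyclic
schemes with fraction recycling (iCCC) — particularly attractive: they
raise capacity utilization, the scarce resource.

Wrap-around membrane modules complicate modeling.  The membrane is wound
around an inner collection cylinder; the feed enters axially, spreads
through an annular gap, crosses the membrane radially, is collected in the
inner cylinder, and leaves through an outlet pipe.  A single 1-D column
model cannot represent the resulting residence-time distribution (RTD),
which shows a sharp front and pronounced tailing.

`memchrom` models the module as five coupled zones, each with its own
convection–dispersion balance:

1. **inlet pipe** — plug-flow pipe,
2. **annular gap** — pipe with distributed radial offtake (flow splitting),
3. **membrane** — radial-flow general-rate medium with adsorption,
4. **inner cylinder** — pipe with distributed radial intake (stream
   merging),
5. **outlet pipe** — plug-flow pipe.

## Model equations

Zones 1, 2, 4 and 5 follow the axial convection–dispersion equation

$$\frac{\partial c_i}{\partial t}
  = -u \frac{\partial c_i}{\partial x}
  + D_{ax} \frac{\partial^2 c_i}{\partial x^2},$$

with zone-specific velocity $u$ and dispersion coefficient $D_{ax}$.  The
annular gap additionally splits the axial flow: under the
constant-resistance assumption every gap cell diverts the same radial flow
$\dot V_r = \dot V_{in}/n_2$ into the membrane, so the axial flow decays
linearly and reaches exactly zero at the closed end
($\dot V_x = \dot V_{x+1} + \dot V_r$).  The inner cylinder merges the
streams with flow-weighted mixing,
$\dot V_{x+1} c_{i,x+1} = \dot V_x c_{i,x} + \dot V_r c_{i,r}$ — the
concentrations of the merging streams are generally different.

The membrane (zone 3) adds adsorption through a lumped linear-driving-force
(LDF) law with a salt-dependent competitive Langmuir equilibrium:

$$\frac{\partial c_i}{\partial t}
  = -u_{int} \frac{\partial c_i}{\partial r}
  + D_{ax} \frac{\partial^2 c_i}{\partial r^2}
  - \frac{1}{\varepsilon_m}\frac{\partial q_i}{\partial t},
  \qquad
  \frac{\partial q_i}{\partial t} = k_La \left(q_i^*(c, c_{mod}) - q_i\right),$$

$$q_i^* = \frac{H_i c_i}{1 + \sum_j (H_j/q_{max,j})\, c_j}
          + L_1 c_{mod} c_i,
  \qquad
  q_{max,i} = a_{1,i} c_{mod} + a_{2,i},
  \qquad
  H_i = b_{1,i}\, c_{mod}^{\,b_{2,i}}.$$

$u_{int} = u/\varepsilon_m$ is the interstitial velocity, $k_La$ (1/min)
lumps the film/pore resistance with the effective transfer area, and the
modifier (salt) concentration $c_{mod}$ is transported as a non-binding
component.  The modifier never enters the competitive denominator; its
whole effect runs through $q_{max}(c_{mod})$ and $H(c_{mod})$.  On ion
exchangers binding weakens with salt ($b_2 < 0$, $L_1 = 0$); on
hydrophobic-interaction media it strengthens ($b_2 > 0$) and the linear
term $L_1 c_{mod} c_i$ is active.

### Why the LDF form and not the literal sink

A sink written directly as $k_La\,(c_i - q_i)$ mixes a liquid concentration
(g/L liquid) with a loading (g/L membrane) and does not close the mass
balance dimensionally.  The package's default therefore treats the term as
linear-driving-force shorthand: the solid balance relaxes $q_i$ toward the
Langmuir equilibrium $q_i^*$ and the liquid loses exactly what the solid
gains.  This conserves mass to solver precision and reproduces the Langmuir
equilibrium at steady state.  The literal form remains available
(`kinetics = "literal"` in `simulate_module()`) for sensitivity checks; its
removed mass is still booked so balances can be audited.

## Discretization and numerics

The five zones are discretized with finite volumes: first-order upwind
advection, central second-order dispersion, and closed-vessel (Danckwerts)
boundary conditions at each zone interface — coupling between zones is
purely advective, which is the natural reading for abrupt geometry changes
and keeps every zone's RTD well defined.  The membrane is discretized as
$n_2$ independent radial columns, one per annular-gap cell; each column
discharges into its matching inner-cylinder cell, so the split/merge
mapping is bijective by construction and no axial dispersion acts across
columns (the radial-only reading of membrane dispersion).

The semi-discrete system is linear in the transport part; it is assembled
once per operating step as a sparse operator and integrated with a stiff
sparse ODE solver (`deSolve::lsodes`), relative tolerance $10^{-6}$,
absolute tolerance $10^{-9}$ g/L.  Stiffness is real: the fitted
dispersion coefficients span six orders of magnitude (9×10⁻⁴ cm²/s in the
inlet and gap, 5×10⁻³ cm²/s in the membrane, 250 cm²/s in the collection
zones, which therefore behave as ideal stirred tanks, Bodenstein numbers
around 10⁻⁴).  Negative concentrations are clipped only in reported
chromatograms, never in the solver state.

Grid sizes: `simulate_module()` defaults to 20 cells for zones 1/2/4/5 and
30 radial membrane cells.  The packaged fixtures and the test suite run at
8/8/12/8/8 (and coarser for multi-cycle process studies); at that
resolution the tracer outlet curve changes by about 1% when the grid is
doubled, which is the accuracy regime the qualitative process studies
need.  All test and fixture problem sizes are chosen on that basis and
stated alongside the fixtures.

## Tracer analysis

`moments()` computes RTD moments by trapezoidal quadrature after
subtracting a baseline estimated as the median of the leading 5% of
points (detector offsets otherwise bias the second moment; the synthetic
tracer fixtures include a tracer-free acquisition window so this estimator
sees genuine baseline).  Voidage follows from
$\varepsilon = (\bar t - \bar t_i)\,\dot V / V_m$, with the extra-column
time $\bar t_i$ measured by a blank run — it is a required input, never
estimated from the module run itself.

Dispersion is inverted from the normalized variance under closed-vessel
($\sigma^2/\bar t^2 = 2x - 2x^2(1 - e^{-1/x})$, $x = D_{ax}/vl$) or
open-vessel ($2x + 8x^2$) assumptions.  The closed-vessel relation is
inverted by a bracketed root search on $\log_{10} x$ spanning $x$ from
$10^{-12}$ to $10^{6}$, which tolerates the full dispersion range above;
its normalized variance is only attainable in $(0, 1)$ and inputs outside
that range are rejected by name.  The open-vessel relation inverts in
closed form.  In the small-dispersion regime the two estimates agree to
first order; the relative gap grows like $2.5\,\sigma^2/\bar t^2$.

### Tailing and what "more mixing" does to it

The flow regime classifies by Bodenstein number $Bo = ul/D_{ax}$ with the
plug-flow/stirred-tank transition at 5.  Turning the collection zones into
stirred tanks adds an exponential tail to the RTD.  Note a subtlety the
package's property tests respect: the *third central moment* of the outlet
curve (the absolute tailing magnitude, additive over zones in series)
grows monotonically with collection-zone dispersion, while the
*normalized skewness* can decrease, because the membrane zone itself is
dispersion-dominated at low flow ($Bo \approx 1$) and already right-skewed,
and extra mixed volume adds variance faster than third moment.  The
tailing property is therefore asserted on the third central moment.

## Geometry assumptions

The internal dimensions of laboratory wrap-around modules (gap and
cylinder volumes, pipe lengths) are not published.  The package treats the
membrane volume $V_m$ (3 mL for the laboratory preset, 8 mm bed height)
and the total voidage $\varepsilon = 0.8$ as the anchors measured by
tracers, and distributes 16% of $V_m$ over the hold-up zones (2/6/6/2% for
inlet, gap, cylinder, outlet).  The membrane porosity is then derived from
the voidage balance
$\varepsilon V_m = V_1 + V_2 + V_4 + V_5 + \varepsilon_m V_m$, giving
$\varepsilon_m = 0.64$ — a typical macroporous-membrane value.  These are
documented assumptions, not fitted quantities; all first-moment
(voidage/residence) results are independent of how the hold-up is
distributed, while tailing shapes are not.

## Isotherm determination

Batch adsorption interprets supernatant measurements through two mass
balances: binding, $q_i = (c_{Feed,i} - c^*_i)\,V_{total}/V_{Ads}$, and
elution, $q_i = c^*_i\,V_{total}/V_{Ads}$; for a loss-free experiment both
give the same loading, which the synthetic generator reproduces exactly.

`fit_isotherm()` minimizes the summed squared loading residuals over all
points and components with Levenberg–Marquardt, starting from a
deterministic linearized-Langmuir initializer (per-level single-component
Langmuir fits, then regressions of $q_{max}$ on $c_{mod}$ and
$\log H$ on $\log c_{mod}$) plus four jittered restarts under a fixed
seed — the Henry power law creates local minima.  $b_1$ is fitted on the
log scale; a soft penalty keeps $q_{max}$ positive over the observed
modifier range.  Loadings enter the objective unfloored: symmetric
supernatant noise must stay symmetric or the fit is biased.

**Identifiability.**  A culture-derived feed diluted into a series, bound
to a single small membrane disc, does not determine all parameters: trace
side components never approach saturation (their $q_{max}$ is invisible)
and a small $V_{Ads}/V_{total}$ ratio amplifies supernatant noise onto the
loadings roughly twentyfold.  The package's recovery and Monte-Carlo tests
therefore use a deliberately identifiable synthetic design —
concentration-ratio-varied feeds including concentrated purified stocks,
and a membrane stack ($V_{Ads} = 1$ mL in a 5 mL bath).  On that design
the noise-free fit recovers the generating parameters to better than
$10^{-6}$ relative, and at 5% multiplicative noise the pooled median
parameter error over 20 seeded replicates stays below 15%.  Individually,
the capacity–salt slopes $a_1$ remain loose ($q_{max}$ varies only ~17%
across the modifier window) and $b_1$ is an extrapolation of the Henry law
to 1 M; the within-range functions $H(c_{mod})$ and $q_{max}(c_{mod})$ are
determined much more sharply than those raw coordinates.

## Synthetic presets and what they do (and do not) show

All isotherm presets are SYNTHETIC: invented, clearly labeled, and not
fitted to any experimental data.  The ion-exchange preset places the three
feed components — antibody product, a weak binder, a strong binder — in
the elution order weak < product < strong on an ascending salt gradient,
with the strong binder only mildly stronger than the product at load salt
(a minor congener).  That last choice matters: a much stronger side
component would turn extended sequential loading into displacement
chromatography, with the product rolling off the first module — contrary
to the capture behavior these processes are designed around.  The
hydrophobic-interaction preset mirrors the order on a descending gradient
and activates the linear term $L_1$.

The feed presets are 1 g/L product with 0.2 g/L total side components
(validation-style) and 5 g/L with 1 g/L (case-study-style).

Passing tests on these fixtures demonstrate internal consistency of the
model chain (conservation, limits, qualitative process behavior).  They do
not validate the model against real modules: real feeds contain many more
species, real isotherm surfaces are rougher than the two-parameter salt
laws, and real modules have hold-up geometries we only assume.

## Process orchestration

**Sequential loading.**  Modules are chained in series; module $k$'s
outlet chromatogram becomes module $k+1$'s inlet (linear interpolation on
the reporting grid).  Loading stops when the product concentration at the
last outlet reaches a threshold fraction of the feed concentration — 1%
by default, a documented choice.  The head module is then eluted and the
chain rotates.  Loading-phase/batch-phase overlap is checked logically (a
warning, or an error in strict mode, when the protocol outlasts the
loading phase); the simulator runs modules one at a time because every
reported quantity depends on masses and durations, not hardware
concurrency.  The loading-gain study reports total protein bound on the
first module at breakthrough of the last — the quantity a loading
measurement sees — with the product share reported separately; on the
fixtures the gain is strictly positive, monotone in the module count, and
saturating.

**iCCC.**  One ion-exchange and one hydrophobic-interaction module run in
cycles.  Each elution chromatogram is cut at three user-chosen elution
volumes (cut points snapped to the reporting grid so the four windows
partition the eluate exactly); the default routing recycles the IEX front
onto IEX, transfers the IEX middle and tail to HIC, recycles the HIC front
onto HIC, takes the HIC middle as product, and returns the HIC tail to
IEX.  Recycled fractions are stored as volume-weighted pools, assumed
conditioned into the next cycle's loading buffer, and prepended to the next
load; there is no inter-cycle degradation and no cut-point optimizer (cut
points are hand-picked inputs).  Accumulation — the failure mode of
tailing-dominated modules — is flagged when the product mass recycled onto
the IEX column grows monotonically over three consecutive cycles by more
than 10% in total, or when a cycle's IEX load exceeds the static capacity
$q^*(c_{feed}) V_m$; the run continues so the failure mode can be
inspected.  Cyclic steady state is declared when product and recycle pool
masses all change by less than a tolerance (3% default) between
consecutive cycles.

On the fixtures, the tailing (laboratory-module) variant — cut as such
peaks force one to cut, with the sharp-fronted product bulk in the first
fraction — accumulates product on the IEX side and never reaches steady
state, while the symmetric variant (a membrane stack in a plain column:
negligible hold-up zones, uniform low dispersion) transfers the product
cleanly and reaches steady state within a handful of cycles.

## Performance case-study arithmetic

The batch-vs-sequential engine is deliberately plain arithmetic, driven by
a `case_study_spec()`:

* capacity (batch) $=$ harvest mass / total membrane volume used;
  sequential capacity multiplies by the configured gain factor (1.71 for a
  four-module train);
* cycle time $=$ loading CV / load flow $+$ protocol CV / protocol flow,
  with loading CV $=$ capacity / titer (module volume cancels);
* per-cycle productivity $=$ capacity × 1440 / cycle time (g/L/day);
* eluent consumption counts **total pumped liquid** — feed plus the full
  protocol buffer volume — per gram of product; that is the accounting
  under which the batch and sequential figures (2.45 and 1.52 L/g) are
  mutually consistent, and a buffer-only variant is available behind a
  flag (it yields 2.25 L/g for the batch case);
* sequential sizing divides the batch membrane volume by the gain factor
  (reported rounded to 1 L, or 0.1 L below 10 L) and derives the cycle
  count from the unrounded volume;
* batch-to-batch productivity divides capacity by a configurable harvest
  interval (365/40 ≈ 9.1 days by default);
* sequential total runtime is reported as cycles × modules × cycle time —
  a non-overlapped upper bound, labeled as such.

The pressure model is linear: per-module coefficient (bar per CV/min) ×
modules × flow + instrument offset, checked against a 4 bar limit; a
four-module train at 3 CV/min contributes 2.4 bar, 3.5 bar with the
1.1 bar instrument offset.

## Known limitations

* Zones are 1-D compartments; no CFD of the hold-up volumes, and membrane
  dispersion acts along the radial coordinate only.
* Mass transfer is lumped into a single $k_La$; no pore/surface diffusion
  split.
* The hold-up volume distribution is an assumption anchored only by total
  voidage; tailing shapes (not first moments) depend on it.
* The competitive Langmuir law with power-law salt dependence is a
  fast-forward screening model, not a thermodynamically rigorous
  description (no SMA or mixed-mode formalism).
* Sequential scheduling is logical, not co-simulated; pumps, valves and
  dead-volumes between modules are not modeled.
* Cut points and module counts are inputs; the package provides no
  optimizer for them.
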