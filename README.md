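# memchrom

Mechanistic simulation of radial-flow **membrane chromatography modules**
and of the semi-continuous capture processes built from them, for
downstream-processing engineers evaluating batch versus continuous
antibody capture.

Wrap-around membrane modules (Sartobind-type laboratory devices and their
scale-ups) have a fluid-dynamic quirk: the feed enters axially, spreads
through an annular gap, crosses the membrane radially, and is collected by
an inner cylinder — producing outlet peaks with a sharp front and heavy
tailing that no single 1-D column model reproduces. `memchrom` models the
module as a **five-zone network** (inlet pipe, flow-splitting annular gap,
radial-flow membrane, stream-merging inner cylinder, outlet pipe), each
zone carrying its own convection–dispersion balance

$$\partial_t c_i = -u\,\partial_x c_i + D_{ax}\,\partial_x^2 c_i,$$

with flow splitting $\dot V_x = \dot V_{x+1} + \dot V_r$ in the gap,
flow-weighted merging
$\dot V_{x+1} c_{i,x+1} = \dot V_x c_{i,x} + \dot V_r c_{i,r}$ in the
cylinder, and lumped linear-driving-force binding in the membrane,

$$\partial_t q_i = k_La\,(q_i^* - q_i), \qquad
  q_i^* = \frac{H_i c_i}{1 + \sum_j (H_j/q_{max,j})c_j} + L_1 c_{mod} c_i,$$

where capacity and Henry coefficient depend on the salt (modifier)
concentration: $q_{max,i} = a_{1,i} c_{mod} + a_{2,i}$,
$H_i = b_{1,i} c_{mod}^{b_{2,i}}$.

On top of the single-module simulator the package provides:

* **Tracer analysis** — RTD moments, voidage
  $\varepsilon = (\bar t - \bar t_i)\dot V / V_m$, axial dispersion by
  closed- and open-vessel Danckwerts inversion, Bodenstein numbers and
  flow-regime classification.
* **Isotherm tools** — batch-adsorption mass balances (binding and
  elution), the salt-dependent competitive Langmuir model, and
  multi-start least-squares fitting (`fit_isotherm()`, an S3 model object
  with `coef`/`predict`/`residuals`/`plot` methods).
* **Process orchestration** — batch cycles, sequential counter-current
  loading with breakthrough-triggered column switching and loading-gain
  studies, and two-column iCCC cycles with fraction recycling,
  accumulation detection and cyclic-steady-state detection.
* **Performance case studies** — the batch-vs-sequential arithmetic
  (capacity, cycle times, productivities, eluent consumption, pressure
  constraint) for fed-batch harvest scenarios.
* **Synthetic fixtures** — deterministic generators (tracer curves,
  batch-adsorption datasets, three-component feeds, clearly-labeled
  SYNTHETIC isotherm presets) so everything is testable without external
  data.

## Worked example: batch versus sequential capture

A fed-batch upstream delivers 2000 L of harvest at 5 g/L IgG, 40 batches
per year. The batch process uses 300 runs on 5 L membrane modules; the
sequential process loads four modules in series at 3 CV/min (capacity gain
factor 1.71), both with a 15 CV wash/gradient/regeneration/equilibration
protocol at 5 CV/min:

```r
library(memchrom)
spec <- case_study_spec(fermenter_volume = 2000, titer = 5,
                        module_volume = 5, batch_runs = 300)
run_case_study(spec)
```

```
Performance report (batch):
  capacity:                   6.667 g/L membrane
  total membrane volume:    1.5e+03 L
  runs/cycles:                  300
  runtime:                    16.33 h
  productivity (cycle):        2939 g/L/day
  productivity (b2b):          0.73 g/L/day
  eluent consumption:          2.45 L/g
  pressure:                    2.10 bar (limit 4.0, ok)
Performance report (sequential):
  capacity:                  11.400 g/L membrane
  total membrane volume:        877 L
  runs/cycles:                   44
  runtime:                    11.03 h
  productivity (cycle):        4366 g/L/day
  productivity (b2b):          1.25 g/L/day
  eluent consumption:          1.52 L/g
  pressure:                    3.50 bar (limit 4.0, ok)
Sequential vs batch: +71.0% capacity, +48.6% productivity, -38.1% eluent
```

Reading this: the sequential train binds 71% more product per litre of
membrane because downstream modules absorb the head module's
breakthrough, which lifts per-cycle productivity by ~49% (2939 → 4366
g/L/day) and cuts total pumped liquid per gram of product by ~38% (2.45 →
1.52 L/g), while the 877 L of membrane replaces 1500 L. The four-module
train at 3 CV/min stays at 3.5 bar, inside the 4 bar limit of the first
module.

A mechanistic example — simulate a tracer pulse through a 3 mL laboratory
module and recover its voidage by moment analysis:

```r
cv <- make_tracer_curve(fixture_spec(), flow = 1)   # zonal-model RTD
m <- moments(cv)
voidage(m$t_mean, attr(cv, "t_instrument"), flow = 1, Vm = 3)
```

```
t_mean = 5.475 min, variance = 2.743 min^2
voidage = 0.800
```

`simulate_module()` runs full bind-and-elute schedules (gradients in the
modifier, multi-step protocols), `run_sequential()` /
`loading_gain_study()` chain modules in series, and `run_iccc()` runs the
coupled IEX + HIC recycling process. A thin command-line wrapper is
installed at `inst/cli/memchrom` (subcommands `simulate`, `tracer-fit`,
`fit-isotherm`, `run-sequential`, `run-iccc`, `case-study`, `fixtures`).

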