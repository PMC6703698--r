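# equihemo

A one-dimensional computer model of the equine arterial circulation.

Horses are large enough that arterial haemodynamics differ qualitatively
from the human case: lumen diameters near 7 cm, a resting heart rate of
40 bpm, cardiac output above 30 L/min, very large Womersley numbers (flat
velocity profiles with thin wall boundary layers), and — in the standing
animal — gravitational pressure differences of ±50 mmHg between head and
limbs.  `equihemo` is a research tool for studying intra-arterial pressure
and flow waveforms throughout the equine arterial tree: where invasive
measurement is ethically and technically difficult, the model predicts
local pressures, flow profiles, wave reflections and their response to
altered wall properties or vascular tone.

## The model

The packaged anatomy describes **117 tapered elastic segments** (62
terminal) of the equine arterial tree.  In each segment the area-averaged
continuity and momentum equations

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\int_A u^2 dA
  = -\tfrac{A}{\rho}\partial_x P + \tfrac{2\pi R}{\rho}\tau_w + A g\cos\theta$$

are solved with an implicit second-order finite-difference scheme (Newton
iteration each step; the linear systems are solved exactly in
O(nodes) by per-segment condensation plus a leaf-to-root sweep over the
junction tree).  Wall friction $\tau_w$ and the momentum-flux term use
Witzig–Womersley oscillatory-flow theory fed by the previous cycle's flow
harmonics.  The wall is nonlinearly elastic with area compliance
$C_A = s\,A\,C_p(P)/(\rho\,\mathrm{PWV}(\bar d)^2)$; terminals carry
three-element Windkessels (parallel total 0.14 mmHg·s/ml, regional flow
fractions heart/brain/muscle/kidney/splanchnic/other =
5/10/15/20/30/20 %, $R_1 = Z_c$, terminal compliance 20 % of the systemic
total); the inlet is a four-phase time-varying elastance left ventricle
($E_{max} = 0.26$ mmHg/ml, HR 40 bpm, systolic duration 478 ms) with
coronary modulation.  Post-processing provides cardiac output, ejection
fraction, regional flow distribution, foot-to-foot pulse wave velocity
(second-derivative wave feet regressed against distance) and wave power
analysis ($d\pi_\pm = \pm(dP \pm Z_c\,dQ)^2/4Z_c$).

See the methods vignette (`vignettes/equine-1d-model.Rmd`) for the
discretisation, the stabilisers, parameter provenance and known
limitations.

## Worked example

```r
library(equihemo)

net <- equine_segment_table() |>
  arterial_network() |>
  derive_terminal_parameters()

sim <- simulate_hemodynamics(net, config = solver_config(n_cycles = 8))
sim
#> <hemo_sim> 117 segments, 1225 nodes, 8 cycles, gravity off
#>   CO 42.4 L/min | SV 1060 ml | EF 68.7% | root 129/70 mmHg (MAP 104)

glance(sim)[, c("co_l_min", "sv_ml", "ef_pct", "map_mmHg", "tvr_mmHg_s_ml")]
#>   co_l_min sv_ml ef_pct map_mmHg tvr_mmHg_s_ml
#> 1     42.4  1060   68.7      104         0.148

hemodynamic_summary(sim)$regional_flow
#>       region q_mean_ml_s share_pct
#> 1      brain        73.9     10.46
#> 2      heart        31.2      4.41
#> 3     kidney       135.9     19.23
#> 4     muscle       111.8     15.82
#> 5      other       148.3     20.98
#> 6 splanchnic       205.7     29.10
```

The one-row `glance()` gives the global haemodynamics of the converged
final cycle: cardiac output 42.4 L/min of mean aortic-root flow, a stroke
volume of 1060 ml ejected at 68.7 % ejection fraction, root pressures
129/70 mmHg around a mean of 104 mmHg, and a total vascular resistance
(MAP/CO) of 0.148 mmHg·s/ml.  The regional table shows how that output is
distributed over the terminal beds — close to the reference fractions the
terminal resistances were allocated to, with small departures caused by the
series resistance of the conduit vessels.  Adding `gravity = TRUE` raises
mean root pressure to ~114 mmHg, lowers head pressures and raises limb
pressures, and redistributes flow toward the gravity-assisted beds.

Waveforms at any site, wave power and PWV:

```r
probe_waveform(sim, "49", 355)        # common carotid, mid-vessel
probe_wave_power(sim, "1", 0)         # aortic-root wave power decomposition
autoplot(sim)                         # pressure/flow at the canonical probes
```

A thin command-line driver with `simulate`, `analyze`, `validate` and
`make-fixture` subcommands is installed under `inst/cli/equihemo.R`.

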