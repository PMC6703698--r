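---
title: "A 1D model of the equine arterial circulation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 1D model of the equine arterial circulation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equihemo)
```

## The model

`equihemo` simulates pressure and flow wave propagation through the major
arteries of the horse.  The arterial tree is described by 117 straight
tapered elastic segments (62 of them terminal), assembled from post-mortem
equine anatomy: per-segment length, proximal/distal lumen diameter,
branching angle in the sagittal plane, and distensibility at the reference
pressure of 100 mmHg.  In each segment the area-averaged continuity and
momentum equations are solved for pressure $P(x,t)$, flow $Q(x,t)$ and
cross-sectional area $A(x,t)$:

$$\partial_t A + \partial_x Q = 0,$$
$$\partial_t Q + \partial_x\!\int_A u^2\,dA
  = -\frac{A}{\rho}\,\partial_x P + \frac{2\pi R}{\rho}\,\tau_w + A\,g\cos\theta,$$

with blood density $\rho = 1050$ kg/m$^3$, viscosity $\mu = 0.004$ Pa·s,
and an optional gravitational body force for the standing animal
($g = 9.81$ m/s$^2$, $\cos\theta$ the projection of the segment axis on the
downward vertical).

**Wall law.**  Area compliance is
$C_A = s\,\frac{A}{\rho\,\mathrm{PWV}(\bar d)^2}\,C_p(P)$ with
$C_p(P) = a_1 + b_1/[1 + ((P - P_{maxC})/P_{width})^2]$ and the empirical
inverse power law $\mathrm{PWV}(\bar d) = a_2/\bar d^{\,b_2}$
($a_1 = 0.76$, $b_1 = 5$, $P_{maxC} = 10$ mmHg, $P_{width} = 21$ mmHg,
$a_2 = 13.3$, $b_2 = 0.3$, global scale $s = 0.75$).  For the packaged
equine segments the tabulated distensibility column (which already carries
the 0.75 scaling) is authoritative; the diameter law is used for synthetic
segments and as a consistency check.  Because $C_A \propto A$, the law
integrates in closed form:
$A(P) = A_{ref}\exp[\delta\,(G(P) - G(P_{ref}))]$ with
$G(P) = a_1 P + b_1 P_{width}\arctan((P - P_{maxC})/P_{width})$ — exact,
strictly monotone and always positive, so no quadrature table or clamping
of the area is ever needed.  The inverse $P(A)$ uses a
bisection-safeguarded Newton iteration on $G$.

**Oscillatory flow.**  Wall friction and the momentum-flux (convective)
term depend on the instantaneous velocity profile, which a 1D model does
not carry.  Following Witzig–Womersley theory, the profile is reconstructed
from the flow harmonics of the *previous* cardiac cycle (the solution is
periodic), with harmonic-specific Womersley number
$\alpha_k = R\sqrt{\rho\,k\omega/\mu}$ and Bessel-function profiles.  The
oscillatory theory applies to vessels with fundamental $\alpha > 3$ — 75 %
of the packaged segments at 40 bpm — while smaller vessels use the
Poiseuille friction and flat-profile momentum-flux closure.  Complex
$J_0, J_1$ are evaluated from the ascending series ($|z| \le 14$) and
Hankel's asymptotic expansion otherwise, with exponential scaling so that
extreme Womersley numbers never overflow; the implementation is verified
against an independent quadrature representation of $J_n$.

**Boundary conditions.**  Each terminal segment carries a three-element
Windkessel $(R_1, R_2, C_T)$.  The parallel combination of all terminal
resistances is 0.14 mmHg·s/ml, split across body regions in the reference
proportions (heart 5 %, brain 10 %, muscle 15 %, kidney 20 %, splanchnic
30 %, other 20 %) and, within a region, proportionally to terminal distal
area.  $R_1$ equals the terminal characteristic impedance
$Z_c = \rho\,\mathrm{PWV}/A$ (minimal high-frequency reflection; if
$Z_c \ge R_T$ it is clamped to $0.9\,R_T$).  Terminal compliances are
proportional to the distal area compliance and total 20 % of the systemic
vascular compliance.  The proximal boundary is a four-phase time-varying
elastance left ventricle ($E_{min} = 0.01$, $E_{max} = 0.26$ mmHg/ml,
$V_0 = 0$, $\kappa = 55\times10^{-6}$ s/ml, $P_{ed} = 16$ mmHg, HR 40 bpm,
$t_{sys} = 478$ ms, $R_{fill} = 0.003$ mmHg·s/ml), with
$E = E^*(t)(1 - \kappa Q)$ during ejection.  The coronary segments' wall
and terminal parameters are modulated in proportion to the normalised
elastance, the right side with one third the amplitude of the left.

## Design choices made where the design was open

**Normalised elastance shape.**  The isovolumic elastance shape is a
double-Hill curve with rise/decay exponents 1.32/21.9, the standard
analytic parameterisation of normalised mammalian elastance.  Its free time
scale is anchored to the one printed timing parameter available: with the
divisor 0.42 in $s = t/t_{sys}$ units, the coupled equine model closes the
aortic valve (flow reversal, the model's definition of end systole) at
478 ms.  Stroke volume is insensitive to this anchor (it is
filling-limited); peak ejection velocity is not, which is why the anchor is
fixed against the timing parameter rather than any outcome.  A known
consequence of the analytic shape is that it decays to zero in diastole, so
end-diastolic volume relaxes to $P_{ed}/E_{min} = 1600$ ml with time
constant $R_{fill}/E_{min} = 0.3$ s and reaches about 1550 ml at 40 bpm.
An elastance curve retaining a residual diastolic tail of order 1 % of peak
would reduce EDV by roughly 20 %, and stroke volume with it; we do not
introduce such a tail because no printed value constrains it.

**Angle convention.**  The branching angle is read with 0° horizontal
(caudal) and angles increasing counterclockwise in the sagittal plane, so
the gravity projection is $\cos\theta = -\sin(\text{angle})$: the
descending aorta (0°) is gravity-neutral, head vessels (≈90–135°) oppose
gravity and limb vessels (≈240–335°) are assisted.  This is the unique
sign choice consistent with the head-low/limb-high pressure pattern of the
standing animal.

**Connectivity.**  The adjacency list follows the sequential trunk/side
branch reading of the segment table, with one documented exception: the
bicarotid trunk is attached at the end of brachiocephalic segment 4
(together with the right vertebral artery).  This is the only attachment
for which every junction of the tree satisfies the published bound
$|\Gamma| < 0.2$ on the reflection coefficient; the sequential alternative
produces $|\Gamma| = 0.24$–0.26 at two junctions.

**Regional labels.**  The mapping of the 62 terminals to body regions ships
as a dataset column: coronaries → heart; carotid, head and vertebral
branches → brain; fore/hind limb and neck-muscle branches → muscle; renal →
kidney; coeliac and mesenteric → splanchnic; internal thoracic,
broncho-oesophageal, ovarian, uterine and internal iliac → other.

## Numerics

Space is discretised with nodes at most 10 mm apart and at least 5 nodes
per segment (the strongly tapered 5–20 mm terminal stubs need the extra
resolution under the one-sided end stencils); interior derivatives are
central, segment ends use second-order one-sided stencils.  Time stepping
is the one-step $\theta$ scheme with $\theta = 0.55$ and
$\Delta t = 1$ ms; pure Crank–Nicolson ($\theta = 0.5$) is formally second
order but neutrally stable, and grid-scale modes grow through the nonlinear
terms on reflective fixtures, so a small damping offset is the default.
Each step is solved by Newton iteration with an analytic Jacobian
(tolerance $10^{-8}$ on the scaled update, at most 20 iterations, large
steps damped); the linear system is solved exactly in $O(\text{nodes})$
by per-segment banded condensation followed by a leaf-to-root impedance
sweep over the junction tree.

Three further stabilisers address a structural property of collocated
central schemes: the interior operators split the unknowns into two
interleaved sub-grids that communicate only at boundaries, so a
checkerboard (odd–even) mode is invisible to them.  (1) The flat-profile
momentum-flux term is differenced *upwind*, which both stabilises the
nozzle-like tapered stubs and couples the sub-grids.  (2) A
scale-selective fourth-difference artificial dissipation acts on $Q$
(second-difference at next-to-boundary nodes), damping the grid mode at
$\sim 10^2\,$s$^{-1}$ while affecting resolved wavelengths at
$\sim 10^{-3}\,$s$^{-1}$.  (3) The Womersley corrections are applied as
*frozen deviation sources*: the solver always retains the implicit
Poiseuille friction and flat-profile momentum flux at the current state and
adds the difference between the Womersley value and the same closure
evaluated at the previous cycle's state.  At periodic convergence the
combination equals the full Womersley terms exactly, but deviations from
the previous cycle remain implicitly damped.  The Womersley–flat
*convective* deviation (a second-order correction, since profiles at
$\alpha > 3$ are nearly flat) is available behind
`solver_config(conv_deviation = TRUE)` but off by default: its
cycle-to-cycle feedback destabilises the short tapered segments.

Runs start from 100 mmHg and 1 ml/s everywhere and cover 8 cardiac cycles,
with the first cycle bootstrapped on the Poiseuille/flat closure.  Grid
convergence was checked by halving $\Delta t$ and the node spacing
simultaneously: cardiac output changes by 0.03 %, mean and pulse pressure
by less than 0.1 mmHg.  Cycle-to-cycle periodicity reaches 1–2 % at cycle 8
and 0.5 % at cycle 9–10; the slowest transient is the relaxation of the
largest terminal Windkessels ($R_2 C_T$ up to 1.5 s).

## What the toy generators emulate

`toy_network()` builds single tubes, symmetric bifurcations and
three-generation trees whose analytic behaviour is known exactly (matched
junctions, Poiseuille limits, Windkessel relaxation constants, linear wave
speeds including advection by the mean flow); `make_synthetic_waveforms()`
produces waveform sets with constructed properties (pure forward waves with
$dP = Z_c\,dQ$, delayed probe pairs, noisy repeated beats under a fixed
seed).  These fixtures exercise every operation without the packaged
anatomy, but they are idealisations: uniform untapered cylinders, exactly
periodic beats, additive white noise.  Passing them demonstrates that the
numerics reproduce the governing equations and the analysis definitions —
not that the physiological parameter set reproduces any particular animal.

## Known limitations

* The printed heart constants imply an end-diastolic volume near 1550 ml,
  about 20 % above the value implied by the published stroke-volume /
  ejection-fraction pair; cardiac output, stroke volume and pulse pressure
  inherit this offset (ejection fraction, MAP and systolic pressure under
  gravity, aortic PWV and the Womersley numbers do not).
* Series (viscous) resistance of the conduit vessels at mean flow is
  Poiseuille by construction and contributes ~0.008 mmHg·s/ml on this
  geometry; the published total vascular resistance implies a several-fold
  larger series contribution whose mechanism is not stated.
* Terminal conductances are allocated to the reference regional fractions
  at uniform pressure; allocations tuned under gravity would shift the
  no-gravity regional distribution (notably raising carotid flow).
* No venous return (open loop), no baroreflex or autoregulation, purely
  elastic walls, and a minimal proportional coronary rule.
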