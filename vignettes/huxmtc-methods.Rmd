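---
title: "A Huxley-type muscle–tendon complex model with metabolic energetics: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{huxmtc methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`huxmtc` simulates a lumped muscle–tendon complex (MTC) in which the
contractile element (CE) is a two-state Huxley cross-bridge model. A CE and
a parallel elastic element (PEE) act in series with a series elastic
element (SEE); neglecting muscle mass, lengths and forces obey the
congruency relations

$$ l_{MTC} = l_{CE} + l_{SEE}, \qquad F_{SEE} = F_{CE} + F_{PEE}. $$

**Elastic elements.** Both SEE and PEE are quadratic springs,
$F = c\,(l - l_{slack})_+^2$. The SEE stiffness coefficient is defined
through the strain at maximum isometric force,
$c_{SEE} = F_{max} / (\varepsilon_{SEE}\, l_{SEE,slack})^2$ with
$\varepsilon_{SEE} = 4\%$, so the SEE carries exactly $F_{max}$ at 4%
strain. The PEE uses the same construction with slack at
$0.9\,l_{CE}^{opt}$ and an animal-specific shape parameter
$\varepsilon_{PEE}$ (the strain at which the PEE would carry $F_{max}$).
With $\varepsilon_{PEE}$ near 1, passive force at optimum CE length is of
order 1% of $F_{max}$, which matches how small passive forces are in the
fibre-bundle preparations this package emulates.

**Force–length relationship.** The normalized isometric force–length curve
is a 4th-order polynomial in relative CE length
$\tilde l = l_{CE}/l_{CE}^{opt}$ with a single shape parameter
$\tilde a = -16$:

$$ \tilde F_{isom}(\tilde l) = \Big(1 + \tfrac{\tilde a}{2}(\tilde l - 1)^2\Big)^2
   \quad \text{for } (\tilde l - 1)^2 \le -2/\tilde a, \text{ else } 0. $$

This quartic equals 1 at the optimum, is even in $(\tilde l - 1)$, touches
zero smoothly at $\tilde l = 1 \pm \sqrt{-2/\tilde a} \approx 0.65, 1.35$,
and is clamped to zero outside those roots (behaviour outside the fitted
length range is not constrained by data, so the clamp is a package
convention). The perfect-square form was chosen because it realizes a
one-parameter 4th-order polynomial with the required properties without
introducing a second width parameter.

**Activation dynamics.** Free calcium $\gamma \in [0,1]$ follows
first-order dynamics driven by the stimulation signal, with time constant
$\tau_{act}$ while rising and $\tau_{deact}$ while falling. The active
state (fraction of cross-bridges allowed to participate) is a saturating
Hill sigmoid $q(\gamma) = \gamma^n / (\gamma^n + \kappa^n)$, so
$q(\kappa) = 1/2$ and $q(1) = 1/(1+\kappa^n) < 1$. The floor $q_{min} =
10^{-6}$ is applied as a floor (not an additive offset), so resting muscle
retains a vanishing cross-bridge population. The cooperativity $n$ has no
reported value for this preparation; the default is $n = 2$ (typical for
calcium–troponin binding), it is configurable, and it is *not* fitted by
default — only $\kappa$ is estimated in stage 2.

**Cross-bridge distribution.** The state of the CE is the fraction
$n(x,t)$ of attached cross-bridges over normalized bond length $x$ (bond
length divided by the maximal attachment length $h = 10$ nm). The
distribution obeys

$$ \frac{Dn}{Dt} = f(x)\,\big(d(t) - n\big) - g(x)\,n,
   \qquad d(t) = q(\gamma)\,\tilde F_{isom}(\tilde l_{CE}), $$

along characteristics $dx/dt = -u$, where $u$ is the filament sliding
velocity in normalized bond lengths per second. The drive $d$ scales the
attachment term, so the isometric fixed point is
$n^*(x) = d\, f(x) / (f(x)+g(x))$. **Sign convention:** $u > 0$ denotes
shortening, under which the distribution advects toward smaller bond
lengths; $u = -\dot l_{CE} / (2 n_{sarc} h)$ with
$n_{sarc} = l_{CE}^{opt} / s^{opt}$ the number of in-series sarcomeres
(optimal sarcomere length $s^{opt} = 2.4\,\mu m$ for mouse).

**Rate functions.** Attachment is $f_1 x$ on $0 < x < 1$ and zero outside;
detachment is $g_2$ for $x<0$, $g_1 x$ on the unit interval and
$g_1 x + g_3$ beyond it. The extra detachment offset $g_3$ caps eccentric
force, which the original two-state formulation badly overestimates. $g_1$
is fixed at 100 Hz: it controls isometric energy turnover, and no
isometric energy-rate measurements are available to identify it. The
"Gaussian sigmoid" smoothing of the two kinks is implemented as the exact
analytic convolution of the piecewise-linear branches with a Gaussian of
$\sigma = 0.05$ (so the transition is ~95% confined to the stated
0.2-wide windows). The convolution reading was chosen over an
error-function blend of branches because it is guaranteed non-negative
and is directly testable against a numerical convolution oracle; the
kernel choice is isolated behind `attachment_rate()` / `detachment_rate()`.

**Force.** Each attached bridge pulls in proportion to its bond length, so
$F_{CE} = F_{max}\, m_1[n] / m_1[n^*_{q=1}]$, the first moment of the
distribution normalized by the first moment of the isometric steady state
at full drive. The normalization makes the isometric plateau at optimum
length equal $F_{max}$ identically, absorbing the cross-bridge stiffness
constant.

**Quasi-state CE length.** Rather than root-solving the force balance at
every step, $l_{CE}$ is integrated as a quasi-state: differentiating the
force balance in time and solving for $\dot l_{CE}$ gives a rate involving
the SEE/PEE tangent stiffnesses and the distribution moments. A small
stiffness regularization ($10^{-6} F_{max}/l_{CE}^{opt}$, configurable)
keeps the rate defined when everything is slack; an optional residual
feedback gain `beta` (default 0 — not needed in practice, residuals stay
below $10^{-5} F_{max}$ at default tolerances) can suppress secular drift
on very long integrations. Tests verify agreement with an independent
simulator that re-solves the balance by root finding at every step.

## Metabolic energetics

Metabolic power is the weighted rate of cross-bridge unbinding plus a
calcium-pumping term:

$$ P_{met} = r_{dec}\Big( c_1 S \!\!\int_{x < 0.8}\!\! g\,n\,dx
  \; + \; c_2 S \!\!\int_{x \ge 0.8}\!\! g\,n\,dx \Big) + c_3\,\gamma , $$

with the split at $x = 0.8$ separating ordinary (ATP-consuming) cycling
from detachment at long bond lengths during lengthening, which is partly
mechanical ("free") and therefore carries its own, typically smaller,
weight $c_2$. $r_{dec} \in (0,1]$ is the within-trial force-decline ratio.
The split point is configurable; its exact value does not matter much
because the two integrals separate cleanly between concentric and
eccentric contractions.

**Dimensional scaling (an explicitly open reading).** $c_1, c_2$ carry
units J kg$^{-1}$ m$^{-1}$, so the unbinding integrals (units 1/s on the
normalized grid) must be scaled by a length. The package uses
$S = h\, n_{sarc} / m_1[n^*_{q=1}]$: one unbinding event per site
corresponds to $h$ metres of filament travel, summed over in-series
sarcomeres, with the same first-moment normalization as the force
equation. This is unit-consistent and centralized in `cb_power_scale()`,
so an alternative reading changes one line. With coefficient values in the
published per-animal range, this scaling makes the cross-bridge terms much
smaller than the calcium term; since the experimental tables are not
reproducible without the (undeposited) animal data, the package treats the
relative magnitude as unresolved and keeps the calibration pipeline
agnostic: the linear least-squares stage recovers whatever $c_1, c_2, c_3$
generated the data, exactly, regardless of scale — which is what the
acceptance tests verify.

In blebbistatin mode (myosin inhibited, calcium handling intact) the two
unbinding terms are zeroed and $P_{met} = c_3 \gamma$ identically. Resting
metabolism is not modelled: the emulated experiment subtracts it, so all
powers are net.

## Numerics

- **Grid**: canonical $x \in [-2, 3]$, 201 nodes. Boundary attached
  fractions stay below $10^{-8}$ in protocol trials; exceeding $10^{-3}$
  aborts with a re-grid-overflow error.
- **Characteristics and re-gridding**: node positions are
  $x_0 + (l_{CE} - l_{ref})/(2 n_{sarc} h)$ — an affine function of the
  quasi-state, so no extra state is integrated. When the drift exceeds
  0.25 (configurable), the distribution is re-interpolated onto the
  canonical grid with a monotone (Steffen) cubic, clamped to $[0,1]$.
- **Integrator**: adaptive Dormand–Prince 5(4), relative tolerance
  $10^{-6}$, written in C++ inside the package (no suitable ODE solver is
  among the available dependencies, and the characteristics bookkeeping
  needs to live inside the stepper loop). Steps never cross stimulus-pulse
  edges, so the discontinuous input never degrades the error estimate.
  Rate functions are evaluated from a fine cubic-Hermite lookup table with
  analytic knot derivatives (error ~$10^{-8}$, verified against the closed
  forms).
- **Stimulus**: block pulses of 4 ms, amplitude 1, exact edge times.
- **Input interpolation**: MTC length trajectories are interpolated with a
  monotone (Fritsch–Carlson) cubic; the derivative comes from the spline.
- **Quadrature**: trapezoidal rule on the node grid for all moments; the
  energetic split inserts an interpolated node exactly at $x = 0.8$.
- **Units**: SI everywhere inside; CSV I/O can declare mm and converts at
  the boundary.

## Calibration pipeline

Stage order is fixed: static → dynamic → energetic; later stages never
touch earlier parameters.

1. **Static** (`fit_static`): $F_{max}$, $l_{CE}^{opt}$ (constrained to
   $[0.9, 1.1]\times$ resting fibre length), SEE slack and
   $\varepsilon_{PEE}$ are fitted jointly to active and passive
   force–length points by bounded quasi-Newton + Nelder–Mead polish on the
   sum of squared forces. Model points come from root-solving the static
   force balance at full drive (active) and zero drive (passive). Hitting
   a constraint bound raises a warning and a flag.
2. **Dynamic** (`fit_dynamic`): $f_1, g_2, g_3$ (log-scale),
   $\tau_{act}, \tau_{deact}, \kappa$ fitted simultaneously to sinusoidal
   work-loop trials and isometric force–frequency trials by minimizing the
   duration-weighted relative RMSE (percent of $F_{max}$), multi-start
   (5 seeded random starts by default) L-BFGS-B within documented bounds,
   then a Nelder–Mead polish of the best start. The cost's inter-trial
   weighting is duration-weighted pooling by default, with equal-per-trial
   weighting behind a flag; both are covered by a brute-force oracle test.
   The activation and cross-bridge dynamics are two systems in series, so
   different parameter sets can produce near-identical force traces; the
   pipeline therefore promises trace-level recovery, not parameter-level
   identity.
3. **Energetic** (`fit_energetics`): each metabolic trial is simulated
   over its first contraction only; the within-trial force decline enters
   through the measured decline ratio. $c_3$ is solved first on the
   post-blebbistatin trials (pooled least squares), the known
   $c_3\bar\gamma$ is subtracted from the pre-blebbistatin powers, and
   $(c_1, c_2)$ follow from the Moore–Penrose pseudo-inverse. A
   rank-deficient design (e.g. no eccentric trial populating the
   long-bond-length integral) is reported as unidentifiable rather than
   silently returned as zero.

`cross_validate` fills the bundle-by-bundle cost matrix by simulating
bundle $j$'s trials with bundle $i$'s parameters through exactly the same
deterministic code path as the fit objective, so the diagonal reproduces
the stored own-fit objectives bit for bit.

## The synthetic world

`sample_bundle` draws ground-truth parameters from the per-animal ranges
reported for mouse soleus fibre bundles (forces 12–24 mN, optimum CE
lengths 5.3–7.3 mm, tendon slack 2.1–2.9 mm, activation time constants
22–90 ms / 53–83 ms, $\kappa$ 0.15–0.79, $c_1$ 0.086–0.38, $c_2$
0.003–0.23, $c_3$ 48–340). For $g_2$ the sampler uses a factor-two band
around the reported median ($6\times10^3$–$2.6\times10^4$ Hz) rather than
the full published span, which is dominated by two outlier animals and
would make the explicit solver's stability step impractically small; this
is a stated-world choice made a priori. One published table column
labelled as SEE strain (0.16–1.00) conflicts with the fixed 4% SEE strain
and most plausibly holds the PEE shape parameter; the generator defaults
to a PEE-strain reading sampled in [0.6, 1.2] (keeping passive forces at
the stated ~1% level) and exposes the raw-table range behind
`pee_interpretation = "table_raw"`.

Protocols mirror the measurement protocol: isometric force–length series,
isometric force–frequency series, sinusoidal trials (0.25 mm 2 Hz,
0.50 mm 2 Hz, 0.25 mm 3 Hz and others; 4–8 pulses at 100 Hz; 2 kHz
sampling), concentric/eccentric phasing, pre/post-blebbistatin metabolic
trials with one repeated condition. The stimulus train is centred on the
peak-velocity point of the selected half-cycle; the experiments' exact
phase is not documented, so the centring fraction is an explicit config
parameter, not a reported value. Noise: additive Gaussian force noise
(1% of $F_{max}$), multiplicative Gaussian noise on trial-mean metabolic
power (CV 9%, reproducing a repeated-measures RMS-about-mean of order
1–2 W kg$^{-1}$ at typical powers), and a slow exponential within-trial
force decline whose decline ratio feeds the energetic stage. Repeated
trials get independent noise; model predictions for repeats are identical
by construction since the model inputs are identical.

What the generator does *not* emulate: oxygen-electrode dynamics and
back-extrapolation, servo/wire compliance, necrosis, fibre-type variation,
history-dependent activation (the first pulse of a real train produces a
disproportionately large force response). A green end-to-end test
therefore establishes internal consistency of model + pipeline on data
*from the model's own family*, not fidelity to any particular animal.

## Known limitations

- Titin and MyBP-C mechanics, additional weakly-bound cross-bridge states,
  velocity-dependent detachment beyond $g_3$, and mechanistic calcium-pump
  models are out of scope.
- The eccentric force–velocity limb is non-monotone at extreme lengthening
  velocities (force declines again beyond $u \approx -500$ s$^{-1}$), a
  known property of two-state models with finite attachment windows; the
  protocol range stays well inside the plateau region.
- The absolute scale of the cross-bridge power terms depends on the
  dimensional reading discussed above; relative comparisons (concentric
  vs eccentric, pre vs post blebbistatin) and coefficient recovery are
  scale-independent.
- Explicit time stepping makes the cost scale with $g_2$; bundles at the
  extreme of the published $g_2$ span integrate ~5x slower than the
  median.
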