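---
title: "Methods: shift-add emulation of the FitzHugh-Nagumo neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shift-add emulation of the FitzHugh-Nagumo neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordicfhn)
```

## The model and why it is approximated

The FitzHugh-Nagumo (FHN) neuron is the two-variable reduction of
Hodgkin-Huxley dynamics,

$$\frac{dV}{dt} = V - \frac{V^3}{3} - W + I(t), \qquad
  \frac{dW}{dt} = \frac{a - bW + V}{T},$$

with membrane potential $V$, recovery variable $W$, and constants $a$
(recovery offset), $b$ (recovery gain) and $T$ (recovery time constant).
The only nonlinearity is the cubic $V^3$, and it is exactly this term that
makes multiplierless digital implementations attractive: if $V^3$ can be
produced from shifts and additions alone, the whole neuron update consists
of adders and shifters, which are cheap, fast and low-power in
programmable logic. This package studies a CORDIC (COordinate Rotation
DIgital Computer) replacement for the cubic and quantifies, in software,
every behavioural consequence of that substitution: waveform error,
equilibrium structure, bifurcations and chaos under periodic drive, and
population-level spike timing.

### Parameter defaults

| parameter | default | meaning | why this value |
|---|---|---|---|
| `a` | 0.7 | recovery offset | classical excitable regime; reproduces the benchmark equilibria below |
| `b` | 0.8 | recovery gain | pinned by the Jacobian entry $D=-b/T=-0.064$ of the benchmark stability table |
| `T` | 12.5 | recovery time constant (ms) | classical value; spiking period about 36 time units at $I=0.5$ |
| `dt` | $2^{-5}$ | Euler step | a power of two, so the step multiply is a 5-bit right shift in fixed point |

Published descriptions of this hardware family circulate with `a` and `b`
swapped (0.8 and 0.7). The swapped assignment is inconsistent with the
benchmark stability table this package reproduces: with $b = 0.7$ the
Jacobian entry $D = -b/T$ would be $-0.056$, not the tabulated $-0.064$,
and the tabulated fixed points $(-0.8048, -0.1311)$, $(0.4089, 1.3861)$,
$(1.3341, 2.5426)$ at $I \in \{0.5, 1, 2\}$ are only reproduced (to all
four printed decimals, by root finding) with $a=0.7$, $b=0.8$. Both
assignments remain available through `fhn_params()`.

## The CORDIC multiplier and cube

`cordic_multiply(x, y)` recodes the multiplier $y$ into signed powers of
two over an iteration window $i = i_{\min} \dots i_{\max}$ (default $-7
\dots +8$, sixteen steps): at step $i$ the residual moves by $\mu_i
2^{-i}$ and the product accumulates $\mu_i\, x\, 2^{-i}$, so only shifts,
adds and sign tests are used. Two invariants pin the algorithm down:

* **conservation** -- $z_i + x\,y_i$ is constant along the iteration
  (checkable with `cordic_trace()`), and
* **residual bound** -- after the last step the unrecoded remainder
  satisfies $|r| \le 2^{-i_{\max}}$, so the product is $x(y - r)$.

The direction rule is $\mu_i = \mathrm{sign}(y_i)$ with $\mu_i = 0$ once
the residual is exactly zero. The zero case matters: it makes exactly
recodable multipliers exact (`cordic_multiply(1.7, 0)` is 0,
`cordic_multiply(-1.5, 1.25)` is exactly $-1.875$), which a strict
$\pm 1$ comparator rule would perturb by up to one final shift. Any rule
that preserves the two invariants gives the same error envelope; the
package's rule is frozen by its tests.

`cordic_cube(v)` runs two multiplier stages, $(V \times V) \times V$,
32 iterations in total at the default window. On the $[-2, 2]$ membrane
range the worst-case error is bounded by
$|V|2^{-i_{\max}}(1+|V|) + V^2 2^{-i_{\max}}$ (about 0.032 at $V = 2$).

One consequence worth stating explicitly: on an evaluation grid whose step
equals $2^{-i_{\max}}$ (the default sweep grid is one Q8.8 ulp), every
grid value is recoded *exactly* by the zero-skipping rule, so the
real-backend mean absolute error of the cube is 0 at 16 and 18 iterations
per stage and the measured error curve decays by a factor of ~4 per two
added iterations where it is nonzero. Published hardware error tables for
this construction decay by a factor of ~2 per two iterations and bottom
out near $8 \cdot 2^{-i_{\max}}$; those figures evidently include
datapath quantization beyond the recoding residual itself. The package
therefore treats published MAE figures as upper bounds, and its sweeps
(`cube_error_sweep()`) report both backends so the gap is visible rather
than hidden.

## Fixed-point arithmetic (Q8.8)

The bit-accurate backend models a 16-bit word: 8 integer bits including
sign, 8 fraction bits, range $[-128, 128 - 2^{-8}]$, ulp $2^{-8}$.
Quantization truncates toward $-\infty$ (the behaviour of an arithmetic
right shift) and additions saturate rather than wrap. Three design points
came out of implementing, not speculation, and are deliberate:

1. **Widened CORDIC internals.** The multiplier's intermediate
   accumulators transit through values as large as $|x| \cdot 2^{8}$
   during the coarse iterations before cancelling back down. Clamping
   every intermediate to the 16-bit range destroys the product entirely
   (errors of order 40 were measured). The datapath therefore carries
   overflow guard headroom internally and saturates only the final
   result -- the software analogue of the extra guard bits a hardware
   adder tree holds.

2. **Guard fraction bits in the integrator.** The recovery increment per
   Euler step is $\frac{dt}{T}(a - bW + V) \approx 0.6$ ulp of Q8.8.
   An accumulator held at output precision truncates this to zero on
   every step: $W$ freezes, and the neuron fires once and dies (this was
   measured, not inferred). `simulate_discrete(backend = "fixed")`
   therefore keeps `guard_bits = 8` extra fraction bits in the state
   registers -- standard practice in fixed-point integrators -- while the
   CORDIC unit and the exported trajectory see the Q8.8 view.

3. **Shift-add constants.** Multiplications by $1/3$, $b$ and $1/T$ are
   greedy signed-power-of-two decompositions with error below one ulp
   (`shift_decompose()`); the chosen shift sets are recorded in each
   trajectory's `shift_sets` attribute. The decompositions detune the
   effective constants by up to $2^{-8}$ ($0.08 \to 0.078125$,
   $0.8 \to 0.796875$), which shifts the spiking period by about 1%.
   Over a 1000-unit run the fixed-point spike train therefore slides out
   of phase with the real-valued one: spike counts, waveform shape and
   state-space ranges agree, but the pointwise MAE between the two
   backends saturates near the size of a spike. The regression tests
   freeze spike counts and the measured MAE rather than pretending the
   phase drift away.

## Solvers

Continuous solutions use the Dormand-Prince 4(5) pair (`deSolve::ode`,
method `ode45`) from zero initial conditions, tolerances
`rtol = 1e-8` / `atol = 1e-10` for the smooth model. The CORDIC model's
right-hand side is a staircase whose treads are $2^{-8}/3$ tall; error
control below that granularity merely forces the step-size controller to
resolve every recoding discontinuity (a measured ~20x slowdown with no
trajectory improvement), so the CORDIC model defaults to `rtol = 1e-6` /
`atol = 1e-8`. Discrete simulation is plain forward Euler (first-order
convergence is property-tested) in either backend.

The spike detector -- upward crossing of $V = 1$ with a 5 ms refractory
hold -- is a package convention, configurable everywhere it is used; the
differential equations themselves define no discrete spike event.

## Chaos tooling

Under sinusoidal drive $I(t) = I_{in} \sin(2\pi f t)$ the model shows
periodic, period-doubled and chaotic responses. Two instruments quantify
them:

* `bifurcation_diagram()` records all strict local maxima of $V$ after a
  500-unit transient, refining each peak with a three-point parabolic fit
  so that branch splitting is not masked by the sampling grid;
  `count_peak_clusters()` then counts branches at a $10^{-3}$ tolerance.
* `max_lyapunov()` is a Wolf-style two-trajectory estimator: reference
  and perturbed runs are co-integrated and the log separation growth is
  accumulated at each renormalization (default every 1 time unit). The
  two-trajectory form needs no Jacobian, which matters because the
  staircase nonlinearity has none. It is validated against the logistic
  map, whose exponent at growth parameter 4 is exactly $\ln 2$.

The initial separation default is model-dependent, and this is the one
estimator setting that genuinely matters: probing the CORDIC model with a
separation below the staircase tread width measures the jump between
treads rather than the divergence of the flow, and reports spuriously
positive exponents in every regime (measured: $+0.14$ at a frequency
where the smooth model is firmly negative). At or above one tread
($2^{-i_{\max}}$, the CORDIC default) the two models' exponent curves
agree closely; the smooth model keeps the conventional $10^{-8}$.

**A finding the tests document honestly:** with these tools, the
amplitude sweep at drive frequency $f = 0.01$ locks 1:1 to the drive and
shows only one- and two-branch windows -- verified both with the package's
Euler engine at refined steps and independently with the adaptive solver,
on a 200-point amplitude grid. The period-doubling route ($2 \to 4 \to$
chaos) lives at $f = 0.13$ (four-branch windows around
$I_{in} \in [0.6, 0.9]$, chaotic bands near 0.5 and 1.0) and at
$f = 0.16$. Accounts of this system that place 2- and 4-period cycles at
$f = 0.01$ do not reproduce under these conditions, and the acceptance
suite leaves that single expectation failing rather than relabeling the
frequencies.

## The network experiment

`build_network()` draws, from one seed, a population (default 1000
neurons) in which every neuron receives exactly 100 presynaptic inputs
(uniform, no self-connections) and 80% of neurons are excitatory. The
"each neuron connects to 100 others" reading is taken as the operational
definition; a Bernoulli variant (`connectivity = "bernoulli"`) is
available. The synapse is the minimal coupling consistent with
excitatory/inhibitory roles: a current-based rectangular pulse, defaults
$w_{exc} = +0.05$, $w_{inh} = -0.25$ mA for 1 ms, injected into all
targets of a spiking cell. These synaptic constants are package choices
-- no published value exists for them -- exposed in `network_config()` and
embedded in every output. With zero weights each neuron reproduces the
single-neuron simulator bit for bit, which is the decoupling test that
anchors the implementation.

Both models run on identical wiring (same seed) for 1200 ms under
constant 0.5 mA drive; the last 1000 ms are analysed.
`raster_discrepancy()` matches spikes per neuron greedily within a 20 ms
window and reports the mean absolute timing difference and the matched
fraction. At 16 CORDIC iterations the seeded default run lands near 8 ms
mean discrepancy with ~93% of spikes matched; the discrepancy grows as
the cube is coarsened from 16 to 12 iterations and saturates by 10, where
the trains have decohered enough that the matching window itself limits
what is measurable.

## Problem sizes used by the test-suite

The shipped tests integrate single neurons for 50-1000 time units,
bifurcation and exponent sweeps over up to 50 parameter points with a
4500-5000-unit horizon, exhaustive fixed-point lattices at one-ulp
resolution, and one full 1000-neuron network pair; these sizes were
chosen so the full suite characterizes every claim while remaining a
routine desk run. Each statistic scales with its controlling argument
(`horizon`, `sweep_values`, `n_neurons`) for larger studies.

## What the synthetic conditions do and do not show

Everything here is exercised on the model's own synthetic regimes --
constant and sinusoidal drive, seeded random wiring. That is the right
arena for the question the package answers (does the shift-add neuron
behave like the exact one?), but passing tests say nothing about fit to
biological recordings: the FHN model is dimensionless, the "ms" and "mA"
labels are conventions, the spike threshold is a convention, and the
synaptic pulse model is the simplest one consistent with the population
experiment's description. Cross-model exponent-curve statistics
(`nrmse_mle()`) additionally depend on every estimator setting
(separation, renormalization interval, horizon, sweep grid), so the
package reports them for comparison rather than asserting published
figures.

## Known limitations

* Only linear-mode CORDIC is implemented -- no circular/hyperbolic modes,
  no division; formats are limited to 64 total bits.
* The continuous CORDIC-model solution treats the staircase with a
  general-purpose adaptive solver rather than event detection at tread
  boundaries; tolerances below the tread size are wasted effort.
* The fixed-point backend models arithmetic, not timing: pipeline depth,
  latency and clocking of a hardware realization are out of scope.
* Jacobians of the CORDIC model are central finite differences (default
  step $2^{-6}$) of a staircase; the reported entries are slope averages
  over two treads, not derivatives.
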