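---
title: "Balanced E-I QIF networks and their exact neural mass model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced E-I QIF networks and their exact neural mass model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qifbalance)
```

## The model

`qifbalance` simulates two sparsely coupled populations of quadratic
integrate-and-fire (QIF) neurons — $N^{(e)}$ excitatory and $N^{(i)}$
inhibitory — in the balanced regime, together with the exact low-dimensional
neural mass model that describes their collective dynamics.

Each membrane potential obeys
$\tau_m \dot v = v^2 + \sqrt{K} I_0 + \text{synaptic pulses}$,
with a spike emitted when $v$ diverges to $+\infty$ and the neuron re-entering
at $-\infty$. Synapses are instantaneous $\delta$-pulses. Couplings and DC
currents are rescaled with the median in-degree $K$ in the standard balanced
fashion: $g = g_0/\sqrt{K}$, $I = \sqrt{K} I_0$. Within-population in-degrees
are drawn from a Lorentzian distribution with median $K$ and half-width
$\Delta_0\sqrt{K}$ (structural heterogeneity); cross-population in-degrees
are exactly $K$.

The Lorentzian choice is what makes the reduction exact: quenched in-degree
disorder is equivalent to Lorentzian-distributed synaptic couplings, and for
Lorentzian heterogeneity the infinite-network dynamics closes on two
variables per population, the mean membrane potential $V^{(\alpha)}$ and the
instantaneous population rate $R^{(\alpha)}$:

$$
\tau_m \dot R^{(\alpha)} = R^{(\alpha)}
  \left[ 2 V^{(\alpha)} + \frac{g_0^{(\alpha\alpha)}\Delta_0^{(\alpha\alpha)}}{\pi} \right],
\qquad
\tau_m \dot V^{(\alpha)} = \left[V^{(\alpha)}\right]^2
  - \left[\pi R^{(\alpha)} \tau_m\right]^2
  + \sqrt{K}\left[ I_0^{(\alpha)}
  + \left(g_0^{(\alpha e)} R^{(e)} - g_0^{(\alpha i)} R^{(i)}\right)\tau_m \right].
$$

All internal computation uses milliseconds and rates in 1/ms; the interfaces
report rates in Hz.

## Stationary balanced solutions

At a fixed point the mean potentials are pinned by the heterogeneity,
$\bar V^{(\alpha)} = -g_0^{(\alpha\alpha)}\Delta_0^{(\alpha\alpha)}/(2\pi)$,
and the rates solve a quadratic 2x2 system in which
$\varepsilon = 1/\sqrt{K}$ multiplies the quadratic terms.
`stationary_state()` solves it by damped Newton iteration (tolerance
$10^{-12}$ on the residual max-norm, initialised at the zeroth-order
solution, negative-rate roots rejected). `rate_expansion()` instead expands
the rates in powers of $\varepsilon$; every order solves the same linear
system, with inhomogeneities built recursively from lower-order rates. The
series is asymptotic — coefficients grow quickly — so low orders at large $K$
are where it is useful; the tests verify the strict order-by-order
improvement at $K \ge 10^4$ and the $\varepsilon$-contraction at $K = 10^6$.

The zeroth order is the classic balanced-state solution and exists when the
ratio $I_0^{(e)}/I_0^{(i)}$ sits on the correct side of the two coupling
ratios (`is_balance_feasible()`). The asymptotic effective currents
`asymptotic_effective_currents()` follow from the first-order coefficients
and equivalently from the identity
$I_a^{(\alpha)} = (\pi \bar R_0^{(\alpha)} \tau_m)^2 - (\bar V^{(\alpha)})^2$,
which the tests enforce to $10^{-12}$. Input-current fluctuations are
estimated in a Poissonian approximation,
$\Delta I^{(\alpha)} = \sqrt{\tau_m [(g_0^{(\alpha e)})^2 R^{(e)} +
(g_0^{(\alpha i)})^2 R^{(i)}]}$; the square root makes the quantity an RMS
amplitude of order one, the scale on which its reference values are quoted.

## Stability, Lyapunov spectra, and units of the exponents

`jacobian_eigenvalues()` linearises the neural mass model analytically at a
fixed point. Eigenvalues come in conjugate pairs; the fixed point is
classified by the leading pair (node/focus, stable/unstable), and the
imaginary parts give the relaxation frequencies
$\nu_k = \mathrm{Im}\,\Lambda^{(k)}/(2\pi)$, which predict the frequencies of
fluctuation-driven collective oscillations in the network. In the large-$K$
limit the linearisation reduces to a zero-trace system
(`largeK_eigenvalues()`) whose eigenvalues scale as $K^{1/4}$ and, with both
DC currents proportional, as $\sqrt{I_0^{(e)}}$; the package computes the
reduced spectrum numerically from the 4x4 matrix rather than from a closed
form, and uses the scaling only as a testable property (slopes
$0.25 \pm 0.02$ and $0.50 \pm 0.02$).

`lyapunov_spectrum()` implements the Benettin method: the reference orbit
and four tangent vectors are advanced with a common RK4 step (the tangent
stages use the Jacobian at the state stages), and the frame is
re-orthonormalised by modified Gram-Schmidt every 10 steps by default, with
the exponents read off the accumulated log-stretchings. Defaults follow the
reference conditions: $dt = 0.01$ ms, 200 s of averaging after a 10 s
transient. Zero exponents converge as $1/T$, so at 200 s they are resolved
to a few $10^{-4}$ on the per-$\tau_m$ scale.

A note on units: the package reports exponents and eigenvalue real parts in
1/ms. The reference figures for these quantities are printed on a per-$\tau_m$
scale (values 20 times larger); we verified this correspondence numerically —
the full four-exponent spectra at a focus, on a limit cycle, and in the
chaotic regime all match the printed values under that conversion while the
relaxation frequencies only make sense in straight 1/ms — and the acceptance
outputs convert accordingly.

## Bifurcation analysis at desk scale

There is no continuation engine in the package; bifurcation structure is
recovered by two scan primitives.

`find_hopf()` bisects a control parameter on the sign of the maximal
eigenvalue real part, re-solving the fixed point at every step (60 iterations
maximum, relative tolerance $10^{-6}$), and confirms a Hopf point by a
nonzero imaginary part at the crossing. The crossing on the canonical cuts is
extremely shallow (the maximal real part changes by only $\sim 10^{-6}$/ms
across a 0.1% displacement of the control), so agreement with reference
values obtained by a different continuation code is expected at the 0.1%
level, not to all printed digits.

`peak_map()` integrates the model over a grid of control values and collects
the local maxima of $R^{(e)}(t)$ after a transient (parabolic refinement on
the integration grid). Maxima are grouped at a 0.5% relative gap; at least
200 post-transient maxima are required before bands are counted. Period-1, 2
and 4 windows appear as 1, 2 and 4 clusters; chaos appears as many clusters
that remain confined to at least four disjoint bands (the four-burst
structure of the oscillation survives the cascade, so the bands never merge).

`classify_regime()` combines both: a stable fixed point is labelled node or
focus from its spectrum; an unstable one is integrated, with a zero (positive)
maximal Lyapunov exponent at tolerance $10^{-3}$/ms marking a stable limit
cycle (chaos), and trajectory escape marking the regime with no bounded
collective solution. The unstable limit cycle that coexists with the stable
focus near the subcritical Hopf is *not* searched for — detecting it would
require continuation or a two-initial-condition hysteresis scan, which is
available to users by passing their own initial conditions but is not part of
the classifier.

Escapes are detected by an overflow guard ($|V|$ or $\tau_m R$ exceeding
$10^6$); the quadratic potential dynamics genuinely reach infinity in finite
time in that regime, so the guard value is uncritical. Negative rates arising
from round-off at the invariant manifold $R = 0$ are clipped and counted; more
than 0.1% of steps clipped is treated as a step-size failure.

## The spiking network simulator

`simulate_network()` integrates the network with an Euler scheme (default
desk-scale step $10^{-3}$ ms) and a finite threshold: a neuron spikes when
$v \ge v_{peak}$ (default 100), is reset to $-v_{peak}$, and is held for
$2\tau_m/v_{peak}$ — the time the exact QIF dynamics would spend traversing
beyond the threshold to infinity and back. Held neurons receive no input and
are excluded from the reported mean potential. Pulses emitted in one step are
delivered at the start of the next; with $\delta$-pulses under Euler there is
no canonical within-step placement, and next-step delivery is deterministic
and order-independent.

The per-spike jump is $g_0/\sqrt{K}$ by default, the amplitude consistent
with the neural mass drive term, so that network-versus-mean-field
comparisons are meaningful; a `pulse_factor = 2` switch reproduces the
literal pulse amplitude of the network equations, which carry an extra
factor 2 relative to the mean-field drive. Which convention produced the
reference network figures cannot be determined from the text; the default
prioritises internal consistency.

Initial potentials are uniform in $[-v_{peak}/10, v_{peak}/10]$ from an
explicit seed; identical seeds give bit-identical rasters.

## What the desk-scale conditions do and do not show

The reference network results use up to $8\times 10^4$ neurons,
$K = 16{,}384$ and 100 s of simulated time. The package supports those sizes
through its configuration files, but its tests run scaled-down conditions
chosen once: $N^{(e)} = 2{,}500$, $N^{(i)} = 625$, $K \le 256$, $T = 20$ s,
Euler step $10^{-3}$ ms. At those sizes the asynchronous-regime mean rates
match the exact mean-field fixed point to within 15% at $K = 256$ (the
excitatory rate sits above the mean-field value at small $K$ — the same
deviation the full-scale study reports for $K < 100$ — and the deviation
shrinks as $K$ grows), silent neurons concentrate in the predicted in-degree
tails, and the uncoupled-neuron firing rate matches the QIF closed form
$\sqrt{c}/(\pi\tau_m)$ to 1%. What the scaled runs cannot show are the
quantitative full-scale results: the log-normal fit means of the
$K = 16{,}384$ rate distributions, the network curves at
$N^{(e)} = 80{,}000$, or coherence values at large $K$; those remain
config-reachable but outside the test envelope.

One reference result resisted reproduction under every reading we could
construct: the drop of the excitatory-to-inhibitory burst delay from
$\simeq 28$ ms to $\simeq 5$ ms when the inhibitory membrane time constant is
increased by $\simeq 5$ ms. At the stated parameter point our model provably
reaches the same attractor (all four Lyapunov exponents match the printed
spectrum), yet the peak-to-peak delay on that attractor is 14.5 ms, and under
three different per-population generalisations of $\tau_m$ the limit cycle
survives only on a $\sim 1$ ms interval of $\tau_m^{(i)}$ before the
trajectory escapes. The delay estimator itself (`burst_delay()`,
`ping_delay_mf()`) is verified on constructed traces — zero for identical
traces, exact recovery of imposed shifts, antisymmetry — and the qualitative
PING signature (the excitatory peak leads the inhibitory one) holds at the
baseline; the corresponding quantitative acceptance check is left failing
rather than redefined to pass.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `g0_ee, g0_ei, g0_ie, g0_ii` | rescaled couplings | 0.27, 0.96286, 0.3, 0.953939 | canonical set; first index = postsynaptic |
| `I0_e`, `I0_i` | rescaled DC currents | —, `I0_e/1.02` | the 1.02 ratio keeps the balance inequalities satisfied |
| `K` | median in-degree | 1000 | real in the mean field, integer in networks |
| `delta0_ee, delta0_ii` | heterogeneity widths | 2.5, 1.0 | set $\bar V$; widths scale as $\Delta_0\sqrt{K}$ |
| `tau_m_e, tau_m_i` | membrane constants (ms) | 20, 20 | distinct values supported throughout the mean field |
| `dt` (mean field / network) | step (ms) | 0.01 / 0.001 | RK4 / Euler |
| `v_peak` | spike threshold | 100 | reset $-v_{peak}$, hold $2\tau_m/v_{peak}$ |
| `pulse_factor` | per-spike jump convention | 1 | 2 = literal network-equation amplitude |

## Known limitations

* No continuation: the saddle-node-of-limit-cycles line and two-parameter
  bifurcation curves are approximated by grid scans only.
* The rate expansion requires equal membrane time constants (its recursion is
  defined for a single $\tau_m$); the exact Newton solve does not.
* The network simulator ignores pulses arriving during the refractory hold;
  at the default hold of 0.4 ms and desk-scale rates this loses a negligible
  fraction of synaptic input, but it is a convention, not physics.
* `classify_regime()` cannot see coexisting attractors (region II/IV
  hysteresis) unless the user supplies initial conditions on both branches.
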