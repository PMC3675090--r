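---
title: "A mechanochemical model of cell reorientation under cyclic stretch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical model of cell reorientation under cyclic stretch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellreorient)
```

## The biological problem

Spindle-shaped cells (fibroblasts, endothelial cells, muscle cells) adhere to
their substrate through focal adhesions (FAs) — clusters of ligand-receptor
bonds reinforced by plaque proteins — and pull on them through stress fibers
(SFs), contractile actin-myosin bundles aligned with the cell's long axis.
When the substrate is stretched cyclically at around 1 Hz, many cell types
reorient away from the stretch axis, provided the amplitude exceeds a few
percent; under static or very slow stretch they instead align with the
stretch or stay random. `cellreorient` implements a coupled mechanochemical
model of this phenomenon: FA bond kinetics and SF kinetics are coupled
through a force-dependent bond energy, the SF force is set by a viscoelastic
filament model, the substrate may strain-stiffen, and whole-cell
reorientation proceeds by a detach/rotate/re-attach search loop. The working
hypothesis is that cells settle where the long-time stress-fiber density —
and hence adhesion strength — is largest, and that orientations where
adhesion collapses are simply uninhabitable.

## Model

All quantities are normalized: time by the bond association rate
$k_{on}$, densities by their maxima, energies by $k_BT$, forces by the
myosin stall force $F_0$.

**Geometry.** A cell at angle $\theta$ to the stretch axis feels the
effective strain amplitude
$\epsilon_a = \epsilon_A(\cos^2\theta - \nu\sin^2\theta)$,
where $\nu$ is the substrate Poisson ratio. For $\nu = 1/2$ there is a
zero-strain direction at $\theta^* = \arctan\sqrt2 \approx 54.7^\circ$.

**Kinetics.** Bond density $\xi$ and filament density $\zeta$ obey
first-order kinetics with Bell-type dissociation,

$$\dot\xi = (1-\xi) - \xi e^{-\hat G}, \qquad
  \dot\zeta = c\,\xi - d\,\zeta,$$

so filament growth is proportional to the available bonds and, at steady
state, $\zeta/\xi \to u_{ss} = c/d$. The bond energy reduction

$$\hat G = g_0 + a\,u - \frac{\beta}{s}\,(u\hat F)^2, \qquad u = \zeta/\xi,$$

has a negative baseline $g_0$ (no stable adhesion without SFs), a
reinforcement gain $a\,u$ from plaque proteins recruited in proportion to
the per-bond filament density, and an elastic penalty for the energy stored
in the bond-substrate spring under the average per-bond load
$F_b = u\hat F$. The compliance parameter $\beta$ grows as the substrate
softens; the stiffening factor $s = \max\{1, (|\epsilon|/\epsilon_c)^{3/2}\}$
raises the modulus above the critical strain $\epsilon_c$.

**Filament force.** Each filament is a constant contractile force in
parallel with a Maxwell element (spring $\hat k$ in series with a dashpot,
relaxation rate $\gamma$): $\hat F = 1 + \hat F_v$ with
$\dot{\hat F}_v + \gamma \hat F_v = \hat k\,\dot\epsilon_f$. Static stretch
therefore always yields $\hat F = 1$: given time, the fiber remodels away
any held strain. Under periodic strain of angular frequency $\Omega$ the
steady oscillation amplitude of $\hat F_v$ is
$\hat k\epsilon_a\Omega/\sqrt{\gamma^2+\Omega^2}$ for a signed sinusoid
(half that for the raised-cosine waveform below); `filament_force()` exposes
both the initial-value numerical solution and this closed form, which the
test suite uses as an oracle.

**Statics.** On an unstretched substrate the model closes:
$\hat G_{ss} = g_0 + a u_{ss} - \beta u_{ss}^2$,
$\xi_{ss} = (1 + e^{-\hat G_{ss}})^{-1}$, $\zeta_{ss} = u_{ss}\xi_{ss}$.
The bond density decays roughly exponentially with compliance, and beyond a
threshold compliance the fixed point loses linear stability and any
fluctuation sends both densities to zero — the model's version of the
observation that stable adhesions cannot form on very soft substrates.
`classify_fixed_point()` reports both the numeric (Jacobian eigenvalue)
label and the analytic reinforcement-feedback threshold
$\beta^* = ad/(2c)$, the compliance where $d\hat G/du$ changes sign at
steady state. These two do not coincide: because
$\det J = d\,(1+e^{-\hat G_{ss}}) > 0$ identically, stability is lost where
$\mathrm{tr}\,J = 0$, which for the default constants happens near
$\beta \approx 1.02$, somewhat above $\beta^* = 0.875$. The feedback
threshold is the physically interpretable lower bound (beyond it, a dip in
bond density raises the per-bond load and lowers the bond energy); the
eigenvalue crossing is where the destabilizing feedback actually overcomes
the kinetic restoring terms. `stability_transition_beta()` locates the
crossing by bisection.

## The stretch waveform

Stretch devices impose a nonnegative strain: the substrate is stretched
from rest to the amplitude and released, never compressed. The package
default is therefore the raised cosine
$\epsilon(\tau) = \epsilon_A\,(1-\cos\Omega\tau)/2$, with the signed
sinusoid $\epsilon_A\sin\Omega\tau$ available as an option. The choice
matters: with the signed sinusoid the force peak leads the strain peak by
$\arctan(\gamma/\Omega)$ and lands in the unstiffened part of the cycle, so
at 10%/1 Hz even the Rho-inhibited parallel state (which the model should
hold stable at $\bar\zeta \approx 0.135$) is torn down each cycle. With the
raised cosine, peak force coincides with peak stiffening, and the package
reproduces the full phenomenology: parallel Rho-inhibited cells stable and
denser than perpendicular ones on a stiffening substrate, the two modes
switching with substrate linearity, and normal cells collapsing parallel to
the stretch while persisting near perpendicular.

## Collapse detection

Trajectories start from a nascent focal complex: $\xi_0 = 0.3$ bonds and no
filaments ($\zeta_0 = 0$). Because $\hat G = g_0$ while $\zeta$ is still
small, every healthy trajectory transiently passes through very low bond
densities before the filament pool builds up; collapse detection is
therefore armed only after $\tau = 20$ (two SF relaxation times), by which
time viable states have recovered well above the threshold. A cell is
declared detached when $\xi$ stays below 0.02 for a full forcing period
(instantaneously on a static substrate) — stable oscillating states near
the band edge may dip below the threshold within a cycle and recover — or
when $\xi$ reaches 0.002, an absorbing runaway. Past collapse both
densities are held at zero. The thresholds separate cleanly: collapsed
states sit below $10^{-2}$, while the weakest retained stable state
(Rho-inhibited, $\approx 0.11$) is five-fold above the threshold;
classifications are unchanged for thresholds 0.01-0.04.

## Numerics

Integration uses `deSolve::lsoda` (with `lsodar` root-stopping at the
absorbing floor) at `rtol = 1e-6`, with the step capped at
$\min(0.5, T/50)$ for forcing period $T$ so that each stretch cycle is
resolved; results are insensitive to tightening to `rtol = 1e-9` and $T/200$.
The Bell factor $e^{-\hat G}$ is capped at $e^{20}$ inside the solver; the
cap only engages during terminal runaway, after the per-bond load ratio
diverges. Long-time averages discard $\max(200, T)$ and then average over
an integer number of cycles; quasi-static protocols (periods beyond the
default horizon) are averaged over one full cycle after a one-period
warm-up, since the state then tracks its instantaneous quasi-equilibrium.

## Population Monte Carlo

Cells that cannot stabilize adhesion detach, rotate by diffusion
($\Delta\theta = \sqrt{2D_r t_0}\,N$, $N$ standard normal, over the
focal-complex nucleation time $t_0$), and try again; a cell that survives a
full trial window (500 $\tau$) is settled and frozen. Orientations live on
the nematic half-circle $(-\pi/2, \pi/2]$ and alignment is tracked by
$S = \langle\cos 2\theta\rangle$ ($+1$ parallel, $-1$ perpendicular, $0$
random).

Because the attached-phase dynamics at fixed orientation are deterministic,
each trial's outcome (survive, or collapse at a known time) depends only on
the folded angle. `simulate_population()` therefore consults a precomputed
`angle_response_table()` on a 1-degree grid rather than re-integrating the
ODE for every trial; this is exact up to the grid resolution and makes
multi-seed ensembles of $10^4$-trial runs take seconds. The default
horizon is $6\times10^4$ $\tau$ with 100 cells, chosen so that well over
90% of cells settle while ensembles of ten replicates remain cheap; the
rotational diffusivity default $D_r = 5\times10^{-3}$ rad$^2/\tau$ places
whole-population reorientation at $10^4$-$10^5$ $\tau$, far slower than
FA/SF remodeling, as the separation of scales requires. Decay kinetics are
quantified by fitting $S(\tau) = S_\infty + (S_0-S_\infty)e^{-\tau/\tau_c}$
(`fit_characteristic_time()`, Levenberg-Marquardt; the fit is refused when
the trace shows no decay).

## Physical-time mapping

One normalized time unit is $1/k_{on} = 0.16$ s ($k_{on} = 6.25\,$s$^{-1}$),
fixed so that the SF turnover time $1/d = 10\,\tau$ is about 1.6 s. A 1 Hz
stretch then has $\Omega = 2\pi/6.25 \approx 1.005$. The Poisson-ratio
analyses are run at this $\Omega$: experimentally, zero-strain alignment is
seen at tens of mHz in cells with correspondingly slower adhesion kinetics,
which maps onto the same *normalized* frequency regime — the one where the
oscillating fiber force, not substrate stiffening, dominates orientation
selection. At genuinely quasi-static normalized frequency the model instead
predicts parallel alignment on stiffening substrates (the stiffening relief
of the elastic penalty is maximal for parallel cells) and no preference on
linear ones.

## What the simulations do and do not emulate

The parameter defaults describe a generic adherent spindle cell on an
elastomeric substrate: comparable bond and filament densities, bond energies
of a few $k_BT$, SF turnover of seconds, compliance in the experimentally
bracketed range. Rho inhibition is modeled solely as a halved SF association
rate ($c: 0.2 \to 0.1$). The model has one SF axis per cell, no spatial
structure within an adhesion, no cell-cell interactions, no rotation while
attached, and deterministic rate equations rather than stochastic bond
dynamics; passing tests therefore validate the reorientation mechanism —
force-accelerated disassembly competing with stiffening-stabilized adhesion
— not any particular cell line's kinetics. Settled cells never re-enter the
search loop (deterministic stable dynamics cannot destabilize
spontaneously), so late-time $S$ reflects the stable-band occupancy set by
where diffusing cells first land.

## A worked example

```{r example, eval = FALSE}
library(cellreorient)
p <- model_params()
steady_state_densities(p)            # xi_ss ~ 0.401, zeta_ss ~ 0.803
classify_fixed_point(model_params(beta = 1.1))$label   # "unstable"

pr <- stretch_protocol(0.10, 1)      # 10% stretch at 1 Hz
long_time_average_density(pi / 2, pr, model_params(c = 0.1))  # ~0.109
long_time_average_density(0,      pr, model_params(c = 0.1))  # ~0.136

tab <- angle_response_table(pr, p)
set.seed(1)
pop <- simulate_population(100, pr, p, table = tab)
steady_state_order(pop)              # ~ -0.6 to -0.7
```

## Known limitations

* The stable-orientation band at 10%/1 Hz spans roughly 64-90 degrees; its
  edge is set by a parametric (Floquet-type) load-concentration instability
  — when bonds thin momentarily, the per-bond load spikes quadratically in
  $u$ — and is quite sharp. Quantities that integrate over the band edge
  (the steady-state order parameter, the frequency dependence of the decay
  time) are correspondingly sensitive to it.
* The decay-time constant scales inversely with $D_r$, which is not
  independently measured; only $D_r$-insensitive ratios and plateau values
  should be compared across conditions.
* The exponential decay fit treats the ensemble mean as a single relaxation;
  traces that have barely started to decay, or populations that settle in
  two waves, fit poorly and the residual should be checked.
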