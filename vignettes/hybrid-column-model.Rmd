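---
title: "Differentiable solver-in-the-loop hybrid modeling of gradient-elution chromatography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable solver-in-the-loop hybrid modeling of gradient-elution chromatography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Preparative reversed-phase chromatography (RPC) of oligonucleotides is run as
linear gradient elution: the column is equilibrated and loaded at a low
organic-modifier level, then the modifier fraction (%B) ramps linearly until
all species desorb. Mechanistic column models capture the transport physics
well but rest on an adsorption law whose mechanism in RPC is not settled;
purely data-driven models need far more chromatograms than a process
development campaign produces. `chromsol` implements the hybrid middle
ground: a mechanistic column simulator whose *adsorption rates* are
multiplied, node by node and time step by time step, by the output of a
small neural network that is trained end-to-end by backpropagating the
chromatogram misfit **through the time-stepping solver itself**
(solver-in-the-loop). With the network at its identity initialization the
hybrid model *is* the mechanistic model; training only bends the adsorption
kinetics where the data demand it.

# The mechanistic core

For the ternary system of weakly adsorbed impurities W, main product P and
strongly adsorbed impurities S, plus the organic modifier m, the mobile
phase follows an equilibrium-dispersive model on the column axis
$z \in [0, L]$:

$$\frac{\partial c_i}{\partial t} =
  -\frac{u}{\varepsilon_t}\frac{\partial c_i}{\partial z}
  + D_\mathrm{app}\frac{\partial^2 c_i}{\partial z^2}
  - \frac{1-\varepsilon_t}{\varepsilon_t}\frac{\partial q_i}{\partial t},
  \qquad
\frac{\partial c_m}{\partial t} =
  -\frac{u}{\varepsilon_t}\frac{\partial c_m}{\partial z}
  + D_\mathrm{app}\frac{\partial^2 c_m}{\partial z^2},$$

with superficial velocity $u$ (set per method step), total porosity
$\varepsilon_t$, and all band broadening lumped into the flow-dependent
apparent dispersion $D_\mathrm{app} = uL/(2\varepsilon_t N)$ with plate
count $N$ (`apparent_dispersion()`). The stationary phase follows a
simplified stoichiometric displacement model (SDM),

$$k_{\mathrm{kin},i}\,\frac{\partial q_i}{\partial t} =
  k_{\mathrm{eq},i}\Bigl(\Lambda - \sum_j (\nu_j+\sigma_j)q_j\Bigr)^{\nu_i}
  c_i - q_i\,c_m^{\nu_i},
  \qquad
\frac{\partial q_m}{\partial t} = -\sum_j \nu_j \frac{\partial q_j}{\partial t}:$$

binding one solute molecule displaces $\nu_i$ modifier equivalents from the
ligand surface (density $\Lambda$) and sterically shields $\sigma_i$ more;
$k_{\mathrm{eq}}$ sets the equilibrium position, $k_{\mathrm{kin}}$ the
kinetic timescale. Boundary conditions are Danckwerts (Robin) at the inlet
and zero-gradient at the outlet; the initial column is regenerated and
equilibrated ($c$ at the equilibration inlet, $q_i = 0$, and
$q_m = \Lambda$ so that the displacement invariant
$q_m + \sum_j \nu_j q_j$ starts at $\Lambda$ and is conserved exactly —
a per-node identity the tests verify to below $10^{-8}$ relative drift).

**Units.** Internally everything is SI (m, s) with adsorbate concentrations
in g/L. The modifier is carried in %B throughout, so the $c_m^{\nu}$ terms
are in %B$^{\nu}$ and the $k_\mathrm{eq}$ values of any parameter set are
tied to that convention. Configuration files accept the units a method is
written in (mm, cm/h, CV) and convert on load.

# Discretization and time integration

Space is discretized with a nodal discontinuous Galerkin method
(`build_mesh()`): `K` uniform elements carrying degree-`np` Lagrange bases
on Legendre-Gauss-Lobatto nodes (defaults `K = 7`, `np = 3`). The published
DG-FEM literature for chromatography does not pin down the flux choices, so
the standard stable ones are used: upwind numerical flux for convection and
a local-DG first-order system with central fluxes for dispersion, with the
Danckwerts inlet imposed weakly through the boundary flux. Free-stream
preservation, polynomial exactness and h-convergence are unit-tested.

Time integration is fixed-step BDF (`bdf_integrate()`): step size a fixed
fraction of the simulated time (default 5 per-mille, i.e. 200 steps),
redistributed so solver step boundaries coincide with method-step
boundaries — velocities jump between steps and integrating across a
discontinuous forcing would pollute the multistep history, so the order
ramps 1 upward again after every boundary. Each implicit step solves

$$y_n + \sum_{j\ge1} a_j\,y_{n-j} = h\,\beta\, f(y_n)$$

by Newton iteration with an LU-factorized Jacobian. Numerical policy
choices worth recording:

* **Maximum order defaults to 3.** BDF4/5 lose A-stability in a wedge near
  the imaginary axis, exactly where the upwind-DG convection eigenvalues
  sit; on fine meshes a maximum-order-5 run develops growing modifier
  oscillations at these fixed step sizes. Orders up to 5 remain
  selectable (`solver_config(max_order = )`).
* **Modified Newton with monitored refresh.** The factored matrix is
  reused across iterations and steps while the error contracts by at least
  ~3x per iteration; otherwise it is rebuilt at the current iterate,
  degrading gracefully to full Newton on strongly nonlinear steps (load
  fronts, elution of the steep-$\nu$ component S). Updates are capped at
  100% relative change and a residual-norm backtracking line search guards
  against overshoot. Only the residual uses the exact right-hand side, so
  the converged state — and everything differentiated through it — is
  independent of these acceleration heuristics.
* **Newton tolerance** is a relative increment test at $10^{-10}$ by
  default ($10^{-13}$ in gradient-verification runs): gradient checks
  against finite differences are only as good as the nonlinear solves.
* The SDM surface-availability term is clamped at zero *for transient
  Newton iterates* (the residual must be defined off the physical
  manifold); accepted states are validated and a genuinely overloaded
  surface raises an error.

# The learned correction

A fully connected network with 7 inputs, `nL` hidden layers of `nl` ReLU
nodes and 3 Softplus outputs (defaults `nL = 2`, `nl = 14`) acts
independently at every mesh node. Inputs are the local
$(c_m, \tilde c_W, \tilde c_P, \tilde c_S, \tilde q_W, \tilde q_P,
\tilde q_S)$, where the tilde divides by the component's injection
concentration; $q_m$ is excluded and $c_m$ needs no normalization. The
three outputs multiply the three SDM rates, and the displacement balance
and mobile-phase coupling are recomputed from the *corrected* rates, so
the conservation identity holds for the hybrid model by construction.
Softplus keeps every multiplier strictly positive: the sign of the rate is
decided by the mechanistic driving force alone.

**Identity initialization.** Hidden layers are Kaiming-initialized, but the
output layer starts at zero weights with bias $\mathrm{softplus}^{-1}(1) =
\ln(e-1)$, so a fresh network multiplies every rate by exactly 1 and the
initial hybrid loss equals the calibrated mechanistic loss. Pure Kaiming
initialization of the output layer would start the corrections near
$\mathrm{softplus}(0) \approx 0.69$ and visibly perturb the initial model,
contradicting the observed near-mechanistic starting loss this scheme is
designed to reproduce; the deliberate deviation on that one layer
guarantees it exactly.

# Differentiation through the solver

Training gradients are not approximated by any finite-difference or
surrogate scheme: the package implements discretize-then-optimize reverse
mode through the unrolled integration. Each converged BDF step defines
$y_n$ implicitly; by the implicit function theorem, with
$A_n = I - h\beta J_f(y_n)$,

$$A_n\,\mathrm{d}y_n = -\sum_j a_j\,\mathrm{d}y_{n-j}
  + h\beta\,\frac{\partial f}{\partial p}\,\mathrm{d}p,$$

so the reverse sweep solves $A_n^\top w = \bar y_n$ once per step, scatters
$-a_j w$ into the history adjoints, and contracts $h\beta w$ against the
parameter derivatives of the right-hand side — the network weights (via a
hand-written batched backward pass) or the SDM parameters (via their
analytic derivatives, used by `calibrate()`). The Jacobian $J_f$ is
analytic throughout: transport operator blocks plus node-local SDM and
network input-Jacobian blocks. Gradients are exact up to the Newton
tolerance; the test suite checks them against central finite differences at
relative error below $10^{-4}$ on a tiny instance (in practice they agree
to ~$10^{-7}$), for both the network weights and the mechanistic
parameters.

`calibrate()` reuses the same machinery for the mechanistic initialization:
L-BFGS on log-transformed SDM parameters (strict positivity for free),
with the same loss, normalization and data partitioning as hybrid
training. The literature's "parameter-by-parameter" pre-step is delegated
to an external reference we do not reproduce; in its place the function
accepts user initial guesses and offers an optional coarse one-dimensional
scan per parameter before the gradient descent.

# Loss, observation model and benchmark

Observations are *fraction averages*: the outlet concentrations averaged
over consecutive fraction-collector windows (default 0.25 CV — a fixture;
the real fraction volume is not printed) spanning the gradient step only,
which is when fractions are collected in practice. Predictions are averaged
over the same windows (piecewise-linear interpolation of the solver
snapshots, a linear operation the adjoint passes through exactly). The loss
is the normalized squared distance
$L = \lVert \hat C - C\rVert^2 / \lVert C\rVert^2$ pooled over the four
chromatogram columns, with adsorbates divided by their injection
concentrations. The modifier column needs no data-driven normalization
*because %B is already an order-one fraction*: the loss maps it to its 0-1
fractional scale. Carrying it in raw percent instead would make the
modifier dominate both norms roughly fifty-fold and dilute any adsorption
misfit below the noise floor, which is incompatible with mechanistic
misfits of order $10^{-1}$ reported for fits of this kind (a flag excludes
the modifier entirely). Across experiments the arithmetic mean of
per-experiment losses is used, and per-experiment contributions are logged.

**The synthetic benchmark** (`benchmark_dataset()`) stands in for a
six-experiment campaign whose raw data are not public. It reproduces the
printed method program exactly — equilibration 3 CV at 400 cm/h, load at
300, wash 2 CV at 150, linear 30-100 %B gradient at 200, strip 2 CV at
150 — crossed with loadings 7.5/15/22.5 g per liter of packed column and
gradient lengths 4.6/6.5/8.5 CV in the six printed combinations, three for
training and three for testing. Choices the printed record does not fix,
and how they were made:

* **Feed.** The feed concentration is never printed; the generator uses
  1 g/L total so a loading of $x$ g/L$_\mathrm{resin}$ is $x$ CV of feed.
  Composition W:P:S = 10% : 88.8% : 1.2% — only the S share (1.2% of the
  crude) is reported; W is a benchmark choice. The load step runs at the
  equilibration modifier level (30 %B), continuous with its neighbors.
* **Column constants.** $\Lambda = 5000$ (model units) and $N = 2000$
  plates are fixtures (neither is printed); $\Lambda$ leaves ample surface
  capacity at the highest loading, $N$ is typical of a well-packed 10 µm
  bed of this length.
* **SDM parameters.** The published characteristic charges and shielding
  factors are kept ($\nu_W < \nu_P < \nu_S$, $\sigma_S = 0$ — the
  reproducible content, since they set the retention order), while
  $k_\mathrm{eq}$ and $k_\mathrm{kin}$ are *rescaled fixtures*: the printed
  values are tied to an unstated modifier-unit convention and cannot be
  used directly. `benchmark_components()` places each component's
  retention factor at 2 when the modifier reaches a target elution level
  (45/55/70 %B) and gives the kinetics a 120 s relaxation timescale there.
  Both targets were set by forward-simulation screening with two
  requirements fixed in advance: all three peaks elute inside the shortest
  gradient window, and the kinetics are rate-limiting — near-equilibrium
  kinetics would render any rate correction invisible in the chromatogram
  and the benchmark could not exercise hybrid training at all.
* **Ground-truth correction.** W stays mechanistic; P binding accelerates
  saturably with its local mobile concentration,
  $g_P = 1 + 0.3\,\tilde c_P/(0.1 + \tilde c_P)$; S binding accelerates
  linearly with its local stationary loading, $g_S = 1 + 0.015\,\tilde
  q_S$. The $\tilde q_S$ coefficient is set so the amplification peaks
  near 3-4x at the densest S loading ($\tilde q_S$ reaches ~200 because
  the S injection concentration is 0.012 g/L): clearly measurable against
  the 2% observation noise, yet still a kinetic correction rather than a
  regime change — steeper couplings make the implicit steps intractable
  and describe no plausible adsorption physics. The correction evaluates
  its features through the smoothed ramp $(x + \sqrt{x^2+\varepsilon^2})/2$
  ($\varepsilon = 0.05$), equal to the identity on the physical domain to
  within $\varepsilon/2$ but smooth and pole-free for the off-manifold
  states transient Newton iterates visit.
* **Noise.** Multiplicative Gaussian, 2% relative, truncated at zero,
  fully determined by the seed.

**What the generator does not emulate:** detector characteristics and UV
calibration, injection-system dead volumes, the conductivity-to-%B
conversion (the modifier "observation" is the simulated outlet modifier),
HPLC re-assay error structure of collected fractions, and temperature or
buffer-composition effects. Passing the benchmark therefore demonstrates
that the estimator and its gradients work — that a correction of this
functional class is recoverable from three fraction-averaged, noisy
chromatograms — not that any particular laboratory column obeys the
recovered law.

# Training procedure and problem sizes

`train_correction()` runs full-batch Adam (moments 0.9/0.999, eps 1e-8,
default learning rate $10^{-3}$) on the network parameters only; one epoch
is one forward simulation of every training experiment plus one reverse
sweep; the best epoch is retained. `grid_search()` trains every cell of a
(layers x nodes x learning-rate) grid for 20 epochs from the same
identity-initialized seed and reports the full table, the argmin (ties
broken toward fewer parameters, then the smaller learning rate — the tie
rule is ours) and the fraction of cells beating the mechanistic baseline.
The canonical search space is `nL` in 1-3, `nl` in 3-21, learning rate in
$10^{-4}..10^{-1}$ (228 cells); the test suite exercises a 3x3x2 sub-grid.

The package's own verification runs choose deliberately small problem
sizes: benchmark training and evaluation at `K = 4`, `np = 2`, 100 BDF
steps (96 state dimensions); the hyperparameter sub-grid at `K = 3`, 80
steps; gradient verification at `K = 2`, `np = 2`, 10 steps with a
1-layer, 2-node network so every parameter can be checked against central
finite differences. These sizes resolve the chromatograms sufficiently for
the properties being tested while keeping a full training run in the tens
of seconds; production simulations use the `K = 7`, `np = 3`, 200-step
defaults.

# Known limitations

* Single precision is not offered: R's numeric type is double, and
  finite-difference verification of gradients is unreliable in single
  precision anyway.
* Fixed-step BDF only — no adaptive step-size or error control; the
  order-reduction retry on a failed Newton solve is the only adaptivity.
* No pore/film mass-transfer resistances (the equilibrium-dispersive
  model has none) and no activity-model corrections for the organic
  modifier.
* The correction is node-local by design; corrections with spatial or
  temporal memory are out of scope.
* Concentrations are kept positive by resolution and kinetics, monitored
  rather than limited; severe under-resolution can still produce
  undershoots, which surface as validation errors rather than being
  silently clipped.
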