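---
title: "Entropy extensivity in evolving two-layer multiplex networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy extensivity in evolving two-layer multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extensivity)
```

## The question the package answers

A dynamical quantity is *extensive* when it grows linearly with system size
N. For chaotic networks the natural candidate is the sum of the positive
Lyapunov exponents,

$$H_{KS} = \sum_{\lambda_i > 0} \lambda_i,$$

which by Pesin-type relations bounds the Kolmogorov–Sinai entropy — the rate
at which the network produces information. This package implements the full
machinery for asking when $H_{KS}$ of a **two-layer multiplex network**
(two subnetworks joined by inter-layer connections) stays extensive as the
network grows and as inter-layer connections are added by a greedy
evolutionary rule: analytic Lyapunov spectra for diffusively coupled shift
maps, a Hindmarsh–Rose (HR) neuronal simulator with full tangent-space
Lyapunov computation, and the evolution and scaling analyses tying them
together.

## The analytic backbone: shift maps on a supra-Laplacian

Each node of the discrete model carries the doubling map, coupled through

$$x_{n+1} = (2 x_n - \mathbf{L} x_n) \bmod 1,\qquad
  \mathbf{L} = \epsilon \mathbf{L}^B + \gamma \alpha \mathbf{L}^A,$$

where $\mathbf{L}^B$ is the block-diagonal intra-layer Laplacian,
$\mathbf{L}^A$ the inter-layer Laplacian built from the inter-adjacency and
its degree matrices, $\epsilon$ and $\gamma$ the intra- and inter-coupling
strengths, and $\alpha = l_{12}/N_1$ the inter-connection density. The
Jacobian $2I - \mathbf{L}$ is constant, so each exponent is exactly
$\lambda_i = \log|2 - \mu_i|$ with $\mu_i$ the eigenvalues of $\mathbf{L}$
(`les_from_supra()`), and the mod wrap never touches the tangent dynamics.

For the *mirror* configuration — two identical layers, every node linked to
its mirror image — the supra eigenvalues pair in closed form,
$\mu = \epsilon\omega_i$ and $\mu = \epsilon\omega_i + 2\gamma\alpha$ over
the layer spectrum $\omega$ (`les_from_layer()`). A convention worth
stating: the package stores the mirror inter-adjacency as the **unit
identity pattern** and carries link multiplicity in the scalar $\alpha$.
This is the only reading under which the pairing holds exactly when
$l_{12} > N_1$, and it is what the pairing-vs-eigensolver oracle tests pin
down to $10^{-10}$. The general constructor (`build_multiplex()`) uses the
literal 0/1 inter-adjacency and promises no pairing.

One consequence the tests document: with the general constructor the
first-order cost of one extra inter-edge is $\gamma(2l_{12}+1)/N_1$ rather
than the mirror value $\gamma$, because $\alpha$ multiplies the inter-layer
Laplacian and both grow with $l_{12}$.

In the small-coupling, all-exponents-positive regime the entropy proxy has
explicit first-order forms (`hks_taylor_single()`, `hks_taylor_multiplex()`,
`hks_taylor_mixed()`), e.g.

$$H_{KS} \approx N\log 2 - \tfrac{\epsilon}{2}S' - \gamma l_{12},$$

with $S'$ the degree sum of the whole multiplex. These are first-order
expansions: their error contracts about four-fold when
$(\epsilon, \gamma\alpha)$ are halved, which is exactly what the
acceptance suite measures. The package warns (rather than errors) when
$\epsilon\,\omega_{\max} > 0.5$ or $\gamma\alpha > 0.5$, since validity
only requires "sufficiently small" couplings. A supra eigenvalue exactly
equal to 2 makes the Jacobian singular; that is an error with a pointer to
perturb the couplings.

Two counting conventions are fixed deliberately: zero exponents count into
$u$, the number of non-positive exponents (making $u$ deterministic), and
$H_{KS}$ sums *strictly* positive exponents.

The printed all-positivity thresholds in the source material
($\epsilon > 1/\omega_{N_1}$ for all-to-all, $\epsilon > 1/2k$ for rings)
point the opposite way from the exact condition $|2 - \epsilon\omega_i| > 1
\iff \epsilon\omega_i < 1$ on the small-coupling branch.
`all_les_positive()` therefore evaluates the exact condition and never
encodes the printed inequality.

## Extensivity, rescaling and invariance constants

Since $\sum_i \omega_i = \sum_i d_i \equiv S$, the degree sum controls the
coupling budget. If $S \propto N^{\theta+1}$, extensivity survives exactly
when $\epsilon \propto N^{-\theta}$ (`epsilon_rescaling()`): rings and
small worlds ($\theta = 0$) keep $\epsilon$ constant, all-to-all networks
($\theta = 1$) need $\epsilon \propto 1/N$. `fit_hks_scaling()` classifies
a family from two fits: an OLS line $H_{KS} = \sigma N + \nu$ (unweighted,
as no weighting scheme is implied by the theory) and a log–log exponent
estimate $\hat\theta$. The *extensive* call requires both
$|\hat\theta| \le 0.1$ and linear $R^2 \ge 0.95$ by default — a finite-size
test of an asymptotic property needs explicit tolerances, and both are
arguments. When a family loses all positive exponents the power-law fit is
undefined and the family is reported non-extensive.

Whether the *normalised spectrum* ($\lambda_i$ against $i/N$) collapses to
one curve as the family grows is governed by three constants
(`invariance_constants()`): $C = \bar d / \omega_{\max}$,
$C_1 = \epsilon\,\omega_{\max}$ and $C_2 = C_1(C-1)+1$, where $C_2$ also
equals the spectral average $\frac{1}{N_1}\sum_i (C_1 \omega_i /
\omega_{\max} + 1 - C_1)$ — an algebraic identity the package verifies to
machine precision as its self-consistency anchor. One symbol collision in
the source derivation is resolved explicitly: in the reciprocal-coupling
case study the mean degree grows as $\bar d = aN + \xi$ and the slope
involves $a/2$; that $a$ is unrelated to the inter-connection density
$\alpha = l_{12}/N_1$, which is a separate field throughout the package.
The degree-form residual (`extensivity_degree_residual()`) implements the
convenience form with the $N/4$ term as printed; its derivation is not
reproduced here, but the implemented form is checked symbolically at its
algebraic zeroes. The intercept $\nu$ is treated as a free parameter of
the fit.

## The Hindmarsh–Rose multiplex

Each neuron follows the three-variable HR model (membrane potential $p$,
fast recovery $q$, slow adaptation $n$) with the standard chaotic-bursting
constants $a=1, b=3, c=1, d=5, s=4, p_0=-1.6, r=0.005, I_{ext}=3.25$.
Electrical (diffusive) coupling acts *within* layers through the
block-diagonal Laplacian; chemical coupling acts *between* layers through
the sigmoid-gated excitatory current
$-\gamma (p_i - V_{syn}) \sum_j A_{ij} K(p_j)$ with
$K(p) = (1+e^{-\lambda_{sig}(p - \theta_{syn})})^{-1}$,
$\theta_{syn} = -0.25$, $\lambda_{sig} = 10$, $V_{syn} = 2$. The equations
of motion overload one symbol (the matrix multiplying the electrical term
is also called an inter-layer Laplacian in other contexts); the package
follows the physical reading — electrical = intra, chemical = inter — and
records the clash here rather than resolving it.

Numerical choices, each validated by a test rather than assumed:

* **Integrator**: fixed-step classical RK4, `dt = 0.01` by default. A fixed
  step keeps the tangent frame propagation consistent with the orbit;
  step-halving at `t = 100` moves the state by less than $10^{-4}$.
* **Variational equations**: the analytic Jacobian (including the chemical
  derivative terms $-\gamma(p_i - V_{syn})A_{ij}K'(p_j)$) drives the
  tangent frame; it is checked against central finite differences at
  random states to $10^{-5}$.
* **Benettin QR**: the orthonormal frame is re-orthonormalised every 1 time
  unit; exponents are time-averaged log diagonals of R. Defaults
  `t_transient = 1000`, `t_total = 20000` make single-neuron exponents
  reproducible across seeds to about $\pm 0.005$. Consistency oracle: the
  exponent sum must equal the orbit-averaged Jacobian trace (dissipation),
  and on a linear flow $\dot x = (CI - L)x$ the machinery must reproduce
  $C - \mu_i$ to $10^{-3}$.
* **Initial conditions**: per-neuron uniform draws $p \in (-1.6, 1.6)$,
  $q \in (-1, 1)$, $n \in (2.8, 3.2)$, drawn block-wise from one seeded
  stream.
* **Divergence guard**: $|p| > 10^3$ aborts with a diagnostic.

Finite-time caveat: deeply contracting directions ($\lambda < -2$) carry
much larger finite-time fluctuations than the near-zero part of the
spectrum; degeneracy and convergence statements in the tests are therefore
made on the dynamically meaningful band $|\lambda| < 1$.

## Greedy evolution and the coupling sweep

`evolve_multiplex()` implements the growth rule: candidate inter-layer
pairs are drawn in a seeded random order, each visited exactly once, and a
candidate edge is retained **only if it strictly increases** the estimated
$H_{KS}$ (equal values are rejected — "increase" means increase, which
also makes ties impossible). Couplings and intra-topologies stay fixed;
only $\alpha$ grows. The operation takes any estimator
`f(g, epsilon, gamma)`; with the exact map estimator the whole trace is
bit-reproducible under a fixed seed and serves as the oracle for the
greedy logic before any differential equation is integrated. For the HR
estimator an acceptance margin `margin` (default 0, mirroring the strict
rule) can absorb estimator noise; single-visit candidate order means a
rejected pair is never revisited. `coupling_sweep()` re-evolves the same
initial network at every $(\gamma, \epsilon)$ grid point and reports the
argmax with deterministic tie-breaking (smallest $\gamma$, then smallest
$\epsilon$).

`extensivity_experiment()` chains everything: per size, two layers from a
factory, one initial inter-edge, evolve, then classify the final
$(N, H_{KS})$ series. Degree sums before and after evolution (`s_in`,
`s_fn`, inter-edges counted twice) are recorded because linear growth of
the degree sum is the structural side of the extensivity story. The
screening estimator may be cheap; a `final_estimator` with a fuller
Benettin budget re-evaluates each evolved end network, since candidate
*ranking* needs far less accuracy than the reported spectrum.

## What the generators emulate — and what they do not

The study conditions are built in as defaults. Layer generators produce the
regimes the theory distinguishes: ring lattices (`circulant_layer`, total
degree $k$, so $S = kN_1$ exactly), Watts–Strogatz small worlds
(`small_world_layer`, hand-rolled degree-preserving rewiring so $S = kN_1$
holds for every seed — a generator that simplified multi-edges away would
silently break this), all-to-all layers ($S = N_1(N_1-1)$) and
Erdős–Rényi layers (expected $S$ linear at fixed mean degree). Disconnected
stochastic layers are regenerated with an incremented seed, at most 100
times. Rewiring probability and degree default to $p = 0.2$, $k = 4$ where
a choice is needed; the neuronal experiments use two *different* small-world
wirings per multiplex, as different seeds of the same generator.

What passing tests show is fidelity to this idealised setting: undirected,
unweighted, two equal-size layers, excitatory chemical synapses, no delays
or noise. Real neuronal tissue satisfies none of those restrictions, so
extensivity findings here transfer to real data only as far as the degree-sum
mechanism — not the biological detail — is what drives them.

### Problem sizes used in the shipped experiments

The package's own experiments and checks run at deliberately modest sizes,
chosen so that every claim is recomputed from scratch on one CPU: map
families up to $N = 128$ nodes (exact spectra, so size is cheap), HR
extensivity at $N \in \{8, 12, 16\}$ neurons with a screening Benettin
budget of `dt = 0.02`, `t_total = 350` per candidate edge and a final
re-evaluation at `t_total = 1500`, and the single-neuron reference runs at
`t_total = 20000`. The evolved-HR slope at these sizes is a desk-scale
analogue of the full-scale neuronal experiment (dozens of coupling pairs,
$N$ up to ~100): it establishes the *positive linear trend* of $H_{KS}$
with $N$ under fixed near-optimal couplings with $\epsilon \ll \gamma$
($\epsilon = 0.01$, $\gamma = 0.1$ — chosen once from a coarse probe of
the coupling plane, in the regime the theory singles out), not the
full-scale slope value.

## Known limitations

* Two layers only; intra-layer graphs are unweighted and undirected.
* The mirror closed form is exactly that — mirror-only; general multiplexes
  always go through the dense eigensolver.
* Benettin estimates at screening budgets are rankings, not publishable
  exponents; re-evaluate end networks with the defaults before quoting
  numbers.
* The greedy rule never deletes or rewires edges, and no other
  metaheuristic is provided; the evolution is the one rule studied, not an
  optimiser toolbox.
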