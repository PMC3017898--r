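---
title: "Spectral collocation for tumour invasion models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral collocation for tumour invasion models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chebinvade)
```

## The biological model and its assumptions

The package simulates continuum models of avascular tumour invasion in a
one-dimensional scaled tissue domain $x \in [0,1]$. Three densities
interact everywhere in space: tumour cells $n$, extracellular matrix
$f$, and matrix-degradative enzymes $m$; the four-field variant adds an
endogenous inhibitor concentration $u$:

$$
\begin{aligned}
\partial_t n &= d_n\,\partial_x^2 n
  - \gamma\,\partial_x\!\left(n\,\partial_x f\right)
  + \mu_1\,n\,(1 - n - f),\\
\partial_t f &= -\eta\, m f + \mu_2\, f\,(1 - n - f),\\
\partial_t m &= d_m\,\partial_x^2 m + P(n) - \theta\,u m - \beta m,\\
\partial_t u &= d_u\,\partial_x^2 u + \xi f - \theta\,u m - \rho u.
\end{aligned}
$$

The modelling assumptions worth keeping in mind:

* The ECM does not move: $f$ has no transport term, only degradation by
  enzymes ($\eta m f$) and optional logistic renewal ($\mu_2$).
* Haptotaxis is advection of cells up the ECM gradient with constant
  sensitivity $\gamma$; there is no chemotaxis toward diffusible
  signals.
* MDE production is either proportional to the cell density,
  $P(n) = \alpha n$, or saturating, $P(n) = \alpha n(1-n)$, reflecting
  polarised enzyme expression at the invading edge.
* Inhibitors are produced by the surviving matrix ($\xi f$), neutralise
  enzymes pairwise ($\theta u m$), and decay ($\rho u$).

Four variants are exposed (`invasion_variant()`): `basic` ($\mu_1 =
\mu_2 = 0$, absorbing right wall $n = m = 0$), `proliferation`,
`saturating`, and `inhibitor`, the last three with zero-flux conditions
at both walls: the total tumour flux $d_n n_x - \gamma n f_x$ and the
diffusive fluxes $m_x$, $u_x$ vanish there. All runs start from a tumour
centred at the left wall, $n(x,0) = e^{-x^2/\varepsilon}$, with
$f = 1 - 0.5\,n$, $m = 0.5\,n$, $u = 0$.

## Spatial discretisation

Fields are collocated at the $N+2$ Chebyshev–Gauss–Lobatto nodes
$x_i = \tfrac12 - \tfrac12\cos\!\big(i\pi/(N+1)\big)$ and differentiated
through the dense first-order spectral matrix $D$ (`cgl_grid()`).
$D$ is built from the barycentric formula with the negative-sum trick
for the diagonal, so a constant differentiates to exactly zero and the
matrix is exact on polynomials of degree $N+1$ (verified to ~1e-12 up to
$N = 60$ in the tests). Second derivatives are formed by composing
first-order operators, never by a separate second-order matrix.

Boundary conditions are embedded in the operators rather than imposed as
algebraic constraints:

* **Flux walls.** The boundary rows of the derivative of $n$ are
  replaced by the value the flux condition implies,
  $n_x = (\gamma/d_n)\,n f_x$ at the wall. Consequence: the discrete
  wall flux $d_n n_x - \gamma n f_x$ cancels *identically* (to 1e-12,
  property-tested on random states), which is what makes the scheme
  conservative — the Clenshaw–Curtis mass of $n$ drifts by only ~1e-14
  relative over $t \in [0,10]$ in the proliferation variant with
  $\mu_1 = \mu_2 = 0$. For $m$ and $u$ the Neumann rows are simply
  zeroed (`D00`), and the second derivative is the composition
  $D\,D_{00}$.
* **Dirichlet wall** (`basic`). The right-boundary values $n = m = 0$
  are known, so those nodes are dropped from the unknowns (the system
  has $3N+3$ equations) and the known values enter through the last
  column of $D$. The ECM value at that wall never changes — since
  $m(1,t) = 0$, $\partial_t f(1,t) = 0$ — so it is stored once as the
  constant $f(1,0) = 1 - 0.5\,e^{-1/\varepsilon}$ rather than evolved
  as an extra ODE.

One display convention had to be fixed by interpretation: with flux
conditions at both walls all four fields are carried on all $N+2$ nodes
(the wall values appear in the embedded boundary terms and must be
evolved), and the boundary-row-zeroed matrix `D00` is the full square
$(N+2)\times(N+2)$ operator acting on full-length vectors. Likewise the
enzyme and inhibitor diffusion terms are the composition
$D\,(D_{00}\,\cdot)$; a single first-order application would not be a
second derivative, and the package's closed-form heat-equation test
pins this down.

## Time integration

The semidiscrete systems are stiff in a mundane way: the ECM kinetics
$-\eta m f$ with $\eta$ up to 20 and $m = O(1)$ give local rates far
above the transport scales ($d_n = d_m = 10^{-3}$). The default
integrator is `deSolve`'s `lsoda` (adaptive, switches to BDF when
stiffness is detected) with `rel_tol = 1e-8`, `abs_tol = 1e-10`; `bdf`,
`vode`, `lsode`, and `radau` are accepted alternatives
(`integrator_settings()`). The pipeline is deterministic — identical
settings give bit-identical snapshot tables — and integration aborts
with a diagnostic if any field exceeds 1e6 in magnitude (blow-up guard;
no stability theory is available for these schemes). Halving the
tolerances moves snapshot values by far less than the coarser tolerance
(self-consistency test).

## Parameters

| symbol | argument | meaning | base value |
|---|---|---|---|
| $d_n$ | `dn` | tumour random motility | 0.001 |
| $d_m$ | `dm` | MDE diffusion | 0.001 |
| $d_u$ | `du` | inhibitor diffusion | 0.001 (fig15) |
| $\gamma$ | `gamma` | haptotaxis sensitivity | 0.005–0.02 |
| $\eta$ | `eta` | ECM degradation rate | 10 or 20 |
| $\alpha$ | `alpha` | MDE production | 0.1 |
| $\beta$ | `beta` | MDE decay | 0 or 0.07 |
| $\mu_1$ | `mu1` | tumour proliferation | 0, 0.1, 0.5 |
| $\mu_2$ | `mu2` | ECM renewal | 0, 0.1, 0.5 |
| $\theta$ | `theta` | MDE neutralisation | 0.05 (fig15) |
| $\xi$ | `xi` | inhibitor production | 0.03 (fig15) |
| $\rho$ | `rho` | inhibitor decay | 0.07 (fig15) |
| $\varepsilon$ | `epsilon` | initial tumour width | 0.01 |

All quantities are dimensionless (the domain and densities are scaled).
The twelve `invasion_presets()` encode the figure scenarios of the
simulation study the package reproduces; the grid order is $N = 43$ for
the fig5 preset and $N = 30$ elsewhere (the default, overridable).
Validation requires $d_n, d_m, \varepsilon > 0$ (the
embedded boundary substitution contains $\gamma/d_n$) and $d_u > 0$ for
the inhibitor variant.

## Validation design

Because the solutions are smooth fronts, validation rests on three
independent pillars rather than on reference curves:

1. **Closed forms.** With all coupling off, the tumour equation is a
   Neumann heat equation; the solver reproduces
   $1 + e^{-d_n\pi^2 t}\cos(\pi x)$ at $t = 100$, $N = 30$ to ~1e-8
   (tolerance 1e-6 in the acceptance test).
2. **An independent reference solver.** `fd_reference_solve()` is a
   vertex-centred finite-volume scheme on a uniform grid: face-centred
   fluxes with arithmetic-mean densities and centred gradients, no
   upwinding, wall fluxes set to zero (or Dirichlet values pinned), a
   banded-Jacobian stiff integration. It shares no discretisation code
   with the spectral modules. For the fig1 configuration at $t = 1$ the
   two solvers agree to ~2.4e-3 max-abs in $n$ (bound 5e-3 at
   $M = 4001$). A caveat found during the refinement study
   $M \in \{501, 1001, 2001, 4001\}$: the cross-discrepancy *saturates*
   at that level rather than decreasing, because the $N = 30$ spectral
   error dominates the FD error (already below 1e-5 at $M = 501$); what
   decreases monotonically is the FD family's own error against its
   finest member, and that is what the acceptance test asserts.
3. **Structural properties on random states.** Wall-flux cancellation,
   ECM monotonicity when renewal is off, the all-zero fixed point,
   polynomial exactness, and the reversal antisymmetry of $D$ are
   property-tested under fixed seeds.

## Diagnostics: what counts as a "cluster"

The phenomenon of interest is metastatic break-off: a secondary local
maximum of tumour density detaching from the main body. "Cluster" is
made operational as follows (`count_clusters()`): evaluate the
barycentric interpolant on 1001 uniform points; keep local maxima
(boundaries compared one-sidedly) of height at least `height_frac`
(default 0.1) of the global maximum; merge two maxima unless the
minimum between them falls below $1 - {}$`dip_frac` (default 0.1) times
the lower peak. The counts are stable for `height_frac` anywhere in
$[0.05, 0.2]$ on the tested configurations.

With this rule the fig3 configuration ($\gamma = 0.01$) shows two
distinct clusters at $t = 1$ and $t = 10$. The fig1 configuration
($\gamma = 0.005$) shows one cluster at $t = 1$ — the profile is
strictly monotone there, confirmed by both solvers at high resolution —
and two at $t = 10$. The break-off phenomenon is reproduced in both
configurations, with the weaker haptotaxis producing it later.

## Numerical choices and degenerate inputs

* Node ordering is ascending in $x$; no re-indexing from the classical
  descending Chebyshev convention.
* $\gamma = 0$ with $d_n > 0$ is allowed (the boundary substitution
  weight vanishes and the walls become plain Neumann); $d_n = 0$ is
  rejected at parameter validation.
* Requesting only $t = 0$ returns the initial state without invoking
  the integrator.
* The Clenshaw–Curtis weights are obtained by solving the
  Chebyshev-basis moment system (exact moments $\int_{-1}^1 T_j$),
  which is well conditioned and exact for degree $\le N+1$; quadrature
  of a constant returns 1 to 1e-16.
* CSV output uses 17-significant-digit formatting so a written snapshot
  re-imports bit-exactly.

## Problem sizes used in the tests

The shipped tests run the spectral solver at $N \le 30$ (plus kernel
checks at $N = 60$), the reference solver up to $M = 4001$ at $t \le 1$
and $M = 2001$ for the closed-form check at $t = 10$; the full suite
takes a few seconds on one core. These sizes were chosen as the smallest
that exercise every regime (spectral plateau, FD convergence, stiff
kinetics); the solvers themselves accept larger $N$, $M$, and time
horizons.

## Known limitations

* One spatial dimension only; no 2-D domains.
* The inhibitor production law is fixed to $\xi f$; other response
  functions are out of scope.
* Neither scheme is positivity-preserving: small negative undershoots
  (~1e-5) appear ahead of steep fronts in both solvers. They do not
  grow, but users comparing pointwise minima should expect them.
* The cluster rule is a reasonable operationalisation of a visual
  criterion, not a model-intrinsic quantity; counts at other
  `height_frac`/`dip_frac` values are a keystroke away but not
  asserted.
* No parameter estimation against laboratory data is included; presets
  are qualitative scenario values.
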