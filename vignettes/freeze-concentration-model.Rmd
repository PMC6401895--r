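---
title: "A mesoscale phase-field model of freeze concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mesoscale phase-field model of freeze concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icefield)
```

## The problem

When bulk protein solutions are frozen for storage, solutes (protein and
excipients such as sucrose) are excluded from the growing ice crystals and
accumulate in the shrinking interstitial liquid. This *freeze concentration*
— amplified by space confinement between crystals, rising viscosity, and
freezing-point depression — can destabilize the protein. `icefield`
simulates the process at the mesoscale (a periodic box of a few tens of
microns) for a sucrose–water model system, resolving the coupled evolution
of the ice/solution interface, the solute field, temperature, and the weak
flow induced by the density change upon freezing and by buoyancy.

## Model

Two order parameters live on a periodic square domain of side $2\pi L$
($L = 10\,\mu$m):

* $\phi_{s\ell}(\mathbf r, t) \in [-1, 1]$ — a non-conserved phase field,
  $+1$ in ice, $-1$ in liquid, with a smooth $\tanh$ transition of width
  $\sqrt2\,W_{s\ell}$ ($W_{s\ell} = 1\,\mu$m);
* $\phi_c(\mathbf r, t) \in [0, 1]$ — the conserved solute volume fraction.

All equations are integrated in scaled form. Lengths are scaled by $L$,
time by the phase-transition scale $\tau_{s\ell} = 1/(\rho_0 h_{s\ell}
M_{s\ell})$, temperature by $\tilde T = (T - T_0)/\Delta T$ with
$T_0 = 273.15$ K and $\Delta T = 10$ K. By default $\tau_{s\ell}$ is tied
to the solute-diffusion scale $L^2/D_0$ so that the Peclet number is 1.

**Phase field (Allen–Cahn type).** The interface evolves under interfacial
diffusion, a thermodynamic driving force proportional to the local
undercooling below the concentration-dependent liquidus
$T_{eq}(\phi_c) = T_0 - 55\,\phi_c^2$, a double-well restoring term, and a
solute-exclusion barrier from the jump in the Flory interaction parameter
between liquid ($\chi_\ell = 0.5$) and crystal ($\chi_s = 2.5$):

$$
\partial_{\tilde t}\phi_{s\ell} + Pe\,\tilde{\mathbf v}\cdot\tilde\nabla\phi_{s\ell}
= Ch^2 \tilde\nabla^2 \phi_{s\ell}
+ \Lambda_{s\ell}(1-\phi_c) P'\,
  \frac{\tilde T - \tilde T_{eq}}
       {(1+\epsilon \tilde T)(1+\epsilon \tilde T_{eq})}
+ (1-\phi_c)(\phi_{s\ell}-\phi_{s\ell}^3)
- \frac{R}{h_{s\ell}}\chi' G ,
$$

with $\epsilon = \Delta T/T_0$, $Ch = W_{s\ell}/L = 0.1$, and
$\Lambda_{s\ell} = L_a \Delta T/(h_{s\ell} T_0^2) \approx 313$. $P$ is the
fifth-order interpolation polynomial with $P(-1)=1$ (liquid), $P(1)=0$
(solid) and $P' = P'' = 0$ at both wells; $G = 4\phi_c^2(1-\phi_c)^2$ is the
double-well mixing function. The undercooling factor follows from scaling
the dimensional driving force $\propto (T - T_{eq})/(T\,T_{eq})$, which
places *both* temperature corrections in the denominator.

**Solute (Cahn–Hilliard type, conservative).** Solute moves by Fickian and
enthalpic diffusion with the degenerate mobility $\phi_c - \phi_c^2$, by a
drift down the $\chi$ gradient (the exclusion flux at moving fronts), and
by a weak fourth-order gradient-energy flux with coefficient
$Ch^2 h_{s\ell}/R$:

$$
\partial_{\tilde t}\phi_c + Pe\,\tilde{\mathbf v}\cdot\tilde\nabla\phi_c =
\frac{\tau_{s\ell}}{\tau_{\phi_c}} \tilde\nabla\cdot
\Big\{ \tilde D \Big[\tfrac{1-\phi_c}{N} + \phi_c + (\phi_c-\phi_c^2)\chi G''\Big]
 \tilde\nabla\phi_c
+ \tilde D(\phi_c-\phi_c^2) G' \tilde\nabla\chi
- Ch^2 \tfrac{h_{s\ell}}{R}\tilde D(\phi_c-\phi_c^2)
  \tilde\nabla\tilde\nabla^2\phi_c \Big\}.
$$

$N = 11.5$ is the solute-to-water molar-volume ratio (sucrose). The
divergence form makes the domain mean of $\phi_c$ exactly conserved by the
discrete update in no-flow runs.

**Thermal energy.** Conduction (fast: interfacial Lewis number
$Le \approx 4831$), latent-heat and partition-energy release tied to the
material derivative of $\phi_{s\ell}$, a mixing term tied to that of
$\phi_c$, and a uniform volumetric cooling sink
$\tilde{\dot\Omega} = \tau_{s\ell}/\tau_f \approx 4.76$ representing bulk
cooling at $\beta_f = 100$ K/s:

$$
\partial_{\tilde t}\tilde T + Pe\,\tilde{\mathbf v}\cdot\tilde\nabla\tilde T =
Le\, \tilde\nabla\cdot\Big(\frac{\tilde k_T}{\tilde\rho \tilde c_p}
\tilde\nabla \tilde T\Big)
- \frac{1}{\tilde c_p\,Ste_1}\Big[P' + Ste_2\big(\tilde T + \tfrac{T_0}{\Delta T}\big)\chi' G\Big]
  \frac{D\phi_{s\ell}}{D\tilde t}
- \frac{Ste_2}{\tilde c_p\,Ste_1}\big(\tilde T + \tfrac{T_0}{\Delta T}\big)\chi G'
  \frac{D\phi_c}{D\tilde t}
- \tilde{\dot\Omega}.
$$

Scaling the dimensional source $\rho[L_a P' + R T \chi' G]$ by
$\rho_0 c_{p0} \Delta T/\tau_{s\ell}$ puts the factor
$1/(\tilde c_p\,Ste_1)$ in front of the *whole* bracket (since
$R T/(c_{p0}\Delta T) = (Ste_2/Ste_1)(\tilde T + T_0/\Delta T)$); freezing
fronts heat up, which is the self-regulation at the heart of the dynamics.

**Flow.** The fluid is quasi-incompressible: density change upon freezing
prescribes the divergence (blowing flux),
$\tilde\nabla\cdot\tilde{\mathbf v} = -\frac{1}{Pe\,\tilde\rho}
\frac{\partial\tilde\rho}{\partial\phi_{s\ell}} \frac{D\phi_{s\ell}}{D\tilde t}$,
and the solenoidal remainder obeys low-Reynolds-number momentum balance
with variable viscosity (crystals are a $10^4\times$ more viscous fluid, so
rigidity and no-slip are emergent), buoyancy $-Gr(1-\tilde\rho)\hat e_g$,
and the unsteady term $\frac{1}{Sc}\partial_{\tilde t}\tilde{\mathbf v}$
retained as an explicit relaxation; nonlinear inertia is dropped
($Re \approx 10^{-4}$). The velocity is updated by a Helmholtz split:
potential part from a Poisson solve for the prescribed divergence, one
relaxation step for the solenoidal part with the maximum viscosity treated
implicitly, then a pressure-Poisson projection. In the fully periodic box
the $k = 0$ mode of the momentum forcing is removed (zero-net-momentum
gauge), the standard convention for periodic buoyant flow.

## Thermophysical correlations

Properties blend ice and supercooled-solution branches through $P$:
densities $\rho_\ell = \rho_0 - 0.017(T-T_0)^2$,
$\rho_s = 0.917\rho_0 + 0.15(T_0-T)$ (ice floats and blows mass off the
front); specific heats $c_{ps} = c_{p0} + 8(T-T_0)$,
$c_{p\ell} = 4180[1 - 0.953\phi_c(1-0.588\phi_c) + 10^{-3}(T-T_0)]$;
conductivities $k_{Ts} = k_{T0} + 0.013(T_0-T)$,
$k_{T\ell} = 0.58[1 - 0.905\phi_c(1-0.588\phi_c) + 2.6\times10^{-3}(T-T_0)]$;
Vogel–Fulcher–Tammann viscosity
$\eta_\ell(T) = 4.442\times10^{-5}\exp[2.288\cdot168.9/(T-168.9)]$ Pa s
times Mooney's concentration factor $\exp[6.3\phi_c/(1-0.85\phi_c)]$;
Stokes–Einstein diffusivity $\tilde D_\ell = T\eta_0/(T_0\eta_\ell)$ with
crystal floor $10^{-4}$. The temperature corrections of $c_{p\ell}$ and
$k_{T\ell}$ are taken *inside* the bracket (multiplying the prefactor):
outside it they would be numerically negligible, which would contradict the
temperature dependence these correlations are meant to carry.

Two reference conventions deserve note. $c_{p0} = 2110$ J/(kg K) and
$k_{T0} = 2.14$ W/(m K) are the *ice* values at $T_0$; they are the scaling
constants, because only with them do the tabulated groups
($Le = 4830.6$, $Ste_1 = 0.0621$) and the volumetric heat sink
$\rho_0 c_{p0}\beta_f \approx 2\times10^8$ J/(m$^3$ s) come out. The gas
constant is the *specific* gas constant of water, $R = 461.5$ J/(kg K)
(all intensive quantities are per unit mass), which reproduces
$Ste_2 = R\Delta T/L_a = 0.0136$. The viscous diffusion time is computed
from its formula $\rho_0 L^2/\eta_0 = 5.55\times10^{-5}$ s; the tabulated
$9.86\times10^{-5}$ s is consistent instead with the thermal time and is
treated as a transcription slip, because the tabulated $Re = 1.16\times
10^{-4}$ and $Gr = 25.92$ agree with the formula value.

## Numerics

Fourier pseudo-spectral discretization on $n \times n$ collocation points,
periodic boundaries; integer wavenumbers; the Nyquist mode is excluded from
first derivatives; all nonlinear products are dealiased by the 2/3 rule and
the state spectra are kept band-limited. Time stepping is forward Euler at
a uniform scaled step $\tilde{dt} = 2\times10^{-4}$ with semi-implicit
treatment of the stiff linear parts: exact backward-Euler for the
constant-coefficient $Ch^2\tilde\nabla^2\phi_{s\ell}$; for the solute and
thermal equations the increment is filtered by
$(1 + dt(c_2 k^2 + c_4 k^4))^{-1}$ with $c_2, c_4$ the domain maxima of the
variable transport coefficients (max-coefficient stabilization), which is
unconditionally stable and mean-preserving ($k=0$ passes unchanged).

### Choices made where the design was open

* **Clamping of $P$ beyond the wells.** $P$, $P'$ (and hence $\chi$,
  $\chi'$) are evaluated on $\phi_{s\ell}$ clamped to $[-1, 1]$. Evaluating
  the polynomial tail beyond the wells looks harmless but re-activates the
  $O(\Lambda_{s\ell})$ driving force in the bulk, where it amplifies
  spectral ringing faster than the cubic well can restore it; the clamped
  continuation is $C^1$ and keeps the pure phases exact fixed points.
* **Sub-grid stabilization at coarse resolution.** Linearizing the phase
  equation on an interface flank gives a local growth rate of order
  $\Lambda_{s\ell}\max|P''|\,|\tilde T - \tilde T_{eq}| = O(10^2)$. At full
  resolution this is held by interfacial diffusion ($Ch^2 k^2 \approx 2800$
  at the cutoff of a 1600-point grid), but a coarse grid retains only modes
  with $Ch^2 k^2 \lesssim 20$, so short waves in narrowing liquid gaps can
  grow without bound. `advance()` therefore adds a small fourth-order
  spectral stabilization $\nu_4 k^4$, implicit, sized adaptively each step
  to the instantaneous worst-case driving rate:
  $\nu_4 = \sigma/k_c^4$ with
  $\sigma = 1.45\,\Lambda_{s\ell}\max\big[(1-\phi_c)|\tilde T - \tilde
  T_{eq}|/\text{corr}\big]$ (1.45 is $\max|P''|$) and $k_c = n/3$. At the
  cutoff it supplies damping of the order of the destabilizing rate, at
  the scales that carry the front it is a small correction, it vanishes
  identically at thermodynamic equilibrium (so equilibrium-interface
  benchmarks see the unmodified model), and it vanishes as resolution
  grows. It is a regularization of the truncated system, not part of the
  model.
* **Limiters for film closure.** The equilibrium interstitial film between
  stalling crystals has the width of the interface itself ($\approx 0.14$
  scaled, $<3$ cells at $128^2$), so the closure of the last liquid
  pockets is a sub-grid singular event on coarse grids and the oscillation
  around it can run away. The stepper clamps phase-field excursions beyond
  $\pm1.15$ and clamps solute ringing to $[-0.05, 0.95]$ with the clipped
  mass restored uniformly, so the solute budget stays exactly conserved.
  The limiters fire only during film closure; resolved runs never reach
  them.
* **Seed geometry.** Seed coordinates of the reference scenarios are not
  published. The 5-seed base case uses a quincunx (quarter points plus
  centre); the 25-seed case places 15 seeds on the left half and 10 on the
  right, matching the stated left-biased seeding density. The default seed
  radius is $3\,Ch$ — resolvable yet small against the domain.
* **Velocity at $t = 0$** is zero, and the velocity field responds to the
  front motion of the previous step (the blowing source needs
  $D\phi_{s\ell}/D\tilde t$, which is not yet available within the first
  half of a step).
* **$\xi_c$.** The solute gradient coefficient is never given numerically;
  the printed coefficient $Ch^2 h_{s\ell}/R$ of the fourth-order solute
  term implies $\xi_c^2 = \rho_0 h_{s\ell} W_{s\ell}^2$, i.e. equal to
  $\xi_{s\ell}^2$. Adopted.
* **$\phi_c$ clipping.** Before the mobility, double-well and Mooney terms
  are formed, $\phi_c$ is clipped to $[10^{-6}, 1-10^{-6}]$ so spectral
  ringing cannot produce negative mobilities. Correlation-range violations
  (T outside 230–280 K) warn rather than stop: the correlations are
  extrapolations in the deeply supercooled regime anyway.

## What the scenario generator emulates — and what it does not

`fig_base_scenario()` (and `run_config()` defaults) encode the reference
conditions: five prescribed seeds, $\phi_c = 0.05$ in the liquid and 0 in
the seeds, uniform onset supercooling $\tilde T = -1$, cooling at 100 K/s,
$\tilde{dt} = 2\times10^{-4}$, run to $\tilde t = 2.5$. Nucleation
kinetics, anisotropic interfacial energy (dendrites), elasticity and
thermal stress in the crystal, solute crystallization, protein–ice
adsorption, and 3-D effects are all outside the model. Passing tests on
these scenarios therefore validate the transport/phase-transition coupling
and its numerics, not those excluded mechanisms.

Two quantitative caveats on scaled-down runs. First, the phase field
overshoots $\pm1$ near interfaces by an amount that shrinks with
resolution (about $\pm0.02$ at $256^2$ in 1-D front tests, $\pm0.06$ at
$128^2$); bounds like "overshoot $< 0.05$" are resolution statements, met
at fine grids. Second, with $Le \approx 4800$ the domain is nearly
isothermal: temperature self-regulates to sit just below the liquidus at
the level where cooling extracts exactly the latent heat of the growing
crystals, so the spatial temperature *range* at any instant is small
(order $10^{-2}$ in $\tilde T$). A spatially wide instantaneous
temperature spread would require thermal diffusion orders of magnitude
slower than these parameters imply; see the test suite, which asserts the
self-regulating near-isothermal behaviour rather than a wide spread.

Near-isothermal growth has a hard energetic consequence: the latent heat
of freezing the whole domain is $1/Ste_1 \approx 16$ scaled temperature
units while cooling removes $4.76$ per unit time, so by $\tilde t = 2.5$
roughly $85$–$90\%$ of the domain must have frozen. Conservation then
forces the *liquid-average* solute fraction up to $\approx 0.45$, and the
domain peak in the last pockets well above that. A simulation that stores
part of the extracted heat as sensible cold in far-from-front regions
(slow effective thermal transport) freezes less by the same time and caps
the peak concentration much lower; with the parameters as given, the
near-isothermal branch is the self-consistent one, and the reported peak
concentrations should be read in that light.

## Problem sizes used by the tests

Unit and property tests run on $64^2$ grids with short horizons; the
planar-front benchmark uses $128^2$ (fields uniform along one axis); the
full base scenario runs once at $128^2$ to $\tilde t = 2.5$ in the
acceptance suite. These sizes were chosen as the smallest that resolve the
feature each test probes (interface width, film width) — the model itself
is grid-size agnostic.

## Known limitations

* Quantitative observables of the confinement stage (peak $\phi_c$,
  coalescence timing) remain resolution-sensitive at $128^2$; expect
  differences of order tens of percent against fully resolved runs.
* The solenoidal flow is under-relaxed by the maximum-viscosity implicit
  splitting (the crystal/liquid viscosity contrast is $10^4$), so buoyant
  drift develops on a slower numerical clock than a true variable-viscosity
  Stokes solve; its sign and structure are correct, magnitudes are
  qualitative.
* The uniform heat sink stands in for real container-scale heat transfer;
  directional cooling is not modelled.
* Properties are sucrose correlations; protein-specific diffusivity models
  would replace the Stokes–Einstein/Mooney composition when data exist.
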