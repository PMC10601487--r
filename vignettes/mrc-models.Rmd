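---
title: "Multistate harmonic and reaction-coordinate model Hamiltonians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate harmonic and reaction-coordinate model Hamiltonians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrckit)
```

## The modelling problem

Photoinduced charge transfer (CT) and excitation energy transfer (EET) in
condensed phases — an organic photovoltaic triad in solvent, or the
bacteriochlorophyll sites of the Fenna–Matthews–Olson (FMO)
pigment–protein complex — involve nonadiabatic transitions among $F$
electronic states coupled to a macroscopic nuclear environment.  A
practical route to simulating such dynamics is an effective harmonic
model whose parameters are condensed from all-atom simulation: for each
pair of states $(X,Y)$ the equilibrium energy-gap fluctuations define a
reorganization energy $E_r^{(XY)}$ and a spectral density $J(\omega)$.

With $F$ states there are $F(F-1)/2$ pairwise reorganization energies —
more restrictions than states — so a shared bath of one-dimensional
shifted oscillators cannot satisfy them all.  The multistate harmonic
(MSH) construction resolves this by giving every normal mode $F-1$
spatial dimensions: the PES minima of the $F$ states become the vertices
of a polyhedron in $F-1$ dimensions whose squared edge lengths are the
$E_r^{(XY)}$.  The multistate reaction-coordinate (MRC) model is the
exact re-expression of the same Hamiltonian in which a single collective
coordinate per subspace (the reaction coordinate) carries the entire
electronic–nuclear coupling and is bilinearly coupled to $N-1$ residual
secondary modes.  This package constructs both forms, proves their
numerical equivalence trajectory by trajectory, and propagates
semiclassical nonadiabatic dynamics on either.

## Spectral densities, gap correlation functions, and conventions

All internal quantities are in Hartree atomic units ($\hbar = 1$,
mass-weighted coordinates); readers and fixtures accept cm$^{-1}$, eV,
kcal/mol, K and fs.

For a classical energy-gap autocorrelation $C(t)$ at inverse temperature
$\beta$ the package uses one mutually consistent convention set,
centralized in `R/spectral.R`:

$$E_r = \tfrac{\beta}{2} C(0), \qquad
  J(\omega) = \beta\,\omega \int_0^\infty C(t)\cos\omega t\, dt, \qquad
  C(t) = \frac{2}{\pi\beta}\int_0^\infty \frac{J(\omega)}{\omega}
         \cos\omega t\, d\omega, \qquad
  E_r = \frac{1}{\pi}\int_0^\infty \frac{J(\omega)}{\omega}\,d\omega .$$

These four relations close exactly (classically
$\langle\delta U^2\rangle = 2 E_r k_B T$), so the
TCF$\to$density$\to$TCF round trip and `reorg_from_tcf()` are consistent
to quadrature error; under them the Debye density
$J = 2\lambda\omega\omega_c/(\omega^2+\omega_c^2)$ carries $E_r=\lambda$
and the Ohmic density $J = \eta\omega e^{-\omega/\omega_c}$ carries
$E_r = \eta\omega_c/\pi$.  Conventions for these transforms differ by
factors of two across the literature; the forward/inverse prefactors are
single constants so an alternative convention is a one-line change.

`discretize_bath()` maps a density onto $N$ modes carrying equal
reorganization shares: frequencies solve
$F(\omega_j) = \frac{j-1/2}{N} F(\infty)$ with
$F(\omega)=\int_0^\omega J/\omega'\,d\omega'$ (midpoint fractions; a
$j/(N{+}1)$ alternative is exposed), displacements are
$R_j^{\rm eq} = \sqrt{2E_r/N}/\omega_j$.  Analytic kinds invert $F$ in
closed form; tabulated densities use monotone piecewise-cubic
interpolation with zero extrapolation (warned).  Noisy, truncated MD
correlation functions can be damped with an optional $e^{-t/\tau}$
window before transforming; because published work rarely states the
window used, $\tau$ is left configurable and off by default.

## Embedding the reorganization matrix

`embed_polyhedron()` anchors state 1 at the origin and factorizes the
Gram matrix $G_{XY} = (E_r^{(1X)} + E_r^{(1Y)} - E_r^{(XY)})/2$
($X,Y\ge2$) into a lower-triangular vertex array with positive diagonal:
vertex $X$ occupies only its first $X-1$ coordinates, matching the
convention that shift components $S^{(i,X)}$ vanish for $i \ge X$.
Anchoring is a gauge: reordering states changes coordinates but not
distances (tested).

Real matrices need not embed.  Each $E_r^{(XY)}$ is estimated from its
own simulation, and nothing forces the collection to be
Euclidean-consistent; the packaged triad parameter sets indeed violate
the triangle inequality on $\sqrt{E_r}$ in their CT/ground rows, so
their Gram matrices are indefinite at the $-15\%$ level.  The package
refuses such input by default (naming the offending eigenvalue and the
violated inequalities) rather than projecting silently; an explicit
`on_defect = "clip"` performs the sequential clamped Cholesky — the
classic distance-geometry treatment — which preserves all distances in
the leading consistent block exactly and reports the residual deviation
of the remainder.  `triad_model()` uses this mode deliberately and says
so.  Eigenvalues within $-10^{-8}$ (relative) of zero are ordinary
round-off and are clipped with a warning in either mode.

## MSH assembly

Given a bath $\{\omega_j\}$, vertices $\{d_X\}$ and electronic
parameters $(\epsilon_X, \Gamma_{XY})$, the state-$X$ surface is

$$V_X(R) = \epsilon_X + \sum_{i=1}^{F-1}\sum_{j=1}^{N}
  \tfrac12\omega_j^2\big(R_{j,i} + S_j^{(i,X)}\big)^2, \qquad
  S_j^{(i,X)} = \sqrt{2/N}\; d_X[i]/\omega_j,$$

so every mode carries the share $E_r^{(XY)}/N$ of every pairwise
reorganization energy and the total nuclear dimension is $(F-1)N$.  The
sign convention places the state-$X$ minimum at $-S^{(X)}$; flipping it
negates the vertex coordinates with no physical consequence.  Couplings
are constants (Condon approximation); a designated ground state can have
its couplings forced to zero.  `reaction_free_energy()` implements the
linear-response estimate $\Delta E = \langle U\rangle_X - E_r$; because
the sign of the gap $U$ is convention-laden, the direction
(acceptor$-$donor by default) is an explicit flag rather than a silent
assumption.

The isolated-bath (Frenkel-type) comparison model in
`build_frenkel_model()` is realized as the same machinery with $F$
orthogonal vertices $\sqrt{E_r^{(Xg)}}\,e_X$ on per-site baths: its
excited–excited reorganization energies are forced to the additive value
$E_r^{(Xg)}+E_r^{(Yg)}$, which is precisely the restriction set the
shared-bath model lifts.

## The exact transformation to reaction-coordinate form

Within one subspace, the state dependence of $V_X$ is linear with
coefficient vector $\propto a$, $a_j = \omega_j^2R_j^{\rm eq}/\kappa$,
$\kappa = (\sum_j \omega_j^4 (R_j^{\rm eq})^2)^{1/2}$.  A Householder
reflection $P = I - 2uu^T/u^Tu$, $u = e_1 - a$, maps $e_1$ onto $a$;
in the reflected frame the Hessian $K = P^T\Lambda P$ has the reaction
coordinate in its first row, and diagonalizing the trailing
$(N-1)\times(N-1)$ block yields secondary frequencies $\omega_\alpha$
and couplings $c_\alpha = (U^Td)_\alpha$ with $d = K_{2:N,1}$.  The
potential is kept in completed-square Caldeira–Leggett form

$$V_X = \epsilon_X + \sum_i\Big[\tfrac12\Omega^2\big(y_i + S^{(i,X)}\big)^2
 + \sum_\alpha \tfrac12\omega_\alpha^2
   \Big(x_{i\alpha} + \tfrac{c_\alpha}{\omega_\alpha^2}y_i\Big)^2\Big],
 \qquad S^{(i,X)} = \sqrt2\, d_X[i]/\Omega,$$

which settles two conventions at once: the counterterm (the
quadratic-in-$y$ completion) lives inside the squared bath displacement,
so the bare $y$ curvature is exactly $K_{11}$, and the primary frequency

$$\Omega^2 \;=\; \frac{\sum_j\omega_j^4 (R_j^{\rm eq})^2}
                     {\sum_j\omega_j^2 (R_j^{\rm eq})^2}
          \;=\; K_{11} - d^T K_{\rm sub}^{-1} d$$

is the Schur complement of the reflected Hessian — the curvature felt by
the reaction coordinate after adiabatic secondary-bath relaxation.
Under equal-share discretization $\Omega$ reduces to the root-mean-square
normal-mode frequency.  With these choices `mrc_potential()` equals
`msh_potential()` under the orthogonal coordinate map to $10^{-10}$ a.u.
on random phase-space points, every pairwise $E_r$ recomputed from MRC
minima matches the input to $10^{-8}$ relative, and the trace identity
holds as $K_{11} + \sum_\alpha\omega_\alpha^2 = \sum_j\omega_j^2$ (note
the counterterm: $\Omega^2$ alone under-counts by
$\sum_\alpha c_\alpha^2/\omega_\alpha^2$).

Eigenvector signs are fixed (largest component positive) so repeated
runs are bit-identical; the same basis matrix is replicated across the
$F-1$ subspaces, and the secondary parameters depend on the bath only —
not on the states — which is what qualifies $y$ as a reaction
coordinate.

### Numerical choice: arrowhead secular solver

The reverse map diagonalizes the per-subspace arrowhead Hessian built
from $(K_{11}, c_\alpha, \omega_\alpha)$.  A dense symmetric eigensolver
guarantees only absolute accuracy at the norm scale, which destroys the
relative accuracy of the softest modes when the spectrum spans many
decades; `mrc_normal_modes()` instead bisects the secular equation
$f(\lambda) = K_{11} - \lambda - \sum_\alpha
c_\alpha^2/(\omega_\alpha^2-\lambda)$ on each interlacing interval,
which is exact to the stored parameters.  The residual round-trip error
on the softest eigenvalue is then set by the last bit of $K_{11}$
itself, of order $\mathrm{ulp}(K_{11})/\omega_{\min}^2$ — a
representation limit of any double-precision parameter set, relevant
only for extremely broad (e.g. long-tailed Debye) baths.  $K_{11}$ as
formed during the forward transform is cached on the model so it is
never re-derived through a cancellation.

## Semiclassical dynamics

Both representations expose the same propagator: velocity-Verlet nuclei
with the density-matrix-weighted diabatic force, and electronic mapping
variables $c_X = (q_X + i p_X)/\sqrt2$ integrated by fourth-order
Runge–Kutta, 20 updates per nuclear step by default, on the diabatic
matrix linearly interpolated across the step.  The trace of the diabatic
matrix (a global phase) is removed before electronic propagation: all
estimators are phase-invariant and the integrator then resolves the gap
scale rather than the absolute bath-potential scale, which keeps
$\sum_X|c_X|^2$ conserved to $\sim10^{-11}$/ps.  Default nuclear steps
are 0.1 fs for triad-scale models and 1 fs for FMO-scale ones.

Initial nuclear conditions are Wigner samples of the harmonic thermal
state — per-mode Gaussians with variances
$\coth(\beta\omega/2)/2\omega$ (position) and
$(\omega/2)\coth(\beta\omega/2)$ (momentum) — centered at a chosen PES
minimum or at an explicit reaction-coordinate-space center (the
convenient way to prepare nonequilibrium initial states).  Sampling
always happens in the normal-mode basis; MRC-basis runs map the samples
through the orthogonal basis matrix so both representations see the same
physical ensemble.

* **Mean field (Ehrenfest):** $c$ starts in a pure state; populations
  are $\langle|c_X|^2\rangle$; the force weight is $|c_X|^2$.
* **SQC (triangle window):** the published description of the windowing
  scheme leaves details open, so this package's convention is stated
  explicitly rather than claimed to match any reference code: actions
  $n_X = |c_X|^2 - \gamma$ with zero-point parameter $\gamma = 1/3$
  (configurable); initial sampling places $(n_i - 1, \{n_{k\neq i}\})$
  uniformly on the $F$-simplex with uniform phases; a trajectory is
  binned to state $i$ when $n_i \ge 1$, $n_{k\neq i} \ge 0$ and
  $\sum_k n_k \le 2$; populations are renormalized window counts.  The
  force weight is $n_X$.

Per-trajectory seeds are derived from the master seed by a counter
scheme, so trajectory $k$ is reproducible regardless of ensemble size.
Total energy is recorded as a diagnostic; on a triad-scale model with a
bath resolved by the time step it is conserved to $\sim2\times10^{-6}$
hartree over 1 ps at 0.1 fs, improving $\propto dt^2$.

### What the equivalence check does and does not show

`equivalence_report()` draws one shared seeded ensemble, maps it, runs
both representations, and counts matching significant figures of the
population estimators at every output step (assessed on the unit
population scale, since populations are order-one simplex variables;
grading a near-zero population by its own relative error would test a
different, much stronger statement).  Agreement starts at machine
precision and decays as trajectory chaos amplifies per-step round-off
differences between the two (exactly equivalent) arithmetic paths; the
decay rate is a property of the model, with stiff high-frequency modes
both carrying the largest coupling weights and amplifying fastest.  With
the long-tailed synthetic Debye bath used in the tests the agreement is
11–14 digits over the first tens of steps and 3–5 digits at 1 ps;
physical baths with bounded spectra retain more digits for longer.  The
check demonstrates representation equivalence, not method accuracy — no
claim about the quality of mean-field or SQC dynamics is made or tested
beyond closed-form limits (frozen populations at zero coupling, two-level
Rabi oscillation, classical harmonic motion of uncoupled nuclei).

## The synthetic generators and the packaged fixtures

`random_reorg_matrix()` draws $F$ Gaussian points in $F-1$ dimensions
(scale 0.04–0.05 $\sqrt{\rm hartree}$ by default, giving pairwise
energies of a few kcal/mol as in solvated CT systems) and returns their
squared distances — embeddable by construction with zero Gram defect.
`synthetic_model()` adds a Debye bath with $\omega_c = 200$ cm$^{-1}$
(typical intermolecular solvent time scale), minima uniform in
$[-1,0]$ eV and couplings uniform in $[-0.02,0.02]$ eV with a decoupled
ground state.  `synthetic_gap_tcf()` inverts the spectral-density
transform (closed forms for Ohmic/Debye) so statistical round trips
close by construction.  What these emulate is the *structure* of
condensed-phase parameter sets: Gaussian gap statistics, equal-share
discretization, Condon couplings.  What they do not emulate: mutually
inconsistent reorganization estimates (present in the real triad data),
non-Condon couplings, anharmonicity, static-disorder ensembles — so
green tests certify the mathematics of the construction, not fidelity to
any particular molecule.

`triad_fixture()` packages the published four-state
carotenoid–porphyrin–C$_{60}$ parameter sets (two conformations: energy
minima and couplings in eV, reorganization energies in kcal/mol,
excitation-energy corrections carried as metadata only), with zero
ground-state couplings.  The parameterizing spectral densities were not
published, so `triad_model()` attaches a synthetic Debye bath — labelled
as such — with $\lambda$ set to the mean pairwise reorganization energy.
FMO-scale inputs (7/8 sites, $N = 100$) are supported by the same code
paths but their published mode sets are supplementary data not shipped
here.

## Problem sizes and limitations

The test-suite simulations are deliberately desk-scale: single
trajectories or ensembles of $10^2$–$10^3$ on models with 8–200 modes,
with convergence of SQC population curves checked against jackknife
error bands across seeded sub-ensembles.  Published-figure-scale
ensembles ($10^5$–$10^6$ trajectories) are out of scope.  Known
limitations, all discussed above in context: clamped embedding alters
the inconsistent entries of non-Euclidean input matrices; per-eigenvalue
relative round-trip accuracy is bounded by the double-precision
representation of the MRC parameters for baths spanning $\gtrsim8$
decades; equivalence digit counts at long times degrade fastest for
stiff synthetic baths; `mrc_to_msh()` requires equal-share structure (a
generic reaction-coordinate model — e.g. a two-state model with an
independently chosen Ohmic secondary bath — has no equal-share MSH
container and is rejected with an informative error, though its normal
modes are still available through `mrc_normal_modes()` and
`state_minimum()`).
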