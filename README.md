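# mrckit

Model Hamiltonians for nonadiabatic charge and energy transfer in the
condensed phase: **multistate harmonic (MSH)** models built from pairwise
reorganization energies and a discretized spectral density, their exact
transformation into **multistate reaction-coordinate (MRC)** form, and
semiclassical mapping dynamics (Ehrenfest mean field and symmetrical
quasi-classical triangle-window, SQC) on either representation.

It is written for people who parameterize effective Hamiltonians from
all-atom simulation — of systems such as a carotenoid–porphyrin–C₆₀
(CPC₆₀) charge-transfer triad in solvent or the Fenna–Matthews–Olson
light-harvesting complex — and want a reaction-coordinate picture of the
resulting dynamics without any loss of exactness.

## The model

An *F*-state system has *F*(*F*−1)/2 pairwise reorganization energies
*E*ᵣ⁽ˣʸ⁾ — more restrictions than states — so each of the *N* bath normal
modes is given *F*−1 spatial dimensions.  The state minima then sit at the
vertices *d_X* of a polyhedron whose squared edge lengths are the
*E*ᵣ⁽ˣʸ⁾ (recovered here by a lower-triangular Gram-matrix embedding), and
the state-*X* surface is

    V_X(R) = ε_X + Σ_{i,j} ½ ω_j² (R_{j,i} + S_j^{(i,X)})²,
    S_j^{(i,X)} = √(2/N) d_X[i] / ω_j .

A Householder reflection maps each *N*-mode subspace onto one primary
reaction coordinate *y* plus *N*−1 secondary modes; diagonalizing the
reflected sub-Hessian gives secondary frequencies ω_α and bilinear
couplings c_α, and the exact equivalent potential in
Caldeira–Leggett form is

    V_X = ε_X + Σ_i [ ½ Ω² (y_i + √2 d_X[i]/Ω)²
                      + Σ_α ½ ω_α² (x_{iα} + (c_α/ω_α²) y_i)² ],

with the primary frequency Ω² = Σω_j⁴(R_j^eq)² / Σω_j²(R_j^eq)² — the
Schur complement of the reflected Hessian, equal to the root-mean-square
normal-mode frequency under equal-reorganization discretization.  The
entire electronic–nuclear coupling rides on *y*; the secondary bath is a
property of the spectral density alone.  Both directions of the transform
and the coordinate map between representations are provided, and the two
Hamiltonians propagate identically trajectory-for-trajectory up to
floating-point round-off.

See `vignette("mrc-models")` for conventions (TCF ↔ spectral-density
transforms, counterterm, triangle-window scheme), numerical choices and
limitations.

## Worked example

Build the packaged triad conformation-3 model on a synthetic Debye bath
(the published parameterization's own spectral densities are not public),
transform it, and check representation equivalence on a shared seeded
trajectory:

```r
library(mrckit)
m  <- triad_model("conf3", n_modes = 200)
m
#> Multistate harmonic (MSH) model
#>   states          : 4 (pipi*, CT1, CT2, G)
#>   normal modes    : N = 200 per subspace, 3 subspaces
#>   nuclear DOF     : 600
#>   bath E_r scale  : 11.8977 kcal/mol

mr <- msh_to_mrc(m)
cfg <- sim_config(method = "sqc", dt = 0.1, n_steps = 50, n_traj = 1,
                  seed = 1, init_state = 1, init_nuclear = 4)
equivalence_report(m, cfg, mrc = mr)
#> MSH / MRC representation equivalence (SQC)
#>   min matching significant figures, first 50 steps : 13
#>   matching significant figures at t = 5 fs        : 13
```

The 600 nuclear degrees of freedom are (F−1)·N = 3·200; the two
representations agree to 13 significant figures over the first 50 steps —
the transformation is exact and only double-precision round-off
separates them.  A small SQC ensemble after vertical excitation to the
ππ\* state (nuclei in thermal equilibrium with the ground surface):

```r
tr <- sqc_propagate(m, dt = 0.1, n_steps = 1000, n_traj = 200, seed = 7,
                    init_state = 1, init_nuclear = 4, substeps = 5)
tr
#> Population trace: SQC, 200 trajectories, 1001 output times (0..100 fs)
#>   final populations:
#> pipi*   CT1   CT2     G
#> 0.875 0.075 0.050 0.000
rc_trajectory_average(tr)[1001, ]
#>      time_fs      y1      y2      y3
#> 1001     100 -1.8271 -0.9724  0.0311
```

After 100 fs about 12% of the population has transferred to the two CT
states, and the ensemble-averaged reaction coordinate has drifted from
the ground-state geometry toward the CT minima — the nuclear-electronic
feedback the reaction-coordinate picture makes directly visible.

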