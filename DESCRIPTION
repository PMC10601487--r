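Package: mrckit
Title: Multistate Harmonic and Reaction-Coordinate Model Hamiltonians for
    Charge and Energy Transfer Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs multistate harmonic (MSH) model Hamiltonians from
    pairwise reorganization energies, electronic couplings and a harmonic
    bath discretized from an Ohmic, Debye or tabulated spectral density;
    transforms them exactly into multistate reaction-coordinate (MRC) form
    with one primary mode per nuclear subspace bilinearly coupled to
    secondary bath modes, via a Householder reflection and sub-Hessian
    diagonalization; and propagates semiclassical nonadiabatic dynamics
    (Ehrenfest mean-field and symmetrical quasi-classical triangle-window
    mapping) on either representation with Wigner-sampled initial
    conditions, producing electronic populations, coherences and averaged
    reaction-coordinate trajectories.  Includes energy-gap time-correlation
    processing, distance-geometry embedding of reorganization-energy
    matrices, synthetic fixture generators, model serialization and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
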