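## Shared fixture builders: everything is generated in code at test time.

## bath container with hand-picked frequencies (equal-share structure)
make_bath <- function(omegas, er = 0.01) {
  N <- length(omegas)
  req <- sqrt(2 * er / N) / omegas
  structure(list(n_modes = N, omegas = omegas, er = er, req = req,
                 couplings = omegas^2 * req / 2),
            class = "discretized_bath")
}

make_vertices <- function(coords) {
  structure(list(coords = as.matrix(coords), f_states = nrow(coords)),
            class = "polyhedron_vertices")
}

## two-state spin-boson-like MSH model with explicit reorganization energy
two_state_model <- function(er12 = 0.01, omegas = NULL, gamma = 0.001,
                            deps = -0.005, bath_er = 0.01) {
  if (is.null(omegas))
    omegas <- discretize_bath(spectral_density("debye", lambda = bath_er,
                                               omega_c = to_au(200, "cm-1")),
                              8)$omegas
  bath <- make_bath(omegas, bath_er)
  vert <- make_vertices(matrix(c(0, sqrt(er12)), 2, 1))
  el <- electronic_params(c(0, deps),
                          matrix(c(0, gamma, gamma, 0), 2, 2))
  msh_model(bath, vert, el)
}

## small seeded multistate fixture
tiny_model <- function(f = 3, n = 8, seed = 1, scale = 0.04)
  synthetic_model(f_states = f, n_modes = n, seed = seed, scale = scale)

## two-state GOA reaction-coordinate model: primary mode (Omega, carrying
## er) bilinearly coupled to an Ohmic-discretized secondary bath
goa_model <- function(er, Omega, eta, omega_c, n_modes) {
  lam_sec <- eta * omega_c / pi
  sec <- discretize_bath(spectral_density("ohmic", eta = eta,
                                          omega_c = omega_c),
                         n_modes - 1, er_total = lam_sec)
  c_alpha <- sec$omegas * sqrt(2 * lam_sec / (n_modes - 1))
  vert <- make_vertices(matrix(c(0, sqrt(er)), 2, 1))
  el <- electronic_params(c(0, 0), matrix(0, 2, 2))
  structure(list(f_states = 2, subspaces = 1, omega_rc = Omega,
                 bath_omegas = sec$omegas, bath_couplings = c_alpha,
                 primary_shifts = primary_shifts(vert, Omega),
                 basis_matrix = NULL, electronic = el, bath_er = er,
                 vertices = vert),
            class = "mrc_model")
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) /
                pmax(abs(expected), .Machine$double.xmin)), tol)
}
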