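## Multistate harmonic (MSH) model assembly: F electronic states on a
## shared discretized bath whose equilibrium positions, replicated into
## F-1 spatial subspaces per mode, form the embedded polyhedron.

#' Electronic parameters of a multistate model
#'
#' @param epsilons F energy minima (vertical PES offsets).
#' @param gammas symmetric F x F electronic coupling matrix with zero
#'   diagonal (Condon approximation: couplings are constants).
#' @param unit energy unit of both inputs.
#' @param labels optional state names.
#' @param ground optional index of a dynamics-irrelevant ground state whose
#'   couplings are forced to zero.
#' @return object of class `"electronic_params"`.
#' @export
electronic_params <- function(epsilons, gammas, unit = "au", labels = NULL,
                              ground = NULL) {
  f <- length(epsilons)
  gammas <- as.matrix(gammas)
  if (!all(dim(gammas) == f))
    stop("gammas must be F x F with F = length(epsilons)", call. = FALSE)
  if (max(abs(gammas - t(gammas))) > 1e-12 * max(1, max(abs(gammas))))
    stop("gammas must be symmetric", call. = FALSE)
  gammas <- (gammas + t(gammas)) / 2
  diag(gammas) <- 0
  if (!is.null(ground)) { gammas[ground, ] <- 0; gammas[, ground] <- 0 }
  if (is.null(labels)) labels <- paste0("S", seq_len(f))
  structure(list(f_states = f,
                 epsilons = to_au(as.numeric(epsilons), unit),
                 gammas = to_au(gammas, unit),
                 labels = labels),
            class = "electronic_params")
}

#' Build a multistate harmonic (MSH) model
#'
#' Assembles the F-state Hamiltonian on (F-1) x N uncoupled normal modes.
#' Every mode is replicated into F-1 spatial subspaces; the equilibrium
#' shift of state X along mode j in subspace i is
#' \eqn{S_j^{(i,X)} = \sqrt{2/N}\, d_X[i] / \omega_j}
#' (zero for i >= X), where d_X are the polyhedron vertex coordinates.
#' With this scaling each mode carries an equal share E_r^(XY)/N of every
#' pairwise reorganization energy.
#'
#' @param bath a [discretize_bath()] result (shared across subspaces).
#' @param vertices an [embed_polyhedron()] result, or a [reorg_matrix()]
#'   (embedded on the fly).
#' @param electronic an [electronic_params()] object.
#' @return object of class `"msh_model"`.
#' @examples
#' er <- random_reorg_matrix(3, scale = 0.05, seed = 1)
#' bath <- discretize_bath(spectral_density("debye", lambda = 0.01,
#'                                          omega_c = to_au(200, "cm-1")), 16)
#' el <- electronic_params(c(0, -0.01, -0.02), matrix(0.001, 3, 3) -
#'                         diag(0.001, 3))
#' m <- msh_model(bath, er, el)
#' @export
msh_model <- function(bath, vertices, electronic) {
  stopifnot(inherits(bath, "discretized_bath"),
            inherits(electronic, "electronic_params"))
  if (inherits(vertices, "reorg_matrix")) vertices <- embed_polyhedron(vertices)
  stopifnot(inherits(vertices, "polyhedron_vertices"))
  f <- vertices$f_states
  if (electronic$f_states != f)
    stop("electronic parameters are for ", electronic$f_states,
         " states but the polyhedron has ", f, call. = FALSE)
  m <- list(f_states = f, n_modes = bath$n_modes, n_sub = f - 1,
            bath = bath, vertices = vertices, electronic = electronic)
  class(m) <- "msh_model"
  m
}

#' @export
print.msh_model <- function(x, ...) {
  cat("Multistate harmonic (MSH) model\n")
  cat(sprintf("  states          : %d (%s)\n", x$f_states,
              paste(x$electronic$labels, collapse = ", ")))
  cat(sprintf("  normal modes    : N = %d per subspace, %d subspaces\n",
              x$n_modes, x$n_sub))
  cat(sprintf("  nuclear DOF     : %d\n", n_dof(x)))
  cat(sprintf("  bath E_r scale  : %.4f kcal/mol\n",
              from_au(x$bath$er, "kcal/mol")))
  invisible(x)
}

#' Total nuclear degrees of freedom of a model
#' @param model an MSH, MRC or Frenkel model.
#' @return integer DOF count: (F-1)*N for MSH/MRC, F*N for Frenkel.
#' @export
n_dof <- function(model) UseMethod("n_dof")
#' @export
n_dof.msh_model <- function(model) model$n_sub * model$n_modes
#' @export
n_dof.mrc_model <- function(model) model$subspaces * (length(model$bath_omegas) + 1)
#' @export
n_dof.frenkel_model <- function(model) model$n_sub * model$n_modes

## Shift matrix S^(X): N x n_sub, S[j, i] = sqrt(2/N) d_X[i] / omega_j
.msh_shift <- function(model, state) {
  d <- model$vertices$coords[state, ]
  outer(sqrt(2 / model$n_modes) / model$bath$omegas, d)
}

#' Potential-minimum position of a state
#'
#' @param model an MSH or MRC model.
#' @param state state index.
#' @return coordinate matrix in the model's own basis (N x n_sub for MSH:
#'   rows are modes, columns subspaces; for MRC row 1 is the primary
#'   coordinate y and rows 2..N the secondary modes).
#' @export
state_minimum <- function(model, state) UseMethod("state_minimum")
#' @export
state_minimum.msh_model <- function(model, state) -.msh_shift(model, state)
#' @export
state_minimum.mrc_model <- function(model, state) {
  N <- length(model$bath_omegas) + 1
  out <- matrix(0, N, model$subspaces)
  sy <- model$primary_shifts[state, ]
  out[1, ] <- -sy
  out[-1, ] <- outer(model$bath_couplings / model$bath_omegas^2, sy)
  out
}

#' Diabatic potential energy of an MSH model
#'
#' \eqn{V_X(R) = \epsilon_X + \sum_{i,j} \tfrac12 \omega_j^2
#'   (R_{j,i} + S_j^{(i,X)})^2}.
#'
#' @param model an `"msh_model"`.
#' @param state state index X.
#' @param coords N x (F-1) matrix of mass-weighted normal-mode positions
#'   (rows modes, columns subspaces); a plain vector of length N*(F-1) is
#'   reshaped column-wise.
#' @return energy in a.u.
#' @export
msh_potential <- function(model, state, coords) {
  R <- .as_coords(model, coords)
  S <- .msh_shift(model, state)
  model$electronic$epsilons[state] +
    0.5 * sum(model$bath$omegas^2 * (R + S)^2)
}

#' Analytic gradient of [msh_potential()]
#' @inheritParams msh_potential
#' @return N x (F-1) gradient matrix.
#' @export
msh_gradient <- function(model, state, coords) {
  R <- .as_coords(model, coords)
  model$bath$omegas^2 * (R + .msh_shift(model, state))
}

.as_coords <- function(model, coords) {
  N <- if (inherits(model, "mrc_model")) length(model$bath_omegas) + 1
       else model$n_modes
  ns <- if (inherits(model, "mrc_model")) model$subspaces else model$n_sub
  if (is.matrix(coords)) {
    stopifnot(nrow(coords) == N, ncol(coords) == ns)
    coords
  } else {
    stopifnot(length(coords) == N * ns)
    matrix(coords, N, ns)
  }
}

#' Recompute the pairwise reorganization matrix of a model
#'
#' Evaluates \eqn{E_r^{(XY)} = V_Y(\min_X) - V_Y(\min_Y)} from the model's
#' own potential surfaces -- an internal consistency check against the
#' input matrix.
#'
#' @param model an MSH, MRC or Frenkel model.
#' @return F x F matrix in a.u.
#' @export
model_reorg_matrix <- function(model) {
  f <- model$f_states
  pot <- function(s, r) potential(model, s, r)
  out <- matrix(0, f, f)
  mins <- lapply(seq_len(f), function(s) state_minimum(model, s))
  eps <- model$electronic$epsilons
  for (x in seq_len(f)) for (y in seq_len(f)) if (x != y)
    out[x, y] <- pot(y, mins[[x]]) - eps[y]
  out
}

#' Diabatic potential (generic over model representations)
#' @param model a model object.
#' @param state state index.
#' @param coords coordinates in the model's basis.
#' @return energy in a.u.
#' @export
potential <- function(model, state, coords) UseMethod("potential")
#' @export
potential.msh_model <- function(model, state, coords)
  msh_potential(model, state, coords)
#' @export
potential.mrc_model <- function(model, state, coords)
  mrc_potential(model, state, coords)

#' Reaction free energy from gap statistics
#'
#' Linear-response estimate \eqn{\Delta E^{(XY)} = \langle U \rangle_X -
#' E_r^{(XY)}} where the average energy gap is sampled on the initial
#' (donor) state X.  With the default gap direction
#' `"acceptor_minus_donor"` (U = V_Y - V_X), the result is the minimum
#' offset epsilon_Y - epsilon_X; the opposite direction flag flips both
#' signs (Delta E = -<U> ... consistent with U = V_X - V_Y).
#'
#' @param gap_mean mean energy gap on the donor surface (a.u.).
#' @param er reorganization energy E_r^(XY) (a.u.).
#' @param gap_direction `"acceptor_minus_donor"` (default) or
#'   `"donor_minus_acceptor"`.
#' @return Delta E = epsilon_Y - epsilon_X in a.u.
#' @export
reaction_free_energy <- function(gap_mean, er,
                                 gap_direction = c("acceptor_minus_donor",
                                                   "donor_minus_acceptor")) {
  gap_direction <- match.arg(gap_direction)
  u <- if (gap_direction == "acceptor_minus_donor") gap_mean else -gap_mean
  u - er
}

#' Build an isolated-bath (Frenkel-exciton-like) comparison model
#'
#' Each excited site X couples only to its own bath; the model uses only
#' the F excited/ground reorganization energies.  The implied
#' excited--excited reorganization between sites X and Y is additive,
#' E_r^(Xg) + E_r^(Yg), which is what the shared-bath MSH model corrects.
#' Internally this is an MSH-type model with F subspaces whose vertices are
#' orthogonal: site X at sqrt(E_r^(Xg)) along axis X, ground state at the
#' origin.
#'
#' @param per_site_baths list of F [discretize_bath()] objects (one per
#'   site; `er` of bath a is E_r^(ag), zero for the ground state's entry).
#'   All baths must share the same mode count; frequencies may differ.
#' @param electronic an [electronic_params()]; the last state is taken as
#'   the shared ground state unless `ground` names another index.
#' @param ground index of the ground state (default F).
#' @return object of class `"frenkel_model"`.
#' @export
build_frenkel_model <- function(per_site_baths, electronic,
                                ground = electronic$f_states) {
  f <- electronic$f_states
  stopifnot(length(per_site_baths) == f)
  ns <- vapply(per_site_baths, function(b) b$n_modes, integer(1))
  if (length(unique(ns)) != 1)
    stop("all per-site baths must share the same mode count", call. = FALSE)
  ers <- vapply(per_site_baths, function(b) b$er, numeric(1))
  coords <- diag(sqrt(ers), f)
  coords[ground, ] <- 0
  omega_mat <- vapply(per_site_baths, function(b) b$omegas,
                      numeric(ns[1]))      # N x F, column a = bath of site a
  m <- list(f_states = f, n_modes = ns[1], n_sub = f, ground = ground,
            baths = per_site_baths, omega_mat = omega_mat,
            vertices = structure(list(coords = coords, f_states = f),
                                 class = "polyhedron_vertices"),
            electronic = electronic)
  class(m) <- "frenkel_model"
  m
}

.frenkel_shift <- function(model, state) {
  d <- model$vertices$coords[state, ]
  sweep(sqrt(2 / model$n_modes) / model$omega_mat, 2, d, `*`)
}

#' @export
state_minimum.frenkel_model <- function(model, state)
  -.frenkel_shift(model, state)

#' @export
potential.frenkel_model <- function(model, state, coords) {
  R <- if (is.matrix(coords)) coords else
    matrix(coords, model$n_modes, model$n_sub)
  S <- .frenkel_shift(model, state)
  model$electronic$epsilons[state] + 0.5 * sum(model$omega_mat^2 * (R + S)^2)
}

#' @export
print.frenkel_model <- function(x, ...) {
  cat("Isolated-bath (Frenkel) model:", x$f_states, "states,",
      x$n_modes, "modes per site,", n_dof(x), "nuclear DOF\n")
  invisible(x)
}
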