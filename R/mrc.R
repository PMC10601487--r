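## Exact MSH <-> MRC transformation.
##
## Route: the electronic-nuclear coupling of any state pair defines a
## collective direction a (the reaction coordinate) in each N-mode
## subspace; a Householder reflection maps the normal-mode basis onto
## (y, x_1..x_{N-1}); diagonalizing the trailing (N-1) block of the
## reflected Hessian yields uncoupled secondary modes bilinearly coupled
## to y.  Written in completed-square Caldeira-Leggett form, the primary
## frequency Omega is the Schur complement of the reflected Hessian and
## the entire state dependence sits in primary-mode shifts.

#' Primary reaction-coordinate mode of a discretized bath
#'
#' The reaction-coordinate direction has components
#' \eqn{a_j = \omega_j^2 R_j^{eq}/\kappa} with normalization
#' \eqn{\kappa = \sqrt{\sum_j \omega_j^4 (R_j^{eq})^2}}, and the primary
#' frequency satisfies
#' \eqn{\Omega^2 = \sum_j \omega_j^4 (R_j^{eq})^2 / \sum_j \omega_j^2
#' (R_j^{eq})^2}; under the equal-reorganization discretization this is the
#' arithmetic mean of \eqn{\omega_j^2}.
#'
#' @param bath a [discretize_bath()] object.
#' @return list with `Omega`, and the `frame` (class
#'   `"rc_frame"`: unit `direction` a and normalization `kappa`).
#' @export
primary_mode <- function(bath) {
  stopifnot(inherits(bath, "discretized_bath"))
  w2r <- bath$omegas^2 * bath$req
  if (all(w2r == 0))
    stop("all equilibrium displacements are zero: no reaction coordinate ",
         "is definable", call. = FALSE)
  kappa <- sqrt(sum(w2r^2))
  a <- w2r / kappa
  Omega <- sqrt(sum(bath$omegas^4 * bath$req^2) /
                sum(bath$omegas^2 * bath$req^2))
  list(Omega = Omega,
       frame = structure(list(direction = a, kappa = kappa),
                         class = "rc_frame"))
}

#' Householder reflector mapping e1 onto a unit vector
#'
#' \eqn{P = I - 2|u\rangle\langle u|/\langle u|u\rangle} with
#' \eqn{|u\rangle = |e_1\rangle - |a\rangle}; P is symmetric, involutory
#' (P^2 = I) and maps e1 to a.  If a is within 1e-12 of e1 the identity is
#' returned (degenerate reflector).
#'
#' @param a unit vector.
#' @return N x N orthogonal matrix.
#' @export
householder_reflector <- function(a) {
  n <- length(a)
  if (abs(sum(a^2) - 1) > 1e-10)
    stop("a must be a unit vector", call. = FALSE)
  if (abs(1 - a[1]) < 1e-12) return(diag(n))
  u <- -a; u[1] <- 1 + u[1]
  diag(n) - 2 * tcrossprod(u) / sum(u^2)
}

## Sign convention: first component of largest magnitude >= 0 in each
## eigenvector, making runs reproducible bit-for-bit.
.fix_eigvec_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Secondary bath modes by sub-Hessian diagonalization
#'
#' Forms the reflected Hessian \eqn{K = P^T \Lambda P} with
#' \eqn{\Lambda = diag(\omega_j^2)}, diagonalizes its trailing
#' (N-1) x (N-1) block into secondary frequencies \eqn{\omega_\alpha}
#' (ascending) and rotates the first column into the primary/secondary
#' couplings \eqn{c_\alpha = (U^T d)_\alpha}.  Also assembles the full
#' change-of-basis matrix \eqn{T = P\,blockdiag(1, U)} so that
#' \eqn{R = T (y, x)} and \eqn{T^T \Lambda T} is the arrowhead MRC Hessian.
#'
#' @param bath a [discretize_bath()] object.
#' @param frame the `"rc_frame"` from [primary_mode()].
#' @return list with `omega_alphas`, `c_alphas`, `U` ((N-1) x (N-1)),
#'   `basis_matrix` T (N x N) and `K11` (leading reflected-Hessian entry).
#' @export
secondary_bath <- function(bath, frame) {
  stopifnot(inherits(bath, "discretized_bath"), inherits(frame, "rc_frame"))
  N <- bath$n_modes
  if (N < 2)
    stop("secondary bath requires at least two normal modes", call. = FALSE)
  P <- householder_reflector(frame$direction)
  K <- crossprod(P, bath$omegas^2 * P)       # P^T Lambda P
  K <- (K + t(K)) / 2
  Ksub <- K[-1, -1, drop = FALSE]
  d <- K[-1, 1]
  eg <- eigen(Ksub, symmetric = TRUE)
  lam <- rev(eg$values)                      # ascending
  U <- .fix_eigvec_signs(eg$vectors[, rev(seq_len(N - 1)), drop = FALSE])
  if (any(lam < -1e-12 * max(abs(lam))))
    stop(sprintf("sub-Hessian has a negative eigenvalue %.3g", min(lam)),
         call. = FALSE)
  lam <- pmax(lam, 0)
  Tmat <- P %*% rbind(c(1, rep(0, N - 1)), cbind(0, U))
  list(omega_alphas = sqrt(lam), c_alphas = drop(crossprod(U, d)),
       U = U, basis_matrix = Tmat, K11 = K[1, 1])
}

#' Primary-mode equilibrium shifts from polyhedron vertices
#'
#' \eqn{S^{(i,X)} = \sqrt{2}\, d_X[i] / \Omega}: the full pairwise
#' reorganization energy is absorbed by the primary coordinate (after
#' secondary-bath relaxation in the completed-square potential).
#'
#' @param vertices an [embed_polyhedron()] result.
#' @param Omega primary frequency (a.u., > 0).
#' @return F x (F-1) shift matrix (zero for column i >= row X).
#' @export
primary_shifts <- function(vertices, Omega) {
  stopifnot(inherits(vertices, "polyhedron_vertices"), Omega > 0)
  sqrt(2) * vertices$coords / Omega
}

#' Transform an MSH model into its exact MRC form
#'
#' Composes [primary_mode()], [secondary_bath()] and [primary_shifts()];
#' the same orthogonal basis matrix is replicated in every nuclear
#' subspace (eigenvector sign flips are immaterial to the spectrum, so one
#' shared convention is used).
#'
#' @param model an `"msh_model"`.
#' @return object of class `"mrc_model"` with fields `omega_rc`,
#'   `bath_omegas`, `bath_couplings`, `primary_shifts`, `basis_matrix`,
#'   `electronic`, `subspaces`.
#' @export
msh_to_mrc <- function(model) {
  stopifnot(inherits(model, "msh_model"))
  pm <- primary_mode(model$bath)
  sb <- secondary_bath(model$bath, pm$frame)
  m <- list(f_states = model$f_states,
            subspaces = model$n_sub,
            omega_rc = pm$Omega,
            bath_omegas = sb$omega_alphas,
            bath_couplings = sb$c_alphas,
            primary_shifts = primary_shifts(model$vertices, pm$Omega),
            basis_matrix = sb$basis_matrix,
            k11 = sb$K11,
            electronic = model$electronic,
            bath_er = model$bath$er,
            vertices = model$vertices)
  class(m) <- "mrc_model"
  m
}

#' @export
print.mrc_model <- function(x, ...) {
  cat("Multistate reaction-coordinate (MRC) model\n")
  cat(sprintf("  states             : %d\n", x$f_states))
  cat(sprintf("  primary frequency  : Omega = %.6g a.u. (%.2f cm^-1)\n",
              x$omega_rc, from_au(x$omega_rc, "cm-1")))
  cat(sprintf("  secondary modes    : %d per subspace, %d subspaces\n",
              length(x$bath_omegas), x$subspaces))
  cat(sprintf("  nuclear DOF        : %d\n", n_dof(x)))
  invisible(x)
}

## Bare primary curvature K11 = Omega^2 + sum c^2/omega^2.  The value
## formed at transform time is cached on the model: re-forming it from the
## Schur-complement Omega involves a cancellation that costs the softest
## normal modes several digits of relative accuracy.
.mrc_k11 <- function(model) {
  if (!is.null(model$k11)) model$k11
  else model$omega_rc^2 + sum(model$bath_couplings^2 / model$bath_omegas^2)
}

## Arrowhead Hessian D of one MRC subspace (counterterm included):
## D[1,1] = K11, D[1,a+1] = c_a, D[a+1,a+1] = omega_a^2.
mrc_hessian <- function(model) {
  wa2 <- model$bath_omegas^2
  N <- length(wa2) + 1
  D <- diag(c(.mrc_k11(model), wa2))
  D[1, -1] <- model$bath_couplings
  D[-1, 1] <- model$bath_couplings
  D
}

#' Normal modes of an MRC subspace by the arrowhead secular equation
#'
#' The per-subspace MRC Hessian is an arrowhead matrix
#' (diag(omega_alpha^2) bordered by the couplings and the bare primary
#' curvature K11).  Its eigenvalues interlace the secondary omega_alpha^2
#' and are the roots of the secular function
#' \eqn{f(\lambda) = K_{11} - \lambda - \sum_\alpha
#' c_\alpha^2/(\omega_\alpha^2 - \lambda)}, which bisection solves to
#' near machine *relative* accuracy even when the spectrum spans many
#' orders of magnitude -- a dense symmetric eigensolver only guarantees
#' absolute accuracy at the norm scale, which loses the smallest modes.
#'
#' @param model an `"mrc_model"`.
#' @return list with `omegas` (N normal-mode frequencies, ascending) and
#'   `vectors` (orthonormal columns; column j is the mode-j eigenvector in
#'   the (y, x) basis, equal to the j-th row of the basis matrix up to
#'   sign).
#' @export
mrc_normal_modes <- function(model) {
  stopifnot(inherits(model, "mrc_model"))
  d <- model$bath_omegas^2
  cc <- model$bath_couplings
  K11 <- .mrc_k11(model)
  N <- length(d) + 1
  scale <- max(K11, d)
  live <- abs(cc) > .Machine$double.eps * sqrt(scale * pmax(d, scale * 1e-30))
  f <- function(l) K11 - l - sum(cc[live]^2 / (d[live] - l))
  bounds <- c(min(K11, d) - sum(abs(cc)) - scale, d[live],
              max(K11, d) + sum(abs(cc)) + scale)
  roots <- numeric(sum(live) + 1)
  for (k in seq_along(roots)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    ## f -> +inf at the left pole, -inf at the right: strictly decreasing
    for (it in 1:200) {
      mid <- lo / 2 + hi / 2
      if (mid <= lo || mid >= hi) break
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    roots[k] <- lo / 2 + hi / 2
  }
  lam <- sort(c(roots, d[!live]))
  if (any(lam <= 0))
    stop("reconstructed Hessian is not positive definite", call. = FALSE)
  V <- matrix(0, N, N)
  dead_idx <- which(!live)
  for (j in seq_len(N)) {
    l <- lam[j]
    gap <- d - l
    if (any(gap == 0)) {                 # exactly deflated mode
      v <- numeric(N); v[1 + which(gap == 0)[1]] <- 1
    } else {
      v <- c(1, -cc / gap)       # x_alpha = c_alpha/(lambda - d_alpha)
      v[1 + dead_idx] <- 0
      v <- v / sqrt(sum(v^2))
    }
    V[, j] <- v
  }
  list(omegas = sqrt(lam), vectors = V)
}

#' Transform an MRC model back to normal-mode (MSH) form
#'
#' Diagonalizes the per-subspace arrowhead Hessian built from
#' (Omega, omega_alpha, c_alpha) to recover the N normal-mode frequencies
#' and maps the state minima back to the normal-mode basis.  Only
#' equal-reorganization MRC models (the image of [msh_to_mrc()]) can be
#' expressed in the MSH container; anything else raises an error.
#'
#' @param model an `"mrc_model"`.
#' @param er optional total bath reorganization-energy scale for the
#'   reconstructed [discretize_bath()]; defaults to the value carried
#'   through [msh_to_mrc()] (or 1).
#' @return an `"msh_model"`.
#' @export
mrc_to_msh <- function(model, er = NULL) {
  stopifnot(inherits(model, "mrc_model"))
  if (is.null(er)) er <- if (!is.null(model$bath_er)) model$bath_er else 1
  nm <- mrc_normal_modes(model)
  omegas <- nm$omegas
  N <- length(omegas)
  Tm <- nm$vectors
  ## The state-X minimum in MRC coordinates is -S^(i,X) * (1, -c/omega^2);
  ## its normal-mode image is therefore S^(i,X) * v_ref with the
  ## state-independent vector v_ref below.  Equal-share MSH structure
  ## demands |v_ref_j| proportional to 1/omega_j with a common factor
  ## (which equals Omega/sqrt(2)); per-mode eigenvector signs are gauge.
  v_ref <- as.numeric(crossprod(Tm, c(1, -model$bath_couplings /
                                           model$bath_omegas^2)))
  scale <- sqrt(2 / N) / omegas
  q <- abs(v_ref) / scale
  if ((max(q) - min(q)) > 1e-8 * max(q))
    stop("MRC model does not have equal-reorganization structure; ",
         "cannot express it in the MSH container", call. = FALSE)
  coords <- model$primary_shifts * mean(q)
  f <- model$f_states
  bath <- structure(list(n_modes = N, omegas = omegas, er = er,
                         req = sqrt(2 * er / N) / omegas,
                         couplings = omegas^2 * (sqrt(2 * er / N) / omegas) / 2),
                    class = "discretized_bath")
  vert <- structure(list(coords = coords, f_states = f),
                    class = "polyhedron_vertices")
  msh_model(bath, vert, model$electronic)
}

#' Map coordinates/momenta between normal-mode and primary/secondary bases
#'
#' Applies the orthogonal basis matrix T per subspace: positions and
#' momenta transform identically, the map is norm-preserving and exactly
#' invertible.
#'
#' @param model an `"mrc_model"` (carries T).
#' @param coords N x n_sub matrix (or flat vector) in the source basis.
#' @return matrix in the target basis.
#' @export
coords_msh_to_mrc <- function(model, coords) {
  stopifnot(inherits(model, "mrc_model"))
  R <- .as_coords(model, coords)
  crossprod(model$basis_matrix, R)     # (y, x) = T^T R
}

#' @rdname coords_msh_to_mrc
#' @export
coords_mrc_to_msh <- function(model, coords) {
  stopifnot(inherits(model, "mrc_model"))
  Z <- .as_coords(model, coords)
  model$basis_matrix %*% Z             # R = T (y, x)
}

#' Diabatic potential energy of an MRC model
#'
#' Completed-square Caldeira-Leggett form, exactly equivalent to
#' [msh_potential()] under the coordinate map:
#' \deqn{V_X = \epsilon_X + \sum_i \Big[\tfrac12\Omega^2 (y_i +
#'   S^{(i,X)})^2 + \sum_\alpha \tfrac12 \omega_\alpha^2
#'   \big(x_{i\alpha} + \tfrac{c_\alpha}{\omega_\alpha^2} y_i\big)^2\Big].}
#' The counterterm (quadratic-in-y completion) is carried inside the
#' squared bath displacement, so the bare y-curvature equals the reflected
#' Hessian element K11 and Omega^2 is its Schur complement.
#'
#' @param model an `"mrc_model"`.
#' @param state state index X.
#' @param coords N x (F-1) matrix: row 1 the primary coordinates y_i,
#'   rows 2..N the secondary coordinates.
#' @return energy in a.u.
#' @export
mrc_potential <- function(model, state, coords) {
  Z <- .as_coords(model, coords)
  y <- Z[1, ]
  x <- Z[-1, , drop = FALSE]
  sy <- model$primary_shifts[state, ]
  disp <- x + outer(model$bath_couplings / model$bath_omegas^2, y)
  model$electronic$epsilons[state] +
    0.5 * model$omega_rc^2 * sum((y + sy)^2) +
    0.5 * sum(model$bath_omegas^2 * disp^2)
}

#' Analytic gradient of [mrc_potential()]
#' @inheritParams mrc_potential
#' @return N x (F-1) gradient matrix (row 1: d/dy_i).
#' @export
mrc_gradient <- function(model, state, coords) {
  Z <- .as_coords(model, coords)
  y <- Z[1, ]
  x <- Z[-1, , drop = FALSE]
  sy <- model$primary_shifts[state, ]
  cw <- model$bath_couplings
  disp <- x + outer(cw / model$bath_omegas^2, y)
  g <- matrix(0, nrow(Z), ncol(Z))
  g[1, ] <- model$omega_rc^2 * (y + sy) + colSums(cw * disp)
  g[-1, ] <- model$bath_omegas^2 * disp
  g
}
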