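## Synthetic inputs: embeddable reorganization matrices from random point
## clouds, gap TCFs consistent with a prescribed spectral density, and the
## packaged carotenoid-porphyrin-C60 triad parameter sets.

#' Random embeddable reorganization matrix
#'
#' Draws F points in F-1 dimensions from a zero-mean Gaussian and returns
#' their squared pairwise distances: embeddable by construction with zero
#' Gram defect.
#'
#' @param f_states number of states F (>= 2).
#' @param scale standard deviation of the point cloud in sqrt(hartree);
#'   typical pairwise reorganization energies are ~2(F-1) scale^2.
#' @param seed integer seed.
#' @param labels optional state names.
#' @return a [reorg_matrix()].
#' @export
random_reorg_matrix <- function(f_states, scale, seed = 1, labels = NULL) {
  stopifnot(f_states >= 2, scale >= 0)
  pts <- withr_seed(seed, matrix(stats::rnorm(f_states * (f_states - 1),
                                              sd = scale),
                                 f_states, f_states - 1))
  reorg_matrix(as.matrix(stats::dist(pts))^2, labels = labels)
}

## evaluate expr under a local RNG seed without clobbering the caller's RNG
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Synthetic energy-gap TCF from a spectral density
#'
#' Inverse cosine transform
#' \eqn{C(t) = \frac{2}{\pi\beta}\int_0^\infty \frac{J(\omega)}{\omega}
#' \cos(\omega t)\, d\omega}, evaluated by trapezoid on a dense frequency
#' grid, so that [tcf_to_spectral_density()] recovers J and
#' [reorg_from_tcf()] recovers the density's reorganization energy
#' (C(0) = 2 E_r / beta).
#'
#' @param sd a [spectral_density()].
#' @param beta inverse temperature (a.u.).
#' @param t_grid uniform time grid starting at 0 (a.u.).
#' @param omega_max,n_omega quadrature grid for the transform.
#' @return a [gap_tcf()].
#' @export
synthetic_gap_tcf <- function(sd, beta, t_grid,
                              omega_max = NULL, n_omega = 4096) {
  stopifnot(inherits(sd, "spectral_density"), beta > 0)
  ## closed-form inverse transforms for the analytic kinds
  if (sd$kind == "debye")
    return(gap_tcf(t_grid, 2 * sd$lambda / beta * exp(-sd$omega_c * t_grid),
                   beta))
  if (sd$kind == "ohmic")
    return(gap_tcf(t_grid,
                   TCF_INVERSE_PREFAC / beta * sd$eta * sd$omega_c /
                     (1 + (sd$omega_c * t_grid)^2), beta))
  if (is.null(omega_max)) omega_max <- max(sd$table[, 1])
  w <- seq(0, omega_max, length.out = n_omega)
  jw <- density_value(sd, w)
  f <- ifelse(w > 0, jw / w, 0)
  if (length(f) > 1) f[1] <- f[2]          # J ~ omega near zero
  dw <- w[2] - w[1]
  wts <- rep(dw, n_omega); wts[c(1, n_omega)] <- dw / 2
  ct <- vapply(t_grid, function(t) sum(wts * f * cos(w * t)), numeric(1))
  gap_tcf(t_grid, TCF_INVERSE_PREFAC / beta * ct, beta)
}

#' Packaged triad charge-transfer parameter sets
#'
#' Electronic parameters and pairwise reorganization energies for two
#' conformations of the carotenoid-porphyrin-C60 (CPC60) molecular triad
#' in tetrahydrofuran, a four-state photoinduced charge-transfer system
#' with states {pi-pi*, CT1, CT2, G}: the porphyrin-localized bright
#' state, a partially and a fully charge-separated state, and the ground
#' state.  Energy minima and couplings are stored in eV, reorganization
#' energies in kcal/mol, and converted to atomic units on load; couplings
#' between excited states and the ground state are zero.  The published
#' parameterization does not include its all-atom spectral densities, so
#' models built from these fixtures use a synthetic Debye bath stand-in
#' (see [triad_model()]).
#'
#' @param name `"conf3"` or `"conf5"`.
#' @return list with `reorg` ([reorg_matrix()]), `electronic`
#'   ([electronic_params()]), `labels`, and the raw tabulated values
#'   (`er_kcal`, `eps_ev`, `gamma_ev`, `w_ev` excitation-energy
#'   corrections, carried as metadata only).
#' @export
triad_fixture <- function(name = c("conf3", "conf5")) {
  name <- match.arg(name)
  labels <- c("pipi*", "CT1", "CT2", "G")
  if (name == "conf3") {
    eps <- c(0, -0.828, -0.640, 0)
    w   <- c(0.728, -2.103, -2.131, 0)
    g12 <- -1.5e-2; g13 <- 7.2e-3; g23 <- -2.9e-2
    er  <- c(7.880, 11.39, 0.9202, 3.546, 21.23, 26.42)
  } else {
    eps <- c(0, -0.758, -1.128, 0)
    w   <- c(1.551, -0.697, -0.650, 0)
    g12 <- 8.1e-2; g13 <- 4.1e-3; g23 <- -3.2e-3
    er  <- c(6.464, 18.68, 20.22, 0.3096, 7.920, 18.95)
  }
  gm <- matrix(0, 4, 4)
  gm[1, 2] <- gm[2, 1] <- g12
  gm[1, 3] <- gm[3, 1] <- g13
  gm[2, 3] <- gm[3, 2] <- g23
  erm <- matrix(0, 4, 4)
  erm[1, 2] <- er[1]; erm[1, 3] <- er[2]; erm[1, 4] <- er[3]
  erm[2, 3] <- er[4]; erm[2, 4] <- er[5]; erm[3, 4] <- er[6]
  erm <- erm + t(erm)
  list(name = name,
       labels = labels,
       reorg = reorg_matrix(erm, labels = labels, unit = "kcal/mol"),
       electronic = electronic_params(eps, gm, unit = "ev", labels = labels,
                                      ground = 4),
       er_kcal = erm, eps_ev = eps, gamma_ev = gm, w_ev = w)
}

#' Assemble a triad MSH model with a synthetic Debye bath
#'
#' Convenience wrapper: embeds the packaged reorganization matrix of
#' [triad_fixture()] and attaches a Debye bath (a synthetic stand-in for
#' the unpublished all-atom spectral density) discretized into
#' equal-reorganization modes.
#'
#' @param name `"conf3"` or `"conf5"`.
#' @param n_modes modes per subspace (default 200).
#' @param omega_c Debye cutoff in a.u. (default 200 cm^-1, a typical
#'   intermolecular solvent time scale).
#' @param lambda Debye reorganization-energy scale in a.u.; defaults to
#'   the mean pairwise reorganization energy of the fixture.
#' @return an [msh_model()].
#' @export
triad_model <- function(name = c("conf3", "conf5"), n_modes = 200,
                        omega_c = to_au(200, "cm-1"), lambda = NULL) {
  fx <- triad_fixture(name)
  if (is.null(lambda)) {
    v <- fx$reorg$values
    lambda <- mean(v[upper.tri(v)])
  }
  bath <- discretize_bath(spectral_density("debye", lambda = lambda,
                                           omega_c = omega_c), n_modes)
  ## the independently estimated pairwise reorganization energies of the
  ## triad conformations are not exactly Euclidean-consistent (the CT-state
  ## / ground-state entries violate the triangle inequality on sqrt(E_r)),
  ## so the embedding uses the clamped factorization explicitly
  vert <- suppressWarnings(embed_polyhedron(fx$reorg, on_defect = "clip"))
  msh_model(bath, vert, fx$electronic)
}

#' Synthetic multistate fixture for tests and examples
#'
#' Generates a complete random-but-reproducible MSH model: an embeddable
#' reorganization matrix from a Gaussian point cloud, a Debye bath, energy
#' minima drawn uniformly in [-1, 0] eV (state 1 and the last, ground-like
#' state at 0) and couplings uniform in [-0.02, 0.02] eV with zero
#' ground-state couplings.
#'
#' @param f_states number of states.
#' @param n_modes modes per subspace.
#' @param seed integer seed.
#' @param scale point-cloud scale in sqrt(hartree); the default gives
#'   pairwise reorganization energies of a few kcal/mol.
#' @param omega_c Debye cutoff (a.u.).
#' @return an [msh_model()].
#' @export
synthetic_model <- function(f_states = 4, n_modes = 32, seed = 1,
                            scale = 0.05, omega_c = to_au(200, "cm-1")) {
  er <- random_reorg_matrix(f_states, scale, seed)
  v <- er$values
  lambda <- max(mean(v[upper.tri(v)]), 1e-6)
  bath <- discretize_bath(spectral_density("debye", lambda = lambda,
                                           omega_c = omega_c), n_modes)
  el <- withr_seed(seed + 7919, {
    eps <- c(0, stats::runif(f_states - 2, -1, 0), 0)
    gm <- matrix(0, f_states, f_states)
    gm[upper.tri(gm)] <- stats::runif(f_states * (f_states - 1) / 2,
                                      -0.02, 0.02)
    gm <- gm + t(gm)
    gm[f_states, ] <- 0; gm[, f_states] <- 0
    electronic_params(eps, gm, unit = "ev", ground = f_states)
  })
  msh_model(bath, embed_polyhedron(er), el)
}
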