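test_that("primary mode: closed forms and degenerate cases", {
  ## all frequencies (almost) equal: Omega is forced to that frequency
  b <- make_bath(c(0.005, 0.005 + 1e-12))
  expect_equal(primary_mode(b)$Omega, 0.005, tolerance = 1e-9)
  ## equal-share bath {3, 4}: Omega = sqrt((9 + 16)/2)
  b2 <- make_bath(c(3, 4), er = 1)
  expect_equal(primary_mode(b2)$Omega, sqrt((9 + 16) / 2))
  ## direction components proportional to omega_j under equal shares
  b3 <- make_bath(c(1, 2, 5), er = 0.3)
  a <- primary_mode(b3)$frame$direction
  expect_equal(a, c(1, 2, 5) / sqrt(30))
  ## all displacements zero: no reaction coordinate definable
  b0 <- make_bath(c(1, 2)); b0$req <- c(0, 0)
  expect_error(primary_mode(b0), "no reaction coordinate")
})

test_that("Householder reflector: involution, orthogonality, e1 image", {
  expect_equal(householder_reflector(c(1, 0, 0)), diag(3))
  expect_equal(householder_reflector(c(0, 1)),
               matrix(c(0, 1, 1, 0), 2, 2))
  set.seed(4)
  a <- rnorm(50); a <- a / sqrt(sum(a^2))
  P <- householder_reflector(a)
  expect_lt(max(abs(crossprod(P) - diag(50))), 1e-13)
  expect_lt(max(abs(P - t(P))), 1e-15)
  expect_lt(max(abs(P %*% P - diag(50))), 1e-13)
  expect_equal(as.numeric(P %*% c(1, rep(0, 49))), a)
  expect_equal(as.numeric(crossprod(P, a)), c(1, rep(0, 49)),
               tolerance = 1e-12)
  expect_error(householder_reflector(c(1, 1)), "unit")
})

test_that("secondary bath: trace identity, uncoupled limit, spectral round trip", {
  ## N = 2 equal-share bath: the single secondary frequency follows from
  ## trace conservation of the reflected Hessian
  b <- make_bath(c(3, 4), er = 1)
  pm <- primary_mode(b)
  sb <- secondary_bath(b, pm$frame)
  expect_equal(sb$omega_alphas^2 + sb$K11, 9 + 16, tolerance = 1e-12)
  expect_equal(sb$K11, pm$Omega^2 + sum(sb$c_alphas^2 / sb$omega_alphas^2),
               tolerance = 1e-12)
  ## near-equal frequencies: Lambda ~ I commutes with P, couplings vanish
  be <- make_bath(0.005 + c(0, 1e-9, 2e-9))
  sbe <- secondary_bath(be, primary_mode(be)$frame)
  expect_lt(max(abs(sbe$c_alphas)), 1e-10)
  ## random bath: eigenvalues of the rebuilt arrowhead Hessian equal the
  ## original omega_j^2
  set.seed(7)
  b64 <- make_bath(sort(stats::runif(64, 1e-4, 2e-2)), er = 0.01)
  m64 <- msh_model(b64, make_vertices(matrix(c(0, sqrt(0.01)), 2, 1)),
                   electronic_params(c(0, 0), matrix(0, 2, 2)))
  mr64 <- msh_to_mrc(m64)
  lam <- sort(eigen(mrckit:::mrc_hessian(mr64), symmetric = TRUE)$values)
  expect_rel(lam, b64$omegas^2, 1e-10)
})

test_that("primary shifts absorb the pairwise reorganization energies", {
  ## two-state closed form: equilibrium separation sqrt(2 E_r)/Omega
  er <- 0.012
  m <- two_state_model(er12 = er)
  mr <- msh_to_mrc(m)
  dSep <- abs(mr$primary_shifts[2, 1] - mr$primary_shifts[1, 1])
  expect_equal(dSep, sqrt(2 * er) / mr$omega_rc, tolerance = 1e-12)
  expect_true(all(primary_shifts(make_vertices(matrix(0, 3, 2)), 1) == 0))
  ## multistate: E_r recomputed from full MRC PES minima (with
  ## secondary-bath relaxation) matches the input to 1e-8 relative
  m4 <- tiny_model(4, 16, seed = 13)
  mr4 <- msh_to_mrc(m4)
  er_in <- as.matrix(stats::dist(m4$vertices$coords))^2
  er_rec <- model_reorg_matrix(mr4)
  expect_rel(er_rec[er_in > 0], er_in[er_in > 0], 1e-8)
})

test_that("MSH -> MRC -> MSH round trip reproduces the model", {
  for (seed in c(2, 17)) {
    m <- tiny_model(3, 24, seed = seed)
    mr <- msh_to_mrc(m)
    m2 <- mrc_to_msh(mr)
    expect_rel(m2$bath$omegas, m$bath$omegas, 1e-10)
    expect_equal(m2$vertices$coords, m$vertices$coords, tolerance = 1e-9)
    expect_equal(m2$bath$er, m$bath$er)
    ## two-state case: the MRC form is the GOA model (primary frequency,
    ## one shifted coordinate, bilinear secondary couplings)
  }
  ## a generic (non-equal-share) MRC model cannot enter the MSH container
  g <- goa_model(er = 0.01, Omega = 0.002, eta = 0.004,
                 omega_c = 0.02, n_modes = 16)
  expect_error(mrc_to_msh(g), "equal-reorganization")
})

test_that("coordinate maps are orthogonal, invertible and norm-preserving", {
  m <- tiny_model(3, 16, seed = 21)
  mr <- msh_to_mrc(m)
  expect_lt(max(abs(crossprod(mr$basis_matrix) - diag(16))), 1e-12)
  expect_equal(coords_msh_to_mrc(mr, matrix(0, 16, 2)), matrix(0, 16, 2))
  set.seed(2)
  R <- matrix(rnorm(32), 16, 2)
  P <- matrix(rnorm(32), 16, 2)
  Z <- coords_msh_to_mrc(mr, R)
  expect_lt(max(abs(coords_mrc_to_msh(mr, Z) - R)), 1e-12)
  expect_equal(sum(P^2) / 2, sum(coords_msh_to_mrc(mr, P)^2) / 2)
})

test_that("MSH and MRC potentials agree exactly under the coordinate map", {
  m <- tiny_model(4, 20, seed = 5)
  mr <- msh_to_mrc(m)
  set.seed(9)
  for (k in 1:5) {
    R <- matrix(rnorm(60, sd = 10), 20, 3)
    Z <- coords_msh_to_mrc(mr, R)
    for (x in 1:4)
      expect_lt(abs(msh_potential(m, x, R) - mrc_potential(mr, x, Z)), 1e-10)
  }
  ## minima: eps_X after bath relaxation
  for (x in 1:4)
    expect_equal(mrc_potential(mr, x, state_minimum(mr, x)),
                 m$electronic$epsilons[x])
  ## central-difference gradient of the MRC potential
  Z <- coords_msh_to_mrc(mr, matrix(rnorm(60, sd = 5), 20, 3))
  g <- mrc_gradient(mr, 3, Z)
  h <- 1e-5
  gfd <- g * 0
  for (j in 1:20) for (i in 1:3) {
    Zp <- Z; Zp[j, i] <- Zp[j, i] + h
    Zm <- Z; Zm[j, i] <- Zm[j, i] - h
    gfd[j, i] <- (mrc_potential(mr, 3, Zp) - mrc_potential(mr, 3, Zm)) /
      (2 * h)
  }
  expect_lt(max(abs(g - gfd)), 1e-7)
})

test_that("secondary couplings are a bath property, independent of the states", {
  bath <- discretize_bath(spectral_density("debye", lambda = 0.01,
                                           omega_c = to_au(150, "cm-1")), 24)
  el3 <- electronic_params(c(0, 0, 0), matrix(0, 3, 3))
  m_a <- msh_model(bath, random_reorg_matrix(3, 0.03, seed = 1), el3)
  m_b <- msh_model(bath, random_reorg_matrix(3, 0.09, seed = 2), el3)
  expect_identical(msh_to_mrc(m_a)$bath_couplings,
                   msh_to_mrc(m_b)$bath_couplings)
  expect_identical(msh_to_mrc(m_a)$omega_rc, msh_to_mrc(m_b)$omega_rc)
})

test_that("GOA normal modes follow the Leggett effective density when Omega << omega_c", {
  er <- 0.002; eta <- 0.05; wc <- 0.02; N <- 400  # moderately damped RC
  cum_eff <- function(Om, w)
    vapply(w, function(wi) stats::integrate(function(x)
      goa_effective_density(Om, eta, wc, er)(x) / x, 0, wi,
      rel.tol = 1e-9)$value / pi, numeric(1))
  dev_for <- function(Om) {
    g <- goa_model(er, Om, eta, wc, N)
    D <- mrckit:::mrc_hessian(g)
    eg <- eigen(D, symmetric = TRUE)
    wj <- sqrt(rev(eg$values))
    V <- eg$vectors[, rev(seq_len(N)), drop = FALSE]
    dz <- state_minimum(g, 2) - state_minimum(g, 1)      # MRC basis
    dr <- as.numeric(crossprod(V, dz))                   # normal modes
    shares <- 0.5 * wj^2 * dr^2
    probe <- c(0.5, 1, 2, 4) * Om
    cum_disc <- vapply(probe, function(p) sum(shares[wj <= p]), numeric(1))
    max(abs(cum_disc - cum_eff(Om, probe))) / er
  }
  expect_lt(dev_for(0.1 * wc), 0.05)   # asymptotic regime: within 5%
  expect_gt(dev_for(wc), 0.05)         # Omega ~ omega_c: visibly off
})
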