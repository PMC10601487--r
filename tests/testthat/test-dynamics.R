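test_that("Wigner sampling reproduces the quantum thermal moments", {
  ## single mode, beta*omega = 1: position variance coth(1/2)/2
  omega <- KB_AU * 300            # so beta*omega = 1 at 300 K
  bath <- make_bath(c(omega), er = 1e-8)
  m <- msh_model(bath, make_vertices(matrix(0, 2, 1)),
                 electronic_params(c(0, 0), matrix(0, 2, 2)))
  n <- 1e5
  ens <- suppressWarnings(sample_wigner(m, 1, 300, n, seed = 3))
  r <- vapply(ens, function(s) s$positions[1, 1], numeric(1))
  p <- vapply(ens, function(s) s$momenta[1, 1], numeric(1))
  vr_true <- 1 / tanh(0.5) / (2 * omega)
  vp_true <- (omega / 2) / tanh(0.5)
  expect_lt(abs(stats::var(r) - vr_true), 3 * vr_true * sqrt(2 / n))
  expect_lt(abs(stats::var(p) - vp_true), 3 * vp_true * sqrt(2 / n))
  ## classical limit: variances approach kT/omega^2 and kT
  hot <- 300 * 50
  ens2 <- sample_wigner(m, 1, hot, 2e4, seed = 4)
  r2 <- vapply(ens2, function(s) s$positions[1, 1], numeric(1))
  expect_equal(stats::var(r2), KB_AU * hot / omega^2, tolerance = 0.05)
  expect_error(sample_wigner(m, 9, 300, 1), "unknown center")
})

test_that("thermal mean potential energy matches the harmonic average", {
  m <- tiny_model(3, 6, seed = 2)
  n <- 4000
  ens <- sample_wigner(m, 2, 300, n, seed = 5)
  v <- vapply(ens, function(s)
    msh_potential(m, 2, s$positions) - m$electronic$epsilons[2], numeric(1))
  beta <- beta_au(300)
  vtrue <- m$n_sub * sum(m$bath$omegas / tanh(beta * m$bath$omegas / 2)) / 4
  expect_lt(abs(mean(v) - vtrue), 4 * stats::sd(v) / sqrt(n))
})

test_that("explicit reaction-coordinate centers shift the sampled cloud", {
  m <- tiny_model(3, 8, seed = 6)
  y0 <- c(0.8, -0.5)
  ## same seed with and without the shift: the pointwise difference is the
  ## deterministic center, free of sampling noise
  ens1 <- sample_wigner(m, list(y = y0), 300, 5, seed = 7)
  ens0 <- sample_wigner(m, list(y = c(0, 0)), 300, 5, seed = 7)
  a <- primary_mode(m$bath)$frame$direction
  for (k in 1:5) {
    dR <- ens1[[k]]$positions - ens0[[k]]$positions
    expect_equal(colSums(a * dR), y0, tolerance = 1e-12)
    expect_equal(ens1[[k]]$momenta, ens0[[k]]$momenta)
  }
})

test_that("zero coupling freezes the electronic populations", {
  m <- two_state_model(gamma = 0)
  tr <- ehrenfest_propagate(m, dt = 0.5, n_steps = 50, n_traj = 3, seed = 1,
                            init_state = 2)
  expect_lt(max(abs(tr$pops[, 2] - 1)), 1e-10)  # integrator round-off only
  trs <- sqc_propagate(m, dt = 0.5, n_steps = 50, n_traj = 10, seed = 1,
                       init_state = 2, substeps = 2)
  expect_true(all(trs$pops[, 2] == 1))          # window counts are exact
  expect_lt(max(abs(rowSums(tr$pops) - 1)), 1e-10)
})

test_that("two degenerate states with constant coupling Rabi-oscillate", {
  gam <- 0.005
  bath <- make_bath(c(1e-3, 2e-3), er = 1e-10)
  m <- msh_model(bath, make_vertices(matrix(0, 2, 1)),
                 electronic_params(c(0, 0),
                                   matrix(c(0, gam, gam, 0), 2, 2)))
  tr <- ehrenfest_propagate(m, dt = 0.01, n_steps = 2000, n_traj = 1,
                            seed = 2, init_state = 1, record_every = 10)
  tau <- to_au(tr$times, "fs")
  expect_lt(max(abs(tr$pops[, 1] - cos(gam * tau)^2)), 1e-6)
})

test_that("uncoupled nuclear motion is exactly classical harmonic", {
  ## gamma = 0, mean-field: dynamics on V_X is linear; compare against the
  ## analytic normal-mode solution
  m <- two_state_model(gamma = 0, omegas = c(0.001, 0.002, 0.004))
  de <- mrckit:::.dyn_descriptor(m)
  R0 <- matrix(c(1, -2, 0.5), 3, 1)
  P0 <- matrix(c(0.001, 0, -0.002), 3, 1)
  ens <- list(list(positions = R0, momenta = P0, basis = "normal_mode"))
  dtfs <- 0.002
  nst <- 500
  tr <- ehrenfest_propagate(m, dt = dtfs, n_steps = nst, n_traj = 1,
                            seed = 1, init_state = 1, substeps = 1,
                            ensemble = ens)
  ## analytic evolution about state-1 minimum
  w <- m$bath$omegas
  mn <- state_minimum(m, 1)
  t_end <- to_au(dtfs * nst, "fs")
  r_exact <- mn + (R0 - mn) * cos(w * t_end) + P0 / w * sin(w * t_end)
  y_exact <- sum(primary_mode(m$bath)$frame$direction * r_exact)
  expect_lt(abs(tr$rc_mean[nrow(tr$rc_mean), 1] - y_exact), 1e-8)
})

test_that("mean-field energy is conserved and populations stay normalized", {
  ## Ohmic bath: mode range ~ omega_c ln(2N), resolved at dt = 0.1 fs
  bath <- discretize_bath(spectral_density("ohmic", eta = 2,
                                           omega_c = to_au(200, "cm-1")), 16,
                          er_total = 0.008)
  m <- msh_model(bath, random_reorg_matrix(3, 0.04, seed = 31),
                 tiny_model(3, 4, seed = 31)$electronic)
  tr <- ehrenfest_propagate(m, dt = 0.1, n_steps = 2000, n_traj = 2,
                            seed = 6, init_state = 1, record_every = 20)
  expect_lt(max(abs(tr$energy - tr$energy[1])), 1e-6)
  expect_lt(max(abs(rowSums(tr$pops) - 1)), 1e-10)
})

test_that("SQC window assignments are identical on MSH and transformed MRC", {
  m <- tiny_model(3, 12, seed = 41)
  cfg <- sim_config(method = "sqc", dt = 0.2, n_steps = 200, n_traj = 10,
                    seed = 11, init_state = 1, substeps = 5)
  rep <- equivalence_report(m, cfg)
  ## renormalized window counts must agree exactly, not just closely
  expect_identical(rep$msh_trace$pops, rep$mrc_trace$pops)
  expect_gte(min(rep$digits[-1]), 10)
})

test_that("SQC populations converge with trajectory count within error bars", {
  m <- tiny_model(3, 8, seed = 51)
  run <- function(n, seed) sqc_propagate(m, dt = 1, n_steps = 120,
                                         n_traj = n, seed = seed,
                                         init_state = 1, substeps = 5,
                                         record_every = 10)
  t_small <- run(400, seed = 100)
  t_big <- run(800, seed = 200)
  ## jackknife over 8 blocks of the larger ensemble
  blocks <- lapply(1:8, function(b) run(100, seed = 300 + b)$pops[, 1])
  bm <- do.call(cbind, blocks)
  se_big <- apply(bm, 1, stats::sd) / sqrt(8)
  se_small <- se_big * sqrt(2)           # 400 vs 800 trajectories
  tol <- 4 * sqrt(se_big^2 + se_small^2) + 1e-3
  expect_true(all(abs(t_small$pops[, 1] - t_big$pops[, 1]) < tol))
})

test_that("reaction-coordinate traces behave in the closed-form limits", {
  ## E_r = 0: ensemble-mean RC stays at zero from an equilibrium start
  bath <- make_bath(c(0.002, 0.005, 0.01), er = 1e-8)
  m0 <- msh_model(bath, make_vertices(matrix(0, 2, 1)),
                  electronic_params(c(0, 0), matrix(0, 2, 2)))
  tr0 <- ehrenfest_propagate(m0, dt = 1, n_steps = 50, n_traj = 200,
                             seed = 21, init_state = 1, substeps = 1)
  spread <- sqrt(sum(1 / tanh(beta_au(300) * bath$omegas / 2) /
                     (2 * bath$omegas)) / 3)
  expect_lt(max(abs(tr0$rc_mean)), 4 * spread / sqrt(200))
  ## averaging smooths: the fluctuation about the deterministic mean path
  ## shrinks as 1/n
  m <- two_state_model(er12 = 0.01, gamma = 0)
  det_ens <- list(list(positions = state_minimum(m, 2),
                       momenta = state_minimum(m, 2) * 0,
                       basis = "normal_mode"))
  det <- ehrenfest_propagate(m, dt = 1, n_steps = 40, n_traj = 1, seed = 1,
                             init_state = 1, substeps = 1,
                             ensemble = det_ens)$rc_mean[, 1]
  v_of <- function(n) {
    tr <- ehrenfest_propagate(m, dt = 1, n_steps = 40, n_traj = n, seed = 9,
                              init_state = 1, substeps = 1)
    mean((tr$rc_mean[, 1] - det)^2)
  }
  expect_lt(v_of(64), v_of(1) / 4)
  ## accessor returns a tidy frame
  tr <- ehrenfest_propagate(m, dt = 1, n_steps = 10, n_traj = 1, seed = 2,
                            init_state = 1, substeps = 1)
  df <- rc_trajectory_average(tr)
  expect_named(df, c("time_fs", "y1"))
  expect_identical(nrow(df), 11L)
})

test_that("degenerate SQC estimators are reported, not silently normalized", {
  m <- two_state_model()
  gamma <- 1 / 3
  bad <- lapply(1:2, function(k) sqrt(c(0.5, 0.5) + gamma) *
                  exp(2i * pi * c(0.1, 0.7)))
  expect_error(
    propagate(m, sim_config(method = "sqc", dt = 0.5, n_steps = 2,
                            n_traj = 2, seed = 1, init_state = 1),
              electronic_init = bad),
    "degenerate")
})

test_that("basis tags guard against mixed-representation input", {
  m <- tiny_model(3, 8, seed = 61)
  mr <- msh_to_mrc(m)
  ens <- sample_wigner(m, 3, 300, 1, seed = 2)
  expect_error(propagate(mr, sim_config(dt = 0.1, n_steps = 1, n_traj = 1),
                         ensemble = ens),
               "basis")
})
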