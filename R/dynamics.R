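## Ensemble semiclassical nonadiabatic propagation on MSH, MRC or
## isolated-bath models: velocity-Verlet nuclei, 4th-order Runge-Kutta
## electronic mapping variables (updated `substeps` times per nuclear step
## on a linearly interpolated diabatic Hamiltonian), Ehrenfest mean-field
## or symmetrical quasi-classical triangle-window estimators.

#' Simulation configuration
#'
#' @param method `"mf"` (Ehrenfest mean-field) or `"sqc"` (symmetrical
#'   quasi-classical, triangle window).
#' @param dt nuclear time step in fs (default 0.1).
#' @param n_steps number of nuclear steps; alternatively give `t_final`.
#' @param t_final total time in fs (used when `n_steps` is missing).
#' @param substeps electronic updates per nuclear step (default 20).
#' @param n_traj trajectory count.
#' @param seed master integer seed; trajectory k uses an independently
#'   derived stream so it is reproducible regardless of ensemble size.
#' @param temperature bath temperature in K.
#' @param init_state initially populated electronic state.
#' @param init_nuclear state index whose PES minimum centers the Wigner
#'   distribution (default: the last state, ground-like), or
#'   `list(y = ...)` giving an explicit reaction-coordinate-space center.
#' @param zpe_gamma mapping zero-point parameter; default 0 for `"mf"`,
#'   1/3 for `"sqc"` (triangle-window value).
#' @param record_every store observables every this many nuclear steps.
#' @param record_coherences also store the mean off-diagonal electronic
#'   density-matrix elements.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(method = c("mf", "sqc"), dt = 0.1, n_steps = NULL,
                       t_final = NULL, substeps = 20L, n_traj = 1L,
                       seed = 1L, temperature = 300, init_state = 1L,
                       init_nuclear = NULL, zpe_gamma = NULL,
                       record_every = 1L, record_coherences = FALSE) {
  method <- match.arg(method)
  if (is.null(n_steps)) {
    if (is.null(t_final)) stop("give n_steps or t_final", call. = FALSE)
    n_steps <- max(1L, as.integer(round(t_final / dt)))
  }
  stopifnot(dt > 0, substeps >= 1, n_traj >= 1, n_steps >= 1)
  if (is.null(zpe_gamma)) zpe_gamma <- if (method == "sqc") 1 / 3 else 0
  structure(list(method = method, dt = dt, n_steps = as.integer(n_steps),
                 substeps = as.integer(substeps), n_traj = as.integer(n_traj),
                 seed = as.integer(seed), temperature = temperature,
                 init_state = as.integer(init_state),
                 init_nuclear = init_nuclear, zpe_gamma = zpe_gamma,
                 record_every = as.integer(record_every),
                 record_coherences = isTRUE(record_coherences)),
            class = "sim_config")
}

## ---- model descriptors: a uniform interface for the propagator ----------

.dyn_descriptor <- function(model) {
  if (inherits(model, "msh_model")) {
    N <- model$n_modes; nsub <- model$n_sub
    w2 <- model$bath$omegas^2
    list(N = N, nsub = nsub,
         hess = function(Z) w2 * Z,
         b = matrix(sqrt(2 / N) * model$bath$omegas, N, nsub),
         d = model$vertices$coords,
         eps = model$electronic$epsilons,
         gam = model$electronic$gammas,
         basis = "normal_mode")
  } else if (inherits(model, "mrc_model")) {
    N <- length(model$bath_omegas) + 1; nsub <- model$subspaces
    K11 <- .mrc_k11(model)
    cv <- model$bath_couplings; wa2 <- model$bath_omegas^2
    bm <- matrix(0, N, nsub); bm[1, ] <- sqrt(2) * model$omega_rc
    list(N = N, nsub = nsub,
         hess = function(Z) {
           y <- Z[1, ]; x <- Z[-1, , drop = FALSE]
           rbind(K11 * y + colSums(cv * x), outer(cv, y) + wa2 * x)
         },
         b = bm,
         d = model$vertices$coords,
         eps = model$electronic$epsilons,
         gam = model$electronic$gammas,
         basis = "primary_secondary")
  } else if (inherits(model, "frenkel_model")) {
    N <- model$n_modes; nsub <- model$n_sub
    w2m <- model$omega_mat^2
    list(N = N, nsub = nsub,
         hess = function(Z) w2m * Z,
         b = sqrt(2 / N) * model$omega_mat,
         d = model$vertices$coords,
         eps = model$electronic$epsilons,
         gam = model$electronic$gammas,
         basis = "normal_mode")
  } else stop("unsupported model class", call. = FALSE)
}

## ---- initial conditions --------------------------------------------------

#' Wigner-sampled thermal initial nuclear conditions
#'
#' Independent Gaussian draws per harmonic mode with quantum thermal
#' variances coth(beta*omega/2)/(2*omega) for positions and
#' (omega/2)*coth(beta*omega/2) for momenta (mass-weighted a.u.), centered
#' at a chosen state's PES minimum or an explicit reaction-coordinate-space
#' center.  Sampling is performed in the normal-mode basis; map the result
#' with [coords_msh_to_mrc()] when propagating the MRC representation.
#'
#' @param model an `"msh_model"` or `"frenkel_model"`.
#' @param center state index (its PES minimum), or `list(y = ...)` with
#'   one reaction-coordinate value per subspace.
#' @param temperature temperature in K (> 0).
#' @param n number of samples.
#' @param seed integer seed.
#' @return list of `n` phase-space states: each a list with `positions`
#'   and `momenta` (N x n_sub matrices) and a `basis` tag.
#' @export
sample_wigner <- function(model, center, temperature, n, seed = 1) {
  de <- .dyn_descriptor(model)
  if (de$basis != "normal_mode")
    stop("sample in the normal-mode representation, then map", call. = FALSE)
  omega_mat <- if (inherits(model, "frenkel_model")) model$omega_mat
               else matrix(model$bath$omegas, de$N, de$nsub)
  if (is.list(center)) {
    if (is.null(center$y) || length(center$y) != de$nsub)
      stop("explicit center needs one y value per subspace", call. = FALSE)
    if (inherits(model, "frenkel_model"))
      stop("explicit RC center requires an MSH model", call. = FALSE)
    a <- primary_mode(model$bath)$frame$direction
    mu <- outer(a, center$y)
  } else {
    center <- as.integer(center)
    if (center < 1 || center > model$f_states)
      stop("unknown center state index ", center, call. = FALSE)
    mu <- state_minimum(model, center)
  }
  beta <- beta_au(temperature)
  cth <- 1 / tanh(beta * omega_mat / 2)
  sd_r <- sqrt(cth / (2 * omega_mat))
  sd_p <- sqrt(omega_mat * cth / 2)
  withr_seed(seed, lapply(seq_len(n), function(k) {
    list(positions = mu + matrix(stats::rnorm(length(mu)), de$N, de$nsub) * sd_r,
         momenta = matrix(stats::rnorm(length(mu)), de$N, de$nsub) * sd_p,
         basis = "normal_mode")
  }))
}

## uniform draw on the simplex {x_i >= 0, sum x <= 1} in d dimensions
.runif_simplex <- function(d) {
  e <- stats::rexp(d + 1)
  (e / sum(e))[seq_len(d)]
}

## initial mapping variables c = (q + i p)/sqrt(2), |c_k|^2 = n_k + gamma.
## mf: delta occupation.  sqc: triangle-window actions (see vignette):
## (n_i - 1, {n_k}) uniform on the F-simplex, random phases.
.sample_electronic <- function(method, f, init_state, gamma) {
  if (method == "mf") {
    cc <- complex(real = rep(0, f)); cc[init_state] <- 1 + 0i
    return(cc)
  }
  m <- .runif_simplex(f)
  n <- m; n[init_state] <- 1 + m[init_state]
  phi <- stats::runif(f, 0, 2 * pi)
  sqrt(n + gamma) * complex(argument = phi)
}

## triangle-window occupation: state i iff n_i >= 1, n_k >= 0 (k != i),
## and sum(n) <= 2; returns 0 when the point is in no window
.window_state <- function(n) {
  if (any(!is.finite(n)))
    stop("trajectory diverged (non-finite mapping actions): the nuclear ",
         "time step is likely too large for the stiffest bath mode ",
         "(velocity-Verlet requires omega * dt < 2)", call. = FALSE)
  if (sum(n) > 2) return(0L)
  i <- which(n >= 1)
  if (length(i) != 1L) return(0L)
  if (any(n[-i] < 0)) return(0L)
  i
}

## ---- core propagator -----------------------------------------------------

## RK4 on c' = -i H(tau) c with H linearly interpolated from H0 to H1
.rk4_electronic <- function(cc, H0, H1, dt, nsub) {
  h <- dt / nsub
  dH <- (H1 - H0) / nsub
  for (k in seq_len(nsub)) {
    Ha <- H0 + (k - 1) * dH
    Hm <- H0 + (k - 0.5) * dH
    Hb <- H0 + k * dH
    k1 <- -1i * (Ha %*% cc)
    k2 <- -1i * (Hm %*% (cc + (h / 2) * k1))
    k3 <- -1i * (Hm %*% (cc + (h / 2) * k2))
    k4 <- -1i * (Hb %*% (cc + h * k3))
    cc <- cc + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(cc)
}

.propagate_one <- function(de, ic, cc0, cfg, a_dir = NULL) {
  dt <- to_au(cfg$dt, "fs")
  gamma <- if (cfg$method == "sqc") cfg$zpe_gamma else 0
  f <- length(de$eps)
  cc_sum <- rowSums(de$d^2)                 # |d_X|^2 constant terms
  nrec <- cfg$n_steps %/% cfg$record_every + 1L
  pops <- matrix(NA_real_, nrec, f)
  wins <- matrix(0, nrec, f)
  ys <- matrix(NA_real_, nrec, de$nsub)
  energy <- rep(NA_real_, nrec)
  coh <- if (cfg$record_coherences)
    array(NA_complex_, c(nrec, f, f)) else NULL

  Z <- ic$positions; Pm <- ic$momenta; cc <- cc0
  ## the electronic propagation removes the trace of the diabatic matrix
  ## (a global phase): the mapping estimators are phase-invariant and the
  ## integrator then resolves the gap scale instead of the absolute
  ## bath-potential scale
  H <- de$gam
  vfun <- function(Z) {
    hz <- de$hess(Z)
    g <- colSums(de$b * Z)
    list(V = de$eps + 0.5 * sum(Z * hz) + as.numeric(de$d %*% g) + cc_sum,
         hz = hz)
  }
  force <- function(hz, w) {
    dw <- as.numeric(crossprod(de$d, w))
    -(sum(w) * hz + de$b * rep(dw, each = de$N))
  }
  vv <- vfun(Z)
  diag(H) <- vv$V - mean(vv$V)
  rec_row <- 1L
  record <- function(row) {
    n <- Mod(cc)^2 - gamma
    pops[row, ] <<- n          # continuous estimator (|c|^2 for mean field)
    if (cfg$method == "sqc") {
      wst <- .window_state(n)
      if (wst > 0) wins[row, wst] <<- 1
    }
    if (!is.null(a_dir)) ys[row, ] <<- colSums(a_dir * Z)
    else ys[row, ] <<- Z[1, ]
    gg <- de$gam
    energy[row] <<- 0.5 * sum(Pm^2) + sum((Mod(cc)^2 - gamma) * vv$V) +
      sum(Re(Conj(cc) %o% cc) * gg)
    if (cfg$record_coherences) coh[row, , ] <<- cc %o% Conj(cc)
  }
  record(1L)
  w <- Mod(cc)^2 - gamma
  Fm <- force(vv$hz, w)
  for (step in seq_len(cfg$n_steps)) {
    Pm <- Pm + (dt / 2) * Fm
    Z <- Z + dt * Pm
    vnew <- vfun(Z)
    Hn <- de$gam
    diag(Hn) <- vnew$V - mean(vnew$V)
    cc <- .rk4_electronic(cc, H, Hn, dt, cfg$substeps)
    vv <- vnew; H <- Hn
    w <- Mod(cc)^2 - gamma
    Fm <- force(vv$hz, w)
    Pm <- Pm + (dt / 2) * Fm
    if (step %% cfg$record_every == 0L) {
      rec_row <- rec_row + 1L
      record(rec_row)
    }
  }
  list(pops = pops, wins = wins, ys = ys, energy = energy, coh = coh)
}

## derive a reproducible per-trajectory seed below 2^31
.traj_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + k * 65537) %% 2147483647)
}

#' Propagate an ensemble of semiclassical trajectories
#'
#' Velocity-Verlet nuclear propagation with Ehrenfest mean-field or
#' symmetrical quasi-classical (triangle-window) electronic mapping
#' variables.  Initial nuclear conditions are Wigner-sampled in the
#' normal-mode basis (and mapped when the model is in MRC form); the
#' nuclear force is the full density-matrix-weighted diabatic gradient
#' (couplings are constant under the Condon approximation, so only
#' diagonal gradients contribute).
#'
#' @param model an `"msh_model"`, `"mrc_model"` or `"frenkel_model"`.
#' @param config a [sim_config()].
#' @param ensemble optional list of initial phase-space states in the
#'   model's own basis (e.g. from [sample_wigner()], mapped if needed);
#'   drawn automatically when omitted.
#' @param electronic_init optional list of initial mapping-variable
#'   vectors (complex, one per trajectory); drawn automatically.
#' @return object of class `"population_trace"`: `times` (fs), `pops`
#'   (ensemble-mean populations; for SQC the renormalized window counts),
#'   `actions` (mean continuous estimator), `rc_mean` (mean reaction-
#'   coordinate components), `energy` (mean total energy drift per output
#'   time, a.u.), `coherences` (optional), plus the config.
#' @export
propagate <- function(model, config, ensemble = NULL, electronic_init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  de <- .dyn_descriptor(model)
  f <- length(de$eps)
  if (config$init_state < 1 || config$init_state > f)
    stop("init_state out of range", call. = FALSE)
  if (is.null(ensemble)) {
    center <- if (is.null(config$init_nuclear)) f else config$init_nuclear
    if (inherits(model, "mrc_model")) {
      msh <- mrc_to_msh(model)
      raw <- sample_wigner(msh, center, config$temperature, config$n_traj,
                           seed = config$seed)
      ensemble <- lapply(raw, function(s)
        list(positions = coords_msh_to_mrc(model, s$positions),
             momenta = coords_msh_to_mrc(model, s$momenta),
             basis = "primary_secondary"))
    } else {
      ensemble <- sample_wigner(model, center, config$temperature,
                                config$n_traj, seed = config$seed)
    }
  }
  if (length(ensemble) != config$n_traj)
    stop("ensemble size differs from n_traj", call. = FALSE)
  for (s in ensemble)
    if (!is.null(s$basis) && s$basis != de$basis)
      stop("initial-condition basis tag '", s$basis,
           "' does not match the model representation '", de$basis, "'",
           call. = FALSE)
  if (is.null(electronic_init))
    electronic_init <- lapply(seq_len(config$n_traj), function(k)
      withr_seed(.traj_seed(config$seed, k),
                 .sample_electronic(config$method, f, config$init_state,
                                    config$zpe_gamma)))
  a_dir <- if (inherits(model, "msh_model"))
    matrix(primary_mode(model$bath)$frame$direction, de$N, de$nsub)
  else NULL

  nrec <- config$n_steps %/% config$record_every + 1L
  acc_pops <- matrix(0, nrec, f)
  acc_wins <- matrix(0, nrec, f)
  acc_ys <- matrix(0, nrec, de$nsub)
  acc_en <- rep(0, nrec)
  acc_coh <- if (config$record_coherences)
    array(0 + 0i, c(nrec, f, f)) else NULL
  for (k in seq_len(config$n_traj)) {
    res <- .propagate_one(de, ensemble[[k]], electronic_init[[k]], config,
                          a_dir = a_dir)
    acc_pops <- acc_pops + res$pops
    acc_wins <- acc_wins + res$wins
    acc_ys <- acc_ys + res$ys
    acc_en <- acc_en + res$energy
    if (config$record_coherences) acc_coh <- acc_coh + res$coh
  }
  n <- config$n_traj
  times <- seq(0, by = config$dt * config$record_every,
               length.out = nrec)
  if (config$method == "sqc") {
    tot0 <- sum(acc_wins[1, ])
    if (tot0 == 0)
      stop("estimator degenerate: no trajectory lies in any window at t = 0",
           call. = FALSE)
    tot <- rowSums(acc_wins)
    pops <- acc_wins / ifelse(tot > 0, tot, NA_real_)
  } else {
    pops <- acc_pops / n
  }
  structure(list(times = times, pops = pops, actions = acc_pops / n,
                 rc_mean = acc_ys / n, energy = acc_en / n,
                 coherences = if (config$record_coherences) acc_coh / n,
                 method = config$method, n_traj = n, config = config,
                 labels = model$electronic$labels),
            class = "population_trace")
}

#' Ehrenfest mean-field propagation
#' @inheritParams propagate
#' @param ... passed to [sim_config()].
#' @return a `"population_trace"`.
#' @export
ehrenfest_propagate <- function(model, ..., ensemble = NULL,
                                electronic_init = NULL) {
  propagate(model, sim_config(method = "mf", ...), ensemble, electronic_init)
}

#' Symmetrical quasi-classical (triangle window) propagation
#' @inheritParams ehrenfest_propagate
#' @return a `"population_trace"`.
#' @export
sqc_propagate <- function(model, ..., ensemble = NULL,
                          electronic_init = NULL) {
  propagate(model, sim_config(method = "sqc", ...), ensemble, electronic_init)
}

#' @export
print.population_trace <- function(x, ...) {
  cat(sprintf("Population trace: %s, %d trajectories, %d output times (0..%g fs)\n",
              toupper(x$method), x$n_traj, length(x$times), max(x$times)))
  last <- round(x$pops[nrow(x$pops), ], 4)
  names(last) <- x$labels
  cat("  final populations:\n")
  print(last)
  drift <- max(abs(x$energy - x$energy[1]), na.rm = TRUE)
  cat(sprintf("  max mean-energy drift: %.3g hartree\n", drift))
  invisible(x)
}

#' @export
plot.population_trace <- function(x, which = c("populations", "rc"), ...) {
  which <- match.arg(which)
  if (which == "populations") {
    graphics::matplot(x$times, x$pops, type = "l", lty = 1,
                      xlab = "time (fs)", ylab = "population", ...)
    graphics::legend("topright", legend = x$labels, col = seq_len(ncol(x$pops)),
                     lty = 1, bty = "n")
  } else {
    graphics::matplot(x$times, x$rc_mean, type = "l", lty = 1,
                      xlab = "time (fs)", ylab = "<y_i> (a.u.)", ...)
  }
  invisible(x)
}

#' Ensemble-averaged reaction-coordinate trajectory
#'
#' @param trace a `"population_trace"` (single-trajectory runs give the
#'   single sampled RC trajectory).
#' @return data.frame with `time_fs` and one column per RC component.
#' @export
rc_trajectory_average <- function(trace) {
  stopifnot(inherits(trace, "population_trace"))
  out <- data.frame(time_fs = trace$times)
  ys <- as.data.frame(trace$rc_mean)
  names(ys) <- paste0("y", seq_len(ncol(ys)))
  cbind(out, ys)
}

#' Simulate nonadiabatic dynamics of a model
#'
#' `simulate()` method dispatching to [propagate()].
#'
#' @param object an `"msh_model"` or `"mrc_model"`.
#' @param nsim number of trajectories.
#' @param seed master seed.
#' @param ... further [sim_config()] arguments (`method`, `dt`, `n_steps`
#'   or `t_final`, `init_state`, ...).
#' @return a `"population_trace"`.
#' @export
simulate.msh_model <- function(object, nsim = 1, seed = 1, ...) {
  propagate(object, sim_config(n_traj = nsim, seed = seed, ...))
}

#' @rdname simulate.msh_model
#' @export
simulate.mrc_model <- function(object, nsim = 1, seed = 1, ...) {
  propagate(object, sim_config(n_traj = nsim, seed = seed, ...))
}

## ---- representation equivalence -----------------------------------------

## Count of agreeing significant figures between two population-like
## values, capped at 16 (IEEE double); identical values count as 16.
## Populations are dimensionless order-one numbers (they live on the unit
## simplex), so agreement is assessed on the unit scale: grading a
## near-zero population by its own relative error would demand far more
## than "the same within k significant figures" means for such data.
.matching_digits <- function(a, b) {
  d <- abs(a - b)
  ref <- pmax(abs(a), abs(b), 1)
  out <- ifelse(d == 0, 16, floor(-log10(d / ref)))
  pmin(pmax(out, 0), 16)
}

#' Numerical equivalence of MSH and MRC propagation
#'
#' Propagates the same seeded initial conditions on an MSH model and on
#' its exactly transformed MRC counterpart (initial nuclear conditions
#' sampled once in the normal-mode basis and mapped through the orthogonal
#' basis matrix; identical electronic draws) and reports, at every output
#' time, the minimum over states of the number of agreeing significant
#' figures between the two population traces.  Agreement is limited only
#' by double-precision round-off accumulating along the trajectories, not
#' by the transformation, which is exact.
#'
#' @param msh an `"msh_model"`.
#' @param config a [sim_config()].
#' @param mrc optional pre-computed [msh_to_mrc()] result.
#' @return object of class `"equivalence_report"`: `times` (fs), `digits`
#'   (min matching significant figures per output time), and both traces.
#' @export
equivalence_report <- function(msh, config, mrc = NULL) {
  stopifnot(inherits(msh, "msh_model"))
  if (is.null(mrc)) mrc <- msh_to_mrc(msh)
  f <- msh$f_states
  center <- if (is.null(config$init_nuclear)) f else config$init_nuclear
  raw <- sample_wigner(msh, center, config$temperature, config$n_traj,
                       seed = config$seed)
  mapped <- lapply(raw, function(s)
    list(positions = coords_msh_to_mrc(mrc, s$positions),
         momenta = coords_msh_to_mrc(mrc, s$momenta),
         basis = "primary_secondary"))
  el <- lapply(seq_len(config$n_traj), function(k)
    withr_seed(.traj_seed(config$seed, k),
               .sample_electronic(config$method, f, config$init_state,
                                  config$zpe_gamma)))
  tr_msh <- propagate(msh, config, ensemble = raw, electronic_init = el)
  tr_mrc <- propagate(mrc, config, ensemble = mapped, electronic_init = el)
  key <- if (config$method == "sqc") "actions" else "pops"
  a <- tr_msh[[key]]; b <- tr_mrc[[key]]
  digits <- vapply(seq_along(tr_msh$times), function(i)
    min(.matching_digits(a[i, ], b[i, ])), numeric(1))
  structure(list(times = tr_msh$times, digits = digits,
                 msh_trace = tr_msh, mrc_trace = tr_mrc,
                 method = config$method),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  nt <- length(x$times)
  head_n <- min(50L, nt - 1L)
  cat("MSH / MRC representation equivalence (", toupper(x$method), ")\n",
      sep = "")
  cat(sprintf("  min matching significant figures, first %d steps : %g\n",
              head_n, min(x$digits[seq_len(head_n) + 1L])))
  cat(sprintf("  matching significant figures at t = %g fs        : %g\n",
              max(x$times), x$digits[nt]))
  invisible(x)
}
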