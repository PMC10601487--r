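## Model serialization: a versioned JSON document ("mrckit-model-1") with
## blocks {units, states, reorg_matrix, epsilons, gammas, bath, vertices}
## and, for the reaction-coordinate form, {omega_rc, bath_omegas,
## bath_couplings, primary_shifts, basis_matrix}.  Numbers are written at
## full IEEE precision so a write/read round trip is lossless.

MODEL_SCHEMA_VERSION <- "mrckit-model-1"

#' Write a model to a JSON document
#'
#' @param model an `"msh_model"` or `"mrc_model"`.
#' @param path output file path.
#' @param basis_matrix for MRC models, also store the N x N orthogonal
#'   basis matrix (full precision); if `FALSE` (default) it is
#'   reconstructed on read via [msh_to_mrc()] of the stored bath.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, basis_matrix = FALSE) {
  doc <- list(version = MODEL_SCHEMA_VERSION, units = "au")
  if (inherits(model, "msh_model")) {
    doc$kind <- "msh"
    doc$states <- model$electronic$labels
    doc$epsilons <- model$electronic$epsilons
    doc$gammas <- model$electronic$gammas
    doc$vertices <- unname(model$vertices$coords)
    doc$bath <- list(n = model$bath$n_modes, omegas = model$bath$omegas,
                     er = model$bath$er)
    doc$reorg_matrix <- unname(as.matrix(stats::dist(
      model$vertices$coords))^2)
  } else if (inherits(model, "mrc_model")) {
    doc$kind <- "mrc"
    doc$states <- model$electronic$labels
    doc$epsilons <- model$electronic$epsilons
    doc$gammas <- model$electronic$gammas
    doc$vertices <- unname(model$vertices$coords)
    doc$omega_rc <- model$omega_rc
    doc$bath_omegas <- model$bath_omegas
    doc$bath_couplings <- model$bath_couplings
    doc$primary_shifts <- unname(model$primary_shifts)
    doc$bath_er <- model$bath_er
    doc$k11 <- model$k11
    if (isTRUE(basis_matrix)) doc$basis_matrix <- unname(model$basis_matrix)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

.as_matrix <- function(x) {
  if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
}

#' Read a model from a JSON document
#'
#' The model kind is auto-detected from the blocks present; validation
#' errors name the offending field (e.g. the index of a nonpositive
#' frequency), and unknown schema versions are rejected explicitly.
#'
#' @param path file written by [write_model()].
#' @return an `"msh_model"` or `"mrc_model"`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || !identical(doc$version, MODEL_SCHEMA_VERSION))
    stop("unsupported model schema version '", doc$version %||% "<missing>",
         "' (expected '", MODEL_SCHEMA_VERSION, "')", call. = FALSE)
  labels <- as.character(doc$states)
  el <- electronic_params(as.numeric(doc$epsilons), .as_matrix(doc$gammas),
                          labels = labels)
  vert <- structure(list(coords = .as_matrix(doc$vertices),
                         f_states = length(labels)),
                    class = "polyhedron_vertices")
  rownames(vert$coords) <- labels
  if (identical(doc$kind, "msh")) {
    omegas <- as.numeric(doc$bath$omegas)
    bad <- which(omegas <= 0)
    if (length(bad))
      stop("validation error: bath frequency at index ", bad[1],
           " is not positive", call. = FALSE)
    if (is.unsorted(omegas, strictly = TRUE))
      stop("validation error: bath frequencies must be strictly ascending",
           call. = FALSE)
    er <- as.numeric(doc$bath$er)
    N <- length(omegas)
    req <- sqrt(2 * er / N) / omegas
    bath <- structure(list(n_modes = N, omegas = omegas, er = er, req = req,
                           couplings = omegas^2 * req / 2),
                      class = "discretized_bath")
    msh_model(bath, vert, el)
  } else if (identical(doc$kind, "mrc")) {
    wa <- as.numeric(doc$bath_omegas)
    bad <- which(wa <= 0)
    if (length(bad))
      stop("validation error: secondary frequency at index ", bad[1],
           " is not positive", call. = FALSE)
    m <- list(f_states = length(labels),
              subspaces = ncol(vert$coords),
              omega_rc = as.numeric(doc$omega_rc),
              bath_omegas = wa,
              bath_couplings = as.numeric(doc$bath_couplings),
              primary_shifts = .as_matrix(doc$primary_shifts),
              basis_matrix = if (!is.null(doc$basis_matrix))
                .as_matrix(doc$basis_matrix) else NULL,
              electronic = el,
              bath_er = if (!is.null(doc$bath_er))
                as.numeric(doc$bath_er) else 1,
              k11 = if (!is.null(doc$k11)) as.numeric(doc$k11),
              vertices = vert)
    class(m) <- "mrc_model"
    if (is.null(m$basis_matrix))
      m$basis_matrix <- msh_to_mrc(mrc_to_msh(m))$basis_matrix
    m
  } else stop("validation error: unknown model kind '", doc$kind, "'",
              call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-column tabulated spectral density or TCF
#'
#' Delimited text with a comment header such as `# omega_cm-1 J_au` or
#' `# t_fs C_au2`; lines starting with `#` are skipped and units in the
#' recognized headers are converted to atomic units.
#'
#' @param path input file.
#' @param what `"spectral"` (returns a tabulated [spectral_density()]) or
#'   `"tcf"` (returns times/values in a.u.; combine with [gap_tcf()]).
#' @param beta inverse temperature for `what = "tcf"` (a.u.).
#' @return see `what`.
#' @export
read_table2 <- function(path, what = c("spectral", "tcf"), beta = NULL) {
  what <- match.arg(what)
  lines <- readLines(path)
  dat <- utils::read.table(text = lines[!grepl("^\\s*#", lines)],
                           col.names = c("x", "y"))
  if (what == "spectral") {
    hdr <- grepl("omega_cm-1", lines[grepl("^\\s*#", lines)])
    x <- if (any(hdr)) to_au(dat$x, "cm-1") else dat$x
    spectral_density("tabulated", table = cbind(x, dat$y))
  } else {
    if (is.null(beta)) stop("beta required for a TCF table", call. = FALSE)
    hdr <- grepl("t_fs", lines[grepl("^\\s*#", lines)])
    x <- if (any(hdr)) to_au(dat$x, "fs") else dat$x
    gap_tcf(x, dat$y, beta)
  }
}

#' Write a population trace as columnar text
#'
#' @param trace a `"population_trace"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "population_trace"))
  cfg <- trace$config
  hdr <- sprintf("# mrckit population trace | method=%s n_traj=%d seed=%d dt_fs=%g",
                 trace$method, trace$n_traj, cfg$seed, cfg$dt)
  df <- data.frame(time_fs = trace$times)
  p <- as.data.frame(trace$pops); names(p) <- paste0("sigma_", seq_len(ncol(p)))
  y <- as.data.frame(trace$rc_mean); names(y) <- paste0("y", seq_len(ncol(y)))
  df <- cbind(df, p, y)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 12), con, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}
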