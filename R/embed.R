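## Distance-geometry embedding of pairwise reorganization energies.
##
## The F(F-1)/2 reorganization energies E_r^(XY) act as squared distances
## between the potential-minimum positions of the F electronic states.  An
## embeddable matrix admits F vertices in F-1 dimensions; vertex 1 sits at
## the origin and vertex X occupies only the first X-1 dimensions
## (lower-triangular, Cholesky-style anchoring).

#' Pairwise reorganization-energy matrix
#'
#' @param values symmetric F x F matrix with zero diagonal and nonnegative
#'   off-diagonal entries (a.u. unless `unit` given).
#' @param labels optional state names.
#' @param unit energy unit of `values` (converted to a.u. internally).
#' @return object of class `"reorg_matrix"`.
#' @export
reorg_matrix <- function(values, labels = NULL, unit = "au") {
  values <- as.matrix(values)
  f <- nrow(values)
  if (f < 2 || ncol(values) != f)
    stop("need a square matrix with F >= 2", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12 * max(1, max(abs(values))))
    stop("reorganization matrix must be symmetric", call. = FALSE)
  if (any(diag(values) != 0))
    stop("reorganization matrix must have a zero diagonal", call. = FALSE)
  if (any(values < 0))
    stop("reorganization energies must be nonnegative", call. = FALSE)
  values <- to_au((values + t(values)) / 2, unit)
  if (is.null(labels)) labels <- paste0("S", seq_len(f))
  structure(list(f_states = f, values = values, labels = labels),
            class = "reorg_matrix")
}

#' @export
print.reorg_matrix <- function(x, ...) {
  cat("Pairwise reorganization energies for", x$f_states, "states (kcal/mol):\n")
  m <- from_au(x$values, "kcal/mol")
  dimnames(m) <- list(x$labels, x$labels)
  print(round(m, 4))
  invisible(x)
}

## Triangle-inequality diagnostic on sqrt(E_r): quoted in embedding errors.
.triangle_violations <- function(er) {
  d <- sqrt(er$values); f <- nrow(d); out <- character(0)
  for (x in 1:f) for (y in 1:f) for (z in 1:f)
    if (x != y && y != z && x != z && d[x, z] > d[x, y] + d[y, z] + 1e-12)
      out <- c(out, sprintf("sqrt(Er[%d,%d]) > sqrt(Er[%d,%d]) + sqrt(Er[%d,%d])",
                            x, z, x, y, y, z))
  unique(out)
}

#' Embed a reorganization matrix as polyhedron vertices
#'
#' Builds the Gram matrix \eqn{G_{XY} = (E_r^{(1X)} + E_r^{(1Y)} -
#' E_r^{(XY)})/2} over states X, Y >= 2 (state 1 anchored at the origin) and
#' returns its lower-triangular factor: F vertex rows in F-1 columns with
#' units of sqrt(energy), vertex X nonzero only in its first X-1
#' coordinates and positive diagonal entries.  All pairwise squared vertex
#' distances reproduce E_r^(XY).
#'
#' @param er a [reorg_matrix()].
#' @param tol relative eigenvalue clipping tolerance: Gram eigenvalues in
#'   `(-tol * max_eig, 0)` are clipped to zero with a warning; anything more
#'   negative is treated according to `on_defect`.
#' @param on_defect `"error"` (default): a Gram eigenvalue below the
#'   tolerance is a hard error naming the offending eigenvalue -- no silent
#'   projection.  `"clip"`: proceed with a sequential clamped Cholesky
#'   factorization (negative pivots set to zero), the classic
#'   distance-geometry treatment of mutually inconsistent distance
#'   estimates; earlier-anchored vertices are unaffected, later distances
#'   deviate, and a warning reports the residual.  Real pairwise
#'   reorganization energies estimated independently from separate
#'   simulations need not be exactly Euclidean-consistent.
#' @return object of class `"polyhedron_vertices"`: list with `coords`
#'   (F x (F-1) matrix) and `f_states`.
#' @export
embed_polyhedron <- function(er, tol = 1e-8, on_defect = c("error", "clip")) {
  stopifnot(inherits(er, "reorg_matrix"))
  on_defect <- match.arg(on_defect)
  f <- er$f_states
  e <- er$values
  G <- matrix(0, f - 1, f - 1)
  for (x in 2:f) for (y in 2:f)
    G[x - 1, y - 1] <- (e[1, x] + e[1, y] - e[x, y]) / 2
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam_max <- max(eg$values, 0)
  neg <- eg$values < -tol * max(lam_max, .Machine$double.xmin)
  if (any(neg) && on_defect == "error") {
    tri <- .triangle_violations(er)
    stop(sprintf(paste0(
      "reorganization matrix is not embeddable: Gram eigenvalue %.6g ",
      "(limit %.3g).%s"), min(eg$values), -tol * lam_max,
      if (length(tri)) paste0(" Triangle-inequality diagnostics: ",
                              paste(tri, collapse = "; "))
      else ""), call. = FALSE)
  }
  if (any(eg$values < 0) && !any(neg))
    warning("small negative Gram eigenvalues clipped to zero")
  ## lower-triangular semidefinite Cholesky with clipping of round-off
  L <- matrix(0, f - 1, f - 1)
  A <- (G + t(G)) / 2
  for (k in seq_len(f - 1)) {
    dk <- A[k, k] - sum(L[k, seq_len(k - 1)]^2)
    if (dk <= 0) { L[k, k] <- 0; next }
    L[k, k] <- sqrt(dk)
    if (k < f - 1) {
      rows <- (k + 1):(f - 1)
      if (k > 1) {
        L[rows, k] <- (A[rows, k] - L[rows, seq_len(k - 1), drop = FALSE] %*%
                         L[k, seq_len(k - 1)]) / L[k, k]
      } else {
        L[rows, k] <- A[rows, k] / L[k, k]
      }
    }
  }
  coords <- rbind(rep(0, f - 1), L)
  rownames(coords) <- er$labels
  ## verify the restriction set
  dist2 <- as.matrix(stats::dist(coords))^2
  rel <- abs(dist2 - e) / pmax(abs(e), max(e, .Machine$double.xmin))
  if (any(e > 0) && max(rel[e > 0]) > 1e-6)
    warning(sprintf(paste0("embedded distances deviate from the input ",
                           "matrix by up to %.3g relative (clamped ",
                           "factorization of an inconsistent or ",
                           "rank-deficient Gram matrix)"), max(rel[e > 0])))
  structure(list(coords = coords, f_states = f), class = "polyhedron_vertices")
}

#' @export
print.polyhedron_vertices <- function(x, ...) {
  cat("Polyhedron vertices (", x$f_states, " states in ",
      x$f_states - 1, " dimensions, sqrt(hartree)):\n", sep = "")
  print(signif(x$coords, 6))
  invisible(x)
}
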