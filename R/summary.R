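#' Summarize an MSH model
#'
#' Reports the state energetics, the recomputed pairwise reorganization
#' matrix (a self-consistency check of the embedded shifts) and the
#' reaction-coordinate frequency of the exact MRC transform.
#'
#' @param object an `"msh_model"`.
#' @param ... unused.
#' @return the input, invisibly.
#' @export
summary.msh_model <- function(object, ...) {
  print(object)
  cat("\nEnergy minima (eV):\n")
  eps <- from_au(object$electronic$epsilons, "ev")
  names(eps) <- object$electronic$labels
  print(round(eps, 4))
  cat("\nRecomputed pairwise reorganization energies (kcal/mol):\n")
  m <- from_au(model_reorg_matrix(object), "kcal/mol")
  dimnames(m) <- list(object$electronic$labels, object$electronic$labels)
  print(round(m, 4))
  Om <- primary_mode(object$bath)$Omega
  cat(sprintf("\nPrimary (reaction-coordinate) frequency: %.2f cm^-1\n",
              from_au(Om, "cm-1")))
  invisible(object)
}

#' Summarize an MRC model
#'
#' @param object an `"mrc_model"`.
#' @param ... unused.
#' @return the input, invisibly.
#' @export
summary.mrc_model <- function(object, ...) {
  print(object)
  cat(sprintf("  secondary frequency range: %.2f .. %.2f cm^-1\n",
              from_au(min(object$bath_omegas), "cm-1"),
              from_au(max(object$bath_omegas), "cm-1")))
  cat(sprintf("  coupling-weighted bath reorganization sum c^2/(2 w^2): %.3g a.u.\n",
              sum(object$bath_couplings^2 / (2 * object$bath_omegas^2))))
  cat("\nPrimary-mode shifts S^(i,X) (a.u.):\n")
  print(signif(object$primary_shifts, 6))
  invisible(object)
}
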