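# Alignment-tensor (Saupe matrix) back-calculation for a rigid structure:
# plain linear least squares on the 5 independent tensor components, no
# time-averaging of tensor elements or couplings.

#' Alignment tensor from its 5 independent components
#'
#' The order (Saupe) matrix is symmetric and traceless, hence determined by
#' the five components `(Sxx, Syy, Sxy, Sxz, Syz)` with `Szz = -Sxx - Syy`.
#'
#' @param s Numeric vector of length 5: `Sxx, Syy, Sxy, Sxz, Syz`.
#' @return Object of class `alignment_tensor`: list with `s` (the 5
#'   components) and `S` (the full symmetric traceless 3x3 matrix).
#' @export
alignment_tensor <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 5 || any(!is.finite(s))) stop("s must be 5 finite numbers")
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3, byrow = TRUE)
  structure(list(s = s, S = S), class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("Alignment tensor (Saupe matrix), 5 independent components\n")
  cat(sprintf("  Sxx=%.4g Syy=%.4g Sxy=%.4g Sxz=%.4g Syz=%.4g\n",
              x$s[1], x$s[2], x$s[3], x$s[4], x$s[5]))
  ev <- eigen(x$S, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  eigenvalues: %.4g %.4g %.4g\n", ev[1], ev[2], ev[3]))
  invisible(x)
}

#' Design matrix of the alignment-tensor least-squares problem
#'
#' Row k carries the coupling's effective prefactor times the quadratic-form
#' coefficients of the unit bond vector, so that `A %*% s` is the predicted
#' coupling in Hz for tensor components `s = (Sxx, Syy, Sxy, Sxz, Syz)`:
#' `A[k, ] = scale_Hz * (ux^2 - uz^2, uy^2 - uz^2, 2 ux uy, 2 ux uz, 2 uy uz)`.
#' Rows are even in `u`, so the sign convention of the bond vectors is
#' immaterial.
#'
#' @param vectors An `rdc_vectors` table (see [extract_rdc_vectors()]).
#' @return Numeric matrix, one row per vector, 5 columns.
#' @export
build_design_matrix <- function(vectors) {
  ux <- vectors$ux; uy <- vectors$uy; uz <- vectors$uz
  A <- cbind(ux^2 - uz^2, uy^2 - uz^2, 2 * ux * uy, 2 * ux * uz, 2 * uy * uz)
  A * vectors$scale_Hz
}

#' Fit the alignment tensor to target RDCs
#'
#' Solves the unweighted linear least-squares problem
#' `min_s sum_k (D_k(s) - D0_k)^2` over the restrained targets by SVD
#' pseudo-inverse (singular values below 1e-10 of the largest treated as
#' zero; rank deficiency gives the minimum-norm solution with a warning).
#' Predictions are returned for all vectors, restrained or not.
#'
#' @param vectors An `rdc_vectors` table, index-aligned with `targets`.
#' @param targets An `rdc_targets` table; at least 5 rows must have
#'   `restrained = TRUE`.
#' @return List of class `at_fit`: `tensor` (an [alignment_tensor()]),
#'   `predicted` (Hz, all vectors), `rank`, `residual_rms` (Hz, restrained
#'   subset).
#' @export
fit_alignment_tensor <- function(vectors, targets) {
  if (nrow(vectors) != nrow(targets)) stop("vectors and targets must be index-aligned")
  use <- which(targets$restrained)
  if (length(use) < 5) stop("need at least 5 restrained targets to fit 5 tensor components")
  A <- build_design_matrix(vectors)
  sv <- svd(A[use, , drop = FALSE])
  keep <- sv$d > 1e-10 * sv$d[1]
  rank <- sum(keep)
  if (rank < 5) {
    warning("design matrix rank ", rank, " < 5; returning the minimum-norm solution")
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  s <- sv$v %*% (dinv * crossprod(sv$u, targets$D0[use]))
  tensor <- alignment_tensor(drop(s))
  pred <- drop(A %*% tensor$s)
  structure(list(tensor = tensor, predicted = pred, rank = rank,
                 residual_rms = sqrt(mean((pred[use] - targets$D0[use])^2))),
            class = "at_fit")
}

#' @export
print.at_fit <- function(x, ...) {
  cat("Alignment-tensor least-squares fit\n")
  cat(sprintf("  rank %d, restrained-residual RMS %.4g Hz, %d predicted couplings\n",
              x$rank, x$residual_rms, length(x$predicted)))
  print(x$tensor)
  invisible(x)
}

#' Predict RDCs from an alignment tensor
#'
#' `D_k = scale_Hz_k * u_k' S u_k` for each bond vector; invariant under
#' `u -> -u` and under global translation of the structure, and covariant
#' under rotation (`S -> Q S Q'`).
#'
#' @param tensor An [alignment_tensor()].
#' @param vectors An `rdc_vectors` table.
#' @return Numeric vector of couplings in Hz.
#' @export
predict_rdc <- function(tensor, vectors) {
  drop(build_design_matrix(vectors) %*% tensor$s)
}
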