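# Evaluation metrics and diagnostics: RMSD families, deviation counts,
# orientation distributions with magic-angle detection, backbone
# superposition, hydrogen-bond detection.

#' RMSD metrics between calculated and target RDCs
#'
#' Root-mean-square difference over all couplings (RMSD), over the restrained
#' subset (rRMSD) and the unrestrained subset (urRMSD), plus the count of
#' deviations strictly larger than 3 Hz (`n_dev`, the half-width of the
#' flat bottom plus 1 Hz; smaller deviations are considered insignificant)
#' and the count of sign disagreements (`n_dev_s`; an exact zero matches
#' either sign). The partition identity
#' `N * RMSD^2 = N_r * rRMSD^2 + N_ur * urRMSD^2` holds by construction.
#'
#' @param calc Calculated couplings, Hz (index-aligned with `targets`).
#' @param targets An `rdc_targets` table.
#' @param dev_threshold Deviation threshold in Hz (default 3).
#' @return List of class `rdc_metrics`: `rmsd`, `rrmsd`, `urrmsd` (Hz; `NA`
#'   for an empty subset), `n_dev`, `n_dev_s`, `n`, `n_restrained`,
#'   `deviations` (per-RDC data.frame).
#' @export
rmsd_metrics <- function(calc, targets, dev_threshold = 3) {
  if (length(calc) == 0 || nrow(targets) == 0) stop("empty input")
  if (length(calc) != nrow(targets)) stop("calc and targets must be index-aligned")
  dev <- calc - targets$D0
  r <- targets$restrained
  sgn_mismatch <- calc * targets$D0 < 0  # zero matches either sign
  out <- list(
    rmsd = sqrt(mean(dev^2)),
    rrmsd = if (any(r)) sqrt(mean(dev[r]^2)) else NA_real_,
    urrmsd = if (any(!r)) sqrt(mean(dev[!r]^2)) else NA_real_,
    n_dev = sum(abs(dev) > dev_threshold),
    n_dev_s = sum(sgn_mismatch),
    n = length(calc),
    n_restrained = sum(r),
    deviations = data.frame(residue = targets$residue, class = targets$class,
                            D0 = targets$D0, D = calc, dev = dev,
                            restrained = r,
                            flagged = abs(dev) > dev_threshold,
                            sign_flip = sgn_mismatch)
  )
  class(out) <- "rdc_metrics"
  out
}

#' @export
print.rdc_metrics <- function(x, ...) {
  cat(sprintf("RDC metrics over %d couplings (%d restrained)\n", x$n, x$n_restrained))
  cat(sprintf("  RMSD %.2f Hz | rRMSD %.2f Hz | urRMSD %.2f Hz | N_dev %d | N_dev,s %d\n",
              x$rmsd, x$rrmsd, x$urrmsd, x$n_dev, x$n_dev_s))
  invisible(x)
}

#' Cross RMSD between two sets of calculated couplings
#'
#' Used for method-vs-method (AT vs HRS), restraint-set-vs-restraint-set and
#' structure-vs-structure comparisons.
#'
#' @param setA,setB Couplings in Hz, equal length.
#' @return RMSD in Hz.
#' @export
cross_rmsd <- function(setA, setB) {
  if (length(setA) != length(setB)) stop("length mismatch between the two sets")
  sqrt(mean((setA - setB)^2))
}

#' Orientation distribution of the magnetic-field vector with magic-angle check
#'
#' Histograms the angle theta between each sampled mfv orientation and one or
#' more reference vectors in the molecule, weighting each sample by
#' `1/sin(theta)` (the isotropic density), so that a uniform rotational
#' distribution gives a flat histogram. A peak in the weighted histogram near
#' a magic angle (54.74 or 125.26 degrees) signals improper, restraint-induced
#' rotational sampling.
#'
#' @param traj Matrix of sampled unit vectors (rows), e.g. `run_hrs()$traj`.
#' @param ref_vectors Matrix of reference vectors (rows; normalized
#'   internally), e.g. helix-axis vectors connecting two CA atoms.
#' @param bin_deg Histogram bin width, degrees (default 2).
#' @param window_deg Half-width of the magic-angle window, degrees (default 5).
#' @param peak_factor Flag threshold: a magic-angle bin exceeding this multiple
#'   of the mean bin density (default 1.5).
#' @param min_sin Samples with `sin(theta)` below this are dropped from the
#'   weighting (default 1e-6).
#' @return List of class `theta_distribution`: `breaks` (deg), `density`
#'   (matrix, one column per reference vector, each column summing to 1),
#'   `flags` (per reference vector), `flag` (any).
#' @export
theta_distribution <- function(traj, ref_vectors, bin_deg = 2, window_deg = 5,
                               peak_factor = 1.5, min_sin = 1e-6) {
  if (is.null(traj) || nrow(traj) == 0) stop("empty orientation trajectory")
  ref_vectors <- rbind(ref_vectors)
  refs <- ref_vectors / sqrt(rowSums(ref_vectors^2))
  breaks <- seq(0, 180, by = bin_deg)
  mids <- breaks[-1] - bin_deg / 2
  magic <- c(acos(1 / sqrt(3)), pi - acos(1 / sqrt(3))) * 180 / pi
  in_window <- outer(mids, magic, function(m, g) abs(m - g) <= window_deg)
  dens <- matrix(0, length(mids), nrow(refs))
  flags <- logical(nrow(refs))
  for (j in seq_len(nrow(refs))) {
    ct <- pmin(1, pmax(-1, drop(traj %*% refs[j, ])))
    th <- acos(ct) * 180 / pi
    st <- sin(acos(ct))
    keep <- st >= min_sin
    w <- 1 / st[keep]
    h <- vapply(seq_len(length(mids)), function(i) {
      sum(w[th[keep] > breaks[i] & th[keep] <= breaks[i + 1]])
    }, numeric(1))
    h[1] <- h[1] + sum(w[th[keep] == 0])
    dens[, j] <- h / sum(h)
    flags[j] <- any(dens[in_window[, 1] | in_window[, 2], j] >
                      peak_factor * mean(dens[, j]))
  }
  structure(list(breaks = breaks, mids = mids, density = dens,
                 flags = flags, flag = any(flags)),
            class = "theta_distribution")
}

#' Superpose two structures on backbone atoms
#'
#' Optimal least-squares rigid-body superposition (Kabsch, via SVD) of
#' structure B onto structure A using the N, CA and C atoms of the given
#' residue range, followed by per-residue CA and N distances over all residues
#' common to both structures.
#'
#' @param structA,structB `rdc_structure` objects.
#' @param residues Residue range used for the fit (default 3:126, the stable
#'   core used for lysozyme comparisons).
#' @param atoms Backbone atom names used for the fit.
#' @return List of class `superposition`: `rotation` (3x3), `translation`,
#'   `rmsd` (nm, fit atoms), `per_residue` (data.frame: residue, dCA, dN in
#'   nm), and `structB_fitted`.
#' @export
superpose_backbone <- function(structA, structB, residues = 3:126,
                               atoms = c("N", "CA", "C")) {
  selA <- structA[structA$residue %in% residues & structA$atom %in% atoms, ]
  selB <- structB[structB$residue %in% residues & structB$atom %in% atoms, ]
  keyA <- paste(selA$residue, selA$atom); keyB <- paste(selB$residue, selB$atom)
  common <- intersect(keyA, keyB)
  missA <- setdiff(keyB, keyA); missB <- setdiff(keyA, keyB)
  if (length(common) < 3) {
    stop("superposition selection too small; missing atoms: ",
         paste(c(missA, missB), collapse = ", "))
  }
  A <- as.matrix(selA[match(common, keyA), c("x", "y", "z")])
  B <- as.matrix(selB[match(common, keyB), c("x", "y", "z")])
  cA <- colMeans(A); cB <- colMeans(B)
  H <- crossprod(sweep(B, 2, cB), sweep(A, 2, cA))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cA - drop(R %*% cB)
  Bfit <- sweep(tcrossprod(as.matrix(structB[, c("x", "y", "z")]), R), 2, trans, "+")
  fitted <- structB
  fitted[, c("x", "y", "z")] <- Bfit
  Bsel <- sweep(tcrossprod(B, R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((Bsel - A)^2)))
  res_common <- intersect(unique(structA$residue), unique(structB$residue))
  per_res <- do.call(rbind, lapply(res_common, function(ri) {
    d_at <- vapply(c("CA", "N"), function(at) {
      pa <- .atom_xyz(structA, ri, at)
      pb <- .atom_xyz(fitted, ri, at)
      if (is.null(pa) || is.null(pb)) NA_real_ else sqrt(sum((pa - pb)^2))
    }, numeric(1))
    data.frame(residue = ri, dCA = d_at[1], dN = d_at[2])
  }))
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 per_residue = per_res, structB_fitted = fitted),
            class = "superposition")
}

#' Detect backbone hydrogen bonds
#'
#' Geometric criterion: a backbone N-H...O=C hydrogen bond exists when the
#' hydrogen-acceptor distance is strictly less than `dist_cut` (default
#' 0.25 nm) and the donor-hydrogen-acceptor angle is strictly larger than
#' `angle_cut` (default 135 degrees).
#'
#' @param structure An `rdc_structure` with amide protons present.
#' @param dist_cut H...O distance cutoff, nm.
#' @param angle_cut N-H...O angle cutoff, degrees.
#' @return data.frame: `donor_res`, `acceptor_res`, `dist_HO` (nm),
#'   `angle_NHO` (degrees).
#' @export
detect_hbonds <- function(structure, dist_cut = 0.25, angle_cut = 135) {
  don <- structure[structure$atom == "H", ]
  acc <- structure[structure$atom == "O", ]
  out <- list()
  for (i in seq_len(nrow(don))) {
    ri <- don$residue[i]
    h <- as.numeric(don[i, c("x", "y", "z")])
    nn <- .atom_xyz(structure, ri, "N")
    if (is.null(nn)) next
    for (j in seq_len(nrow(acc))) {
      rj <- acc$residue[j]
      if (rj == ri) next
      o <- as.numeric(acc[j, c("x", "y", "z")])
      d <- sqrt(sum((h - o)^2))
      if (d >= dist_cut) next
      v1 <- nn - h; v2 <- o - h
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > angle_cut) {
        out[[length(out) + 1]] <- data.frame(donor_res = ri, acceptor_res = rj,
                                             dist_HO = d, angle_NHO = ang)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_res = integer(0), acceptor_res = integer(0),
                      dist_HO = numeric(0), angle_NHO = numeric(0)))
  }
  do.call(rbind, out)
}
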