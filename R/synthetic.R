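# Synthetic fixtures: ideal helical backbones, targets generated from a known
# alignment tensor, and artificially inverted target sequences. These give the
# package a closed verification loop (generate-then-fit recovers the tensor
# exactly for noise-free targets).

# place a new atom from three reference atoms by internal coordinates
# (bond length nm, bond angle and dihedral in degrees)
.nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), -bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an ideal polyalanine helix
#'
#' Constructs an N, CA, C, O, CB backbone with ideal bond lengths and angles
#' and the given phi/psi dihedrals (omega fixed at 180 degrees). The defaults
#' are alpha-helical (phi = -57, psi = -47), which produce the canonical
#' i -> i+4 backbone hydrogen bonds.
#'
#' @param n_residues Number of residues (>= 4).
#' @param phi,psi Backbone dihedrals in degrees.
#' @return An `rdc_structure` (without protons; see [build_amide_protons()]
#'   and [build_virtual_ha()]).
#' @export
make_helix <- function(n_residues, phi = -57, psi = -47) {
  if (n_residues < 4) stop("need at least 4 residues")
  # ideal backbone geometry (nm / degrees)
  b_NCA <- 0.1458; b_CAC <- 0.1525; b_CN <- 0.1329; b_CO <- 0.1229; b_CACB <- 0.153
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.5
  atoms <- list()
  push <- function(res, name, xyz, elem) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      atom = name, altloc = " ", resname = "ALA", chain = "A",
      residue = res, icode = " ", x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, element = elem, stringsAsFactors = FALSE)
    xyz
  }
  # seed triad for residue 1
  nn <- c(0, 0, 0)
  ca <- nn + b_NCA * c(1, 0, 0)
  cc <- .nerf_place(nn + c(0, 1, 0), nn, ca, b_CAC, a_NCAC, 52.5)
  push(1L, "N", nn, "N"); push(1L, "CA", ca, "C"); push(1L, "C", cc, "C")
  prev <- list(N = nn, CA = ca, C = cc)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      nn <- .nerf_place(prev$N, prev$CA, prev$C, b_CN, a_CACN, psi)
      ca <- .nerf_place(prev$CA, prev$C, nn, b_NCA, a_CNCA, 180)     # omega
      cc <- .nerf_place(prev$C, nn, ca, b_CAC, a_NCAC, phi)
      push(i, "N", nn, "N"); push(i, "CA", ca, "C"); push(i, "C", cc, "C")
    }
    # carbonyl O in the peptide plane: dihedral N(i)-CA(i)-C(i)-O = psi + 180
    oo <- .nerf_place(nn, ca, cc, b_CO, a_CACO, psi + 180)
    push(i, "O", oo, "O")
    # CB on the tetrahedral branch opposite the HA branch (L-configuration)
    cb <- ca + b_CACB * .tetrahedral_completion(.unit(nn - ca), .unit(cc - ca), s = -1)
    push(i, "CB", cb, "C")
    prev <- list(N = nn, CA = ca, C = cc)
  }
  df <- do.call(rbind, atoms)
  df <- df[order(df$residue, df$atom), ]
  .struct_df(df, source = sprintf("make_helix(%d, %g, %g)", n_residues, phi, psi))
}

#' Backbone dihedral angles of a structure
#'
#' @param structure An `rdc_structure`.
#' @return data.frame with `residue`, `phi`, `psi` (degrees; `NA` at the
#'   termini).
#' @export
backbone_dihedrals <- function(structure) {
  res <- sort(unique(structure$residue))
  out <- data.frame(residue = res, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(res)) {
    ri <- res[k]
    nn <- .atom_xyz(structure, ri, "N"); ca <- .atom_xyz(structure, ri, "CA")
    cc <- .atom_xyz(structure, ri, "C")
    cp <- if (k > 1) .atom_xyz(structure, res[k - 1], "C") else NULL
    nx <- if (k < length(res)) .atom_xyz(structure, res[k + 1], "N") else NULL
    if (!is.null(cp)) out$phi[k] <- .dihedral(cp, nn, ca, cc)
    if (!is.null(nx)) out$psi[k] <- .dihedral(nn, ca, cc, nx)
  }
  out
}

#' A representative synthetic alignment tensor
#'
#' Component magnitudes around 1e-4 to 1e-3, scaled so that noise-free N-HN
#' couplings on a helix span roughly +/- 30 Hz -- the scale of measured
#' backbone RDC sets in weakly aligning media.
#'
#' @return An [alignment_tensor()].
#' @export
default_tensor <- function() {
  alignment_tensor(c(4e-4, -6e-4, 3e-4, 3e-4, -2e-4))
}

#' Generate synthetic RDC targets from a known alignment tensor
#'
#' For every resolvable bond of the requested classes, the noise-free coupling
#' is the tensor prediction `scale_Hz * u' S u`; optional i.i.d. Gaussian
#' noise of standard deviation `sigma` is added. Provenance is `synthetic`.
#'
#' @param structure An `rdc_structure` with protons built.
#' @param tensor An [alignment_tensor()].
#' @param classes Bond classes to generate (default all four).
#' @param sigma Noise standard deviation, Hz (default 0).
#' @param seed Optional seed for the noise draws.
#' @return List with `targets` (an `rdc_targets` table) and `vectors` (the
#'   index-aligned `rdc_vectors`).
#' @export
synth_targets <- function(structure, tensor, classes = .known_classes,
                          sigma = 0, seed = NULL) {
  res <- sort(unique(structure$residue))
  cand <- do.call(rbind, lapply(classes, function(cl) {
    ca <- .class_atoms(cl)
    ok <- vapply(res, function(ri) {
      !is.null(.atom_xyz(structure, ri + ca$o1, ca$a1)) &&
        !is.null(.atom_xyz(structure, ri + ca$o2, ca$a2))
    }, logical(1))
    if (!any(ok)) return(NULL)
    data.frame(residue = res[ok], class = cl, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand)) stop("no resolvable bonds for the requested classes")
  tg0 <- rdc_targets(cand$residue, cand$class, D0 = 0, provenance = "synthetic")
  vec <- extract_rdc_vectors(structure, tg0)
  D <- predict_rdc(tensor, vec)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    D <- D + stats::rnorm(length(D), 0, sigma)
  }
  tg <- rdc_targets(cand$residue, cand$class, D0 = D, provenance = "synthetic")
  list(targets = tg, vectors = vec)
}

#' Invert the sequence of target values along the backbone
#'
#' Produces an artificial restraint set by reversing the ordered list of
#' target values of a single bond class and reassigning them to the same
#' ordered residue positions (an involution that preserves the multiset of
#' values but destroys their spatial distribution).
#'
#' @param targets An `rdc_targets` table containing a single bond class.
#' @return The targets with reversed `D0` values and provenance
#'   `artificial-inverted`.
#' @export
invert_sequence <- function(targets) {
  if (length(unique(targets$class)) != 1) {
    stop("invert_sequence operates on a single bond class")
  }
  ord <- order(targets$residue)
  out <- targets
  out$D0[ord] <- rev(targets$D0[ord])
  out$provenance <- "artificial-inverted"
  out
}
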