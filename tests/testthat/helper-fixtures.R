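# Fixtures are generated in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

fixture_helix <- function(n = 12, phi = -57, psi = -47) {
  build_virtual_ha(build_amide_protons(make_helix(n, phi, psi)))
}

# tiny PDB text with one CA carrying two alternate locations
fixture_altloc_pdb <- function(occA = 0.4, occB = 0.6) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    sprintf("ATOM      2  CA AALA A   1       1.458   0.000   0.000%6.2f  0.00           C", occA),
    sprintf("ATOM      3  CA BALA A   1       1.500   0.100   0.000%6.2f  0.00           C", occB),
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# independent quaternion (Horn) superposition oracle for the Kabsch check
quaternion_fit_rmsd <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  M <- crossprod(B0, A0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  Bf <- tcrossprod(B0, R)
  sqrt(mean(rowSums((Bf - A0)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

# helix-axis reference vectors (CA(i) -> CA(j)) for orientation diagnostics
helix_axis_refs <- function(structure, ranges = list(c(2, 12), c(12, 22), c(20, 30))) {
  do.call(rbind, lapply(ranges, function(rg) {
    p1 <- structure[structure$residue == rg[1] & structure$atom == "CA", c("x", "y", "z")]
    p2 <- structure[structure$residue == rg[2] & structure$atom == "CA", c("x", "y", "z")]
    as.numeric(p2) - as.numeric(p1)
  }))
}

gamma_of <- function(label) {
  iso <- isotope_table()
  iso$gamma_over_2pi[iso$label == label]
}
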