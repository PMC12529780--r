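test_that("PDB write/read round-trips a small synthetic structure", {
  h <- make_helix(4)
  h <- h[h$residue <= 3, ]   # 3-residue fixture
  class(h) <- c("rdc_structure", "data.frame")
  path <- tempfile(fileext = ".pdb")
  write_pdb(h, path)
  s <- read_pdb(path)
  expect_equal(length(unique(s$residue)), 3)
  key <- function(d) paste(d$residue, d$atom)
  expect_setequal(key(s), key(h))
  m <- match(key(h), key(s))
  # PDB stores 0.001 Angstrom = 1e-4 nm precision
  expect_lt(max(abs(as.matrix(s[m, c("x", "y", "z")]) -
                      as.matrix(h[, c("x", "y", "z")]))), 1e-4)
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties to A", {
  s <- read_pdb(fixture_altloc_pdb(occA = 0.4, occB = 0.6))
  ca <- s[s$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$altloc, "B")
  expect_equal(ca$occupancy, 0.6)
  s2 <- read_pdb(fixture_altloc_pdb(occA = 0.5, occB = 0.5))
  expect_equal(s2[s2$atom == "CA", "altloc"], "A")
})

test_that("amide protons sit on the negative bisector at 0.1 nm, in plane", {
  h <- build_amide_protons(make_helix(6))
  res <- 2:6  # N-terminal residue has no proton
  expect_false(any(h$atom == "H" & h$residue == 1))
  for (ri in res) {
    nn <- as.numeric(h[h$residue == ri & h$atom == "N", c("x", "y", "z")])
    hh <- as.numeric(h[h$residue == ri & h$atom == "H", c("x", "y", "z")])
    cp <- as.numeric(h[h$residue == ri - 1 & h$atom == "C", c("x", "y", "z")])
    ca <- as.numeric(h[h$residue == ri & h$atom == "CA", c("x", "y", "z")])
    expect_equal(sqrt(sum((hh - nn)^2)), 0.1, tolerance = 1e-12)
    # coplanar with C'(i-1), N, CA
    nrm <- rdcalc:::pracma_cross(cp - nn, ca - nn)
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(sum((hh - nn) * nrm)), 1e-9)
    # bisector: equal angles to the two neighbours
    a1 <- acos(sum((hh - nn) * (cp - nn)) / (0.1 * sqrt(sum((cp - nn)^2))))
    a2 <- acos(sum((hh - nn) * (ca - nn)) / (0.1 * sqrt(sum((ca - nn)^2))))
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("virtual HA completes the tetrahedron at 0.109 nm", {
  h <- build_virtual_ha(make_helix(6))
  for (ri in 2:5) {
    at <- function(a) as.numeric(h[h$residue == ri & h$atom == a, c("x", "y", "z")])
    ca <- at("CA"); ha <- at("HA")
    expect_equal(sqrt(sum((ha - ca)^2)), 0.109, tolerance = 1e-12)
  }
  # ideal tetrahedral input: HA equidistant in angle from the three ligands
  tet <- 109.4712206 * pi / 180
  u1 <- c(0, 0, 1)
  u2 <- c(sin(tet), 0, cos(tet))
  u3 <- c(sin(tet) * cos(2 * pi / 3), sin(tet) * sin(2 * pi / 3), cos(tet))
  ideal <- data.frame(
    atom = c("N", "CA", "C", "CB"), altloc = " ", resname = "ALA", chain = "A",
    residue = 1L, icode = " ",
    x = c(0.1458 * u1[1], 0, 0.1525 * u2[1], 0.153 * u3[1]),
    y = c(0.1458 * u1[2], 0, 0.1525 * u2[2], 0.153 * u3[2]),
    z = c(0.1458 * u1[3], 0, 0.1525 * u2[3], 0.153 * u3[3]),
    occupancy = 1, element = c("N", "C", "C", "C"), stringsAsFactors = FALSE)
  class(ideal) <- c("rdc_structure", "data.frame")
  w <- build_virtual_ha(ideal)
  ha <- as.numeric(w[w$atom == "HA", c("x", "y", "z")]) / 0.109
  angs <- sapply(list(u1, u2, u3), function(u) acos(sum(ha * u)))
  expect_lt(max(angs) - min(angs), 1e-8)
  expect_equal(angs[1], tet, tolerance = 1e-6)
})

test_that("HA construction is equivariant under mirroring", {
  h <- make_helix(5)
  m <- h
  m$x <- -m$x
  class(m) <- class(h)
  ha1 <- build_virtual_ha(h)
  ha2 <- build_virtual_ha(m)
  a1 <- ha1[ha1$atom == "HA", c("x", "y", "z")]
  a2 <- ha2[ha2$atom == "HA", c("x", "y", "z")]
  expect_equal(a2$x, -a1$x, tolerance = 1e-12)
  expect_equal(a2$y, a1$y, tolerance = 1e-12)
  expect_equal(a2$z, a1$z, tolerance = 1e-12)
})

test_that("glycine HA uses a tetrahedral completion without CB", {
  h <- make_helix(5)
  h <- h[!(h$residue == 3 & h$atom == "CB"), ]
  h$resname[h$residue == 3] <- "GLY"
  class(h) <- c("rdc_structure", "data.frame")
  w <- build_virtual_ha(h)
  at <- function(a) as.numeric(w[w$residue == 3 & w$atom == a, c("x", "y", "z")])
  ca <- at("CA"); ha <- at("HA")
  u <- (ha - ca) / 0.109
  un <- (at("N") - ca); un <- un / sqrt(sum(un^2))
  uc <- (at("C") - ca); uc <- uc / sqrt(sum(uc^2))
  expect_equal(sum(u * un), sum(u * uc), tolerance = 1e-9)
  expect_equal(sum(u * un), -1 / 3, tolerance = 1e-9)
})

test_that("extracted RDC vectors are unit, correctly spanned and equivariant", {
  h <- fixture_helix(8)
  tg <- rdc_targets(rep(4:6, each = 4), rep(c("N-HN", "CA-HA", "CA-C", "C-N"), 3),
                    rep(1, 12))
  v <- extract_rdc_vectors(h, tg)
  expect_equal(sqrt(v$ux^2 + v$uy^2 + v$uz^2), rep(1, 12), tolerance = 1e-9)
  expect_equal(v$b[v$class == "N-HN"], rep(0.1, 3), tolerance = 1e-12)
  expect_equal(v$b[v$class == "CA-HA"], rep(0.109, 3), tolerance = 1e-12)
  # C-N spans residues i-1/i: its length is the peptide bond of the build
  expect_equal(v$b[v$class == "C-N"], rep(0.1329, 3), tolerance = 1e-9)
  # rotation equivariance
  set.seed(7)
  Q <- random_rotation()
  hr <- h
  hr[, c("x", "y", "z")] <- as.matrix(h[, c("x", "y", "z")]) %*% t(Q) + 0.5
  class(hr) <- class(h)
  vr <- extract_rdc_vectors(hr, tg)
  expect_equal(as.matrix(vr[, c("ux", "uy", "uz")]),
               as.matrix(v[, c("ux", "uy", "uz")]) %*% t(Q),
               tolerance = 1e-9, ignore_attr = TRUE)
  # unresolvable targets are reported by name
  expect_error(extract_rdc_vectors(h, rdc_targets(99, "N-HN", 1)),
               "N-HN @ residue 99")
})

test_that("RDC tables merge duplicate measurements and reject bad input", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tbond_class\tD0_Hz\tD0_Hz_2",
               "5\tCA-HA\t10.0\t12.0",
               "6\tCA-HA\t-3.5\t",
               "7\tN-HN\t4.25\t"), path)
  tg <- read_rdc_table(path)
  expect_equal(tg$D0, c(11.0, -3.5, 4.25))
  expect_equal(tg$provenance, c("averaged-duplicate", "measured", "measured"))

  writeLines(c("residue\tbond_class\tD0_Hz", "5\tCA-HA\t1", "5\tCA-HA\t2"), path)
  expect_error(read_rdc_table(path), "duplicate")
  writeLines(c("residue\tbond_class\tD0_Hz", "5\tXX\t1"), path)
  expect_error(read_rdc_table(path), "unknown bond_class at line\\(s\\) 2")
  writeLines(c("residue\tbond_class\tD0_Hz", "5\tCA-HA\tabc"), path)
  expect_error(read_rdc_table(path), "non-numeric D0_Hz at line\\(s\\) 2")

  # write/read round-trip
  tg2 <- rdc_targets(1:4, "N-HN", c(-8.88, 0, 16.06, 3.3))
  p2 <- tempfile(fileext = ".tsv")
  write_rdc_table(tg2, p2)
  back <- read_rdc_table(p2)
  expect_equal(back$D0, tg2$D0)
})
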