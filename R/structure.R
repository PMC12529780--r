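# PDB structure handling: reading, proton construction, RDC vector extraction.
# Coordinates are stored in nm throughout (PDB Angstrom converted on read).

.struct_df <- function(df, source = "memory") {
  rownames(df) <- NULL
  class(df) <- c("rdc_structure", "data.frame")
  attr(df, "source") <- source
  df
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the first model of a PDB file. Heteroatoms and waters
#' are dropped, a single chain is kept (by default the first protein chain in
#' the file), and alternate conformations are resolved by keeping the location
#' with the highest occupancy (ties broken in favour of altloc "A", then
#' alphabetically). Coordinates are converted from Angstrom to nm.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to keep; `NULL` (default) keeps the first
#'   chain encountered.
#' @param altloc_policy Only `"occupancy"` is implemented (highest occupancy,
#'   ties to "A").
#' @return An `rdc_structure`: a data.frame with columns `residue`, `icode`,
#'   `resname`, `atom`, `x`, `y`, `z` (nm), `occupancy`, `altloc`, `element`,
#'   `chain`.
#' @export
read_pdb <- function(path, chain = NULL, altloc_policy = "occupancy") {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  altloc_policy <- match.arg(altloc_policy, "occupancy")
  lines <- readLines(path, warn = FALSE)
  # first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1)]
  rec <- lines[startsWith(lines, "ATOM  ")]
  if (!length(rec)) stop("no ATOM records found in ", path)
  fx <- function(from, to) trimws(substring(rec, from, to))
  df <- data.frame(
    atom      = fx(13, 16),
    altloc    = substring(rec, 17, 17),
    resname   = fx(18, 20),
    chain     = substring(rec, 22, 22),
    residue   = as.integer(fx(23, 26)),
    icode     = substring(rec, 27, 27),
    x         = as.numeric(fx(31, 38)) / 10,
    y         = as.numeric(fx(39, 46)) / 10,
    z         = as.numeric(fx(47, 54)) / 10,
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element   = fx(77, 78),
    stringsAsFactors = FALSE
  )
  df$occupancy[is.na(df$occupancy)] <- 1
  df <- df[!(df$resname %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (is.null(chain)) chain <- df$chain[1]
  df <- df[df$chain == chain, , drop = FALSE]
  if (!nrow(df)) stop("no atoms for chain '", chain, "' in ", path)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    stop("non-finite coordinates in ", path)
  }
  # altloc resolution: keep highest occupancy per (residue, icode, atom)
  key <- paste(df$residue, df$icode, df$atom, sep = "\r")
  alt_rank <- ifelse(df$altloc %in% c(" ", ""), 0L,
                     ifelse(df$altloc == "A", 1L, 2L + match(df$altloc, LETTERS, nomatch = 25L)))
  ord <- order(key, -df$occupancy, alt_rank)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$residue, df$icode, df$atom), , drop = FALSE]
  .struct_df(df, source = path)
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_pdb()] for fixtures and round-trips: writes ATOM records
#' (coordinates converted nm to Angstrom) and a final END record.
#'
#' @param structure An `rdc_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  s <- structure
  name4 <- ifelse(nchar(s$atom) < 4, sprintf(" %-3s", s$atom), s$atom)
  lines <- sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(s)), name4,
                   ifelse(s$altloc %in% c("", " "), " ", s$altloc),
                   s$resname, ifelse(s$chain %in% c("", " "), "A", s$chain),
                   s$residue, ifelse(s$icode %in% c("", " "), " ", s$icode),
                   s$x * 10, s$y * 10, s$z * 10, s$occupancy, 0,
                   ifelse(nchar(s$element), s$element, substring(s$atom, 1, 1)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.atom_xyz <- function(structure, residue, atom) {
  i <- which(structure$residue == residue & structure$atom == atom)
  if (!length(i)) return(NULL)
  as.numeric(structure[i[1], c("x", "y", "z")])
}

.residue_list <- function(structure) {
  u <- unique(structure[, c("residue", "resname")])
  u[order(u$residue), , drop = FALSE]
}

#' Construct backbone amide protons
#'
#' Places an HN proton on each backbone nitrogen (except prolines and the
#' N-terminal residue) in the C'(i-1)-N(i)-CA(i) plane, along the negative
#' bisector of that angle at N, at 0.1 nm from N. Residues missing the needed
#' neighbour atoms are skipped with a warning.
#'
#' @param structure An `rdc_structure`.
#' @return The structure with added `H` atoms.
#' @export
build_amide_protons <- function(structure) {
  res <- .residue_list(structure)
  rows <- list()
  skipped <- integer(0)
  for (k in seq_len(nrow(res))[-1]) {
    ri <- res$residue[k]
    if (res$resname[k] == "PRO") next
    if (!is.null(.atom_xyz(structure, ri, "H"))) next
    cp <- .atom_xyz(structure, res$residue[k - 1], "C")
    nn <- .atom_xyz(structure, ri, "N")
    ca <- .atom_xyz(structure, ri, "CA")
    if (is.null(cp) || is.null(nn) || is.null(ca)) {
      skipped <- c(skipped, ri)
      next
    }
    dir <- -.unit(.unit(cp - nn) + .unit(ca - nn))
    h <- nn + 0.1 * dir
    rows[[length(rows) + 1]] <- data.frame(
      atom = "H", altloc = " ", resname = res$resname[k],
      chain = structure$chain[1], residue = ri, icode = " ",
      x = h[1], y = h[2], z = h[3], occupancy = 1, element = "H",
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("amide proton skipped for residue(s) missing neighbours: ",
            paste(skipped, collapse = ", "))
  }
  out <- rbind(structure, do.call(rbind, rows))
  out <- out[order(out$residue, out$icode, out$atom), , drop = FALSE]
  .struct_df(out, source = attr(structure, "source"))
}

# The two directions completing a tetrahedral centre given two ligand
# directions u1, u2 (unit, from the centre): d = -p*b + s*q*n with s = +/-1.
.tetrahedral_completion <- function(u1, u2, s = 1) {
  b <- .unit(u1 + u2)
  n <- .unit(c(u1[2] * u2[3] - u1[3] * u2[2],
               u1[3] * u2[1] - u1[1] * u2[3],
               u1[1] * u2[2] - u1[2] * u2[1]))
  cos_half <- sqrt((1 + sum(u1 * u2)) / 2)
  p <- (1 / 3) / cos_half
  if (p >= 1) stop("degenerate geometry: ligand directions nearly collinear")
  q <- sqrt(1 - p^2)
  -p * b + s * q * n
}

#' Construct virtual H-alpha protons
#'
#' Places a virtual HA on each CA at 0.109 nm, along the direction completing
#' the tetrahedron spanned by the N, C' and (if present) CB substituents:
#' `-(u_N + u_C' + u_CB)` normalized. For glycine (no CB) the first of the two
#' tetrahedral completion directions by a fixed chirality rule is used.
#'
#' @param structure An `rdc_structure`.
#' @return The structure with added `HA` atoms.
#' @export
build_virtual_ha <- function(structure) {
  res <- .residue_list(structure)
  rows <- list()
  for (k in seq_len(nrow(res))) {
    ri <- res$residue[k]
    if (!is.null(.atom_xyz(structure, ri, "HA"))) next
    nn <- .atom_xyz(structure, ri, "N")
    ca <- .atom_xyz(structure, ri, "CA")
    cc <- .atom_xyz(structure, ri, "C")
    if (is.null(nn) || is.null(ca) || is.null(cc)) next
    un <- .unit(nn - ca)
    uc <- .unit(cc - ca)
    if (abs(sum(un * uc)) > 1 - 1e-9) {
      stop("degenerate backbone geometry (collinear N, CA, C) at residue ", ri)
    }
    cb <- .atom_xyz(structure, ri, "CB")
    dir <- if (is.null(cb)) {
      .tetrahedral_completion(un, uc, s = 1)
    } else {
      -.unit(un + uc + .unit(cb - ca))
    }
    h <- ca + 0.109 * dir
    rows[[length(rows) + 1]] <- data.frame(
      atom = "HA", altloc = " ", resname = res$resname[k],
      chain = structure$chain[1], residue = ri, icode = " ",
      x = h[1], y = h[2], z = h[3], occupancy = 1, element = "H",
      stringsAsFactors = FALSE)
  }
  out <- rbind(structure, do.call(rbind, rows))
  out <- out[order(out$residue, out$icode, out$atom), , drop = FALSE]
  .struct_df(out, source = attr(structure, "source"))
}

# atom pair defining each bond class; residue offsets relative to the target's
# residue index i (C'-N is the peptide bond C'(i-1)-N(i))
.class_atoms <- function(class) {
  switch(class,
         "N-HN"  = list(a1 = "N",  o1 = 0L,  a2 = "H",  o2 = 0L),
         "CA-HA" = list(a1 = "CA", o1 = 0L,  a2 = "HA", o2 = 0L),
         "CA-C"  = list(a1 = "CA", o1 = 0L,  a2 = "C",  o2 = 0L),
         "C-N"   = list(a1 = "C",  o1 = -1L, a2 = "N",  o2 = 0L),
         stop("unknown bond class: ", class))
}

#' Extract unit RDC vectors for a set of targets
#'
#' For each target, the internuclear vector of its bond class is looked up in
#' the structure, normalized, and paired index-aligned with the target. The
#' actual bond length is reported (not forced to the ideal value).
#'
#' @param structure An `rdc_structure` with protons built (see
#'   [build_amide_protons()], [build_virtual_ha()]).
#' @param targets An `rdc_targets` table.
#' @return data.frame of class `rdc_vectors`: columns `residue`, `class`,
#'   `ux`, `uy`, `uz` (unit vector, molecular frame), `b` (nm), `scale_Hz`
#'   (effective prefactor `Dc * R` in Hz).
#' @export
extract_rdc_vectors <- function(structure, targets) {
  bc <- bond_classes()
  n <- nrow(targets)
  out <- data.frame(residue = targets$residue, class = targets$class,
                    ux = NA_real_, uy = NA_real_, uz = NA_real_, b = NA_real_,
                    stringsAsFactors = FALSE)
  missing <- character(0)
  for (i in seq_len(n)) {
    ca <- .class_atoms(targets$class[i])
    p1 <- .atom_xyz(structure, targets$residue[i] + ca$o1, ca$a1)
    p2 <- .atom_xyz(structure, targets$residue[i] + ca$o2, ca$a2)
    if (is.null(p1) || is.null(p2)) {
      missing <- c(missing, sprintf("%s @ residue %d", targets$class[i], targets$residue[i]))
      next
    }
    v <- p1 - p2
    b <- sqrt(sum(v * v))
    out[i, c("ux", "uy", "uz")] <- v / b
    out$b[i] <- b
  }
  if (length(missing)) {
    stop("unresolvable atoms for target(s): ", paste(missing, collapse = "; "))
  }
  out$scale_Hz <- bc$scale_Hz[match(out$class, bc$class)]
  class(out) <- c("rdc_vectors", "data.frame")
  out
}

#' Read an RDC target table (TSV)
#'
#' Expected columns: `residue`, `bond_class`, `D0_Hz` and optionally `D0_Hz_2`.
#' Rows carrying two measurement columns are merged into a single target by
#' their arithmetic mean (provenance `averaged-duplicate`); duplicated
#' (residue, class) rows are an error.
#'
#' @param path Path to the TSV file.
#' @return An `rdc_targets` table (all `restrained` flags FALSE; see
#'   [select_restraint_set()]).
#' @export
read_rdc_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("residue", "bond_class", "D0_Hz")
  if (!all(need %in% names(raw))) {
    stop("RDC table must have columns: ", paste(need, collapse = ", "))
  }
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad_cls <- !(raw$bond_class %in% .known_classes)
  if (any(bad_cls)) {
    stop("unknown bond_class at line(s) ", paste(lineno[bad_cls], collapse = ", "),
         ": ", paste(unique(raw$bond_class[bad_cls]), collapse = ", "))
  }
  d1 <- suppressWarnings(as.numeric(raw$D0_Hz))
  if (any(is.na(d1))) {
    stop("non-numeric D0_Hz at line(s) ", paste(lineno[is.na(d1)], collapse = ", "))
  }
  has2 <- "D0_Hz_2" %in% names(raw)
  if (has2) {
    blank <- is.na(raw$D0_Hz_2) | trimws(raw$D0_Hz_2) == ""
    d2 <- suppressWarnings(as.numeric(raw$D0_Hz_2))
    if (any(is.na(d2) & !blank)) {
      stop("non-numeric D0_Hz_2 at line(s) ", paste(lineno[is.na(d2) & !blank], collapse = ", "))
    }
  } else {
    blank <- rep(TRUE, nrow(raw))
    d2 <- rep(NA_real_, nrow(raw))
  }
  key <- paste(raw$residue, raw$bond_class)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, bond_class) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  D0 <- ifelse(blank, d1, (d1 + d2) / 2)
  rdc_targets(residue = as.integer(raw$residue), class = raw$bond_class, D0 = D0,
              restrained = FALSE,
              provenance = ifelse(blank, "measured", "averaged-duplicate"))
}

#' Write an RDC target table (TSV)
#'
#' @param targets An `rdc_targets` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rdc_table <- function(targets, path) {
  utils::write.table(
    data.frame(residue = targets$residue, bond_class = targets$class,
               D0_Hz = targets$D0),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
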