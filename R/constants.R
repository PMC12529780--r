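#' Physical constants used in RDC calculations
#'
#' Returns the fundamental constants entering the dipolar-coupling prefactor,
#' in SI units and in the molecular-simulation unit system used throughout the
#' package (length nm, time ps, mass u, energy kJ/mol, charge e). In that unit
#' system frequencies come out in THz; RDCs are nevertheless kept in Hz
#' everywhere in this package, with restraint force constants in
#' kJ mol^-1 Hz^-2 (the corresponding scaling is handled internally).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{mu0_si}{vacuum magnetic permeability, J s^2 C^-2 m^-1}
#'     \item{mu0_sim}{the same in kJ mol^-1 ps^2 e^-2 nm^-1}
#'     \item{h_si}{Planck constant, J s}
#'     \item{h_sim}{the same in kJ mol^-1 ps}
#'     \item{kB}{Boltzmann constant, kJ mol^-1 K^-1}
#'     \item{avogadro, e_charge}{conversion constants (mol^-1, C)}
#'   }
#' @examples
#' rdc_constants()$kB
#' @export
rdc_constants <- function() {
  NA_   <- 6.02214076e23    # mol^-1
  e     <- 1.602176634e-19  # C
  mu0   <- 4 * pi * 1e-7    # J s^2 C^-2 m^-1
  h     <- 6.62607015e-34   # J s
  # J -> kJ/mol: NA/1000; s^2 -> ps^2: 1e24; C^-2 -> e^-2: e^2; m^-1 -> nm^-1: 1e-9
  list(
    mu0_si   = mu0,
    mu0_sim  = mu0 * (NA_ / 1000) * 1e24 * e^2 * 1e-9,
    h_si     = h,
    h_sim    = h * (NA_ / 1000) * 1e12,
    kB       = 8.31446261815324e-3,
    avogadro = NA_,
    e_charge = e
  )
}

#' Gyromagnetic-ratio table
#'
#' Reads the editable isotope table shipped with the package (or a user-supplied
#' TSV with columns `label` and `gamma_over_2pi_MHz_per_T`). Signs are physical:
#' 15N is negative, 1H/13C positive, and they propagate into the sign of the
#' dipolar prefactor.
#'
#' @param path Path to a TSV isotope table; default: the table in
#'   `inst/extdata/isotopes.tsv`.
#' @return data.frame with columns `label`, `gamma_over_2pi` (MHz/T).
#' @examples
#' isotope_table()
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "isotopes.tsv", package = "rdcalc")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "gamma_over_2pi_MHz_per_T") %in% names(tab))) {
    stop("isotope table must have columns 'label' and 'gamma_over_2pi_MHz_per_T'")
  }
  data.frame(label = as.character(tab$label),
             gamma_over_2pi = as.numeric(tab$gamma_over_2pi_MHz_per_T),
             stringsAsFactors = FALSE)
}

.gamma_of <- function(label, isotopes = isotope_table()) {
  i <- match(label, isotopes$label)
  if (anyNA(i)) stop("unknown isotope label(s): ", paste(label[is.na(i)], collapse = ", "))
  isotopes$gamma_over_2pi[i]
}

#' Dipolar-coupling prefactor
#'
#' The distance- and isotope-dependent constant setting the maximal (kHz) scale
#' of a dipolar coupling between two nuclei at reference separation `r0`:
#' \deqn{D^c = -\frac{\mu_0 h}{2\pi (r^0)^3}\,\frac{\gamma_1}{2\pi}\frac{\gamma_2}{2\pi}}
#' The sign is minus the sign of the product of the gyromagnetic ratios, so an
#' 15N-1H pair has a positive prefactor (+24.36 kHz at 0.1 nm) while 13C-1H is
#' negative (-46.66 kHz at 0.109 nm).
#'
#' @param gamma1_over_2pi,gamma2_over_2pi Gyromagnetic ratios over 2 pi, MHz/T
#'   (signed); see [isotope_table()].
#' @param r0 Reference internuclear distance in nm; must be positive.
#' @return Prefactor in kHz.
#' @examples
#' iso <- isotope_table()
#' g <- function(l) iso$gamma_over_2pi[iso$label == l]
#' dipolar_prefactor(g("15N"), g("1H"), 0.1)    # ~ +24.36
#' dipolar_prefactor(g("13C"), g("1H"), 0.109)  # ~ -46.66
#' @export
dipolar_prefactor <- function(gamma1_over_2pi, gamma2_over_2pi, r0) {
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("r0 must be positive")
  cst <- rdc_constants()
  pref <- -cst$mu0_si * cst$h_si / (2 * pi * (r0 * 1e-9)^3)  # J^2 s^3 C^-2 m^-4
  d_hz <- pref * (gamma1_over_2pi * 1e6) * (gamma2_over_2pi * 1e6)
  d_hz / 1e3
}

#' Radial factor of a dipolar coupling
#'
#' `(r0 / b)^3`: the cubed ratio of the reference length to the actual bond
#' length. With the conventional reference r0 = 0.1 nm this gives 1.0 for N-HN
#' (0.1 nm), 0.7722 for CA-HA (0.109 nm), 0.2792 for CA-C (0.153 nm) and
#' 0.4251 for C-N (0.133 nm).
#'
#' @param b Bond (internuclear) length, nm; positive.
#' @param r0 Reference length, nm; positive (default 0.1).
#' @return Dimensionless radial factor.
#' @examples
#' radial_factor(0.153, 0.1)  # 0.2792
#' @export
radial_factor <- function(b, r0 = 0.1) {
  if (any(!is.finite(b)) || any(b <= 0)) stop("b must be positive")
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("r0 must be positive")
  (r0 / b)^3
}

#' Second-order Legendre polynomial P2
#'
#' `P2(x) = (3 x^2 - 1) / 2` with `x = cos(theta)`. Zero at the magic angles
#' (|cos theta| = 3^-1/2, i.e. 54.74 and 125.26 degrees), 1 at 0/180 degrees,
#' -1/2 at 90 degrees, and symmetric about 90 degrees. Inputs are clamped to
#' [-1, 1] within a 1e-12 tolerance; values further outside raise an error
#' (they indicate an unnormalized dot product upstream).
#'
#' @param cos_theta Cosine(s) of the angle between the internuclear vector and
#'   the magnetic-field direction.
#' @return P2 value(s) in [-0.5, 1].
#' @examples
#' legendre_p2(1 / sqrt(3))  # 0 at the magic angle
#' @export
legendre_p2 <- function(cos_theta) {
  if (any(!is.finite(cos_theta)) || any(abs(cos_theta) > 1 + 1e-12)) {
    stop("|cos_theta| must not exceed 1 (beyond 1e-12 tolerance)")
  }
  x <- pmin(1, pmax(-1, cos_theta))
  (3 * x^2 - 1) / 2
}

#' Instantaneous dipolar coupling from its three factors
#'
#' Composes the prefactor, radial factor and orientation factor into a coupling
#' in Hz: `D = Dc * R * P * 1000`.
#'
#' @param Dc Prefactor in kHz (see [dipolar_prefactor()]).
#' @param R Radial factor (see [radial_factor()]).
#' @param P Orientation factor (see [legendre_p2()]).
#' @return Coupling in Hz.
#' @export
rdc_instant <- function(Dc, R, P) {
  Dc * R * P * 1e3
}

#' Backbone bond classes used for protein RDCs
#'
#' The four backbone bond types with their rigid bond lengths, isotopes and
#' derived constants. Two printed conventions coexist in the field and both are
#' provided: `Dc` is the prefactor evaluated at `r0 = b0` (the per-type values
#' quoted in kHz: +24.36, -46.66, -4.241, +2.606), while `R` is the radial
#' factor `(0.1 / b0)^3` relative to the global reference r0 = 0.1 nm
#' (1.0, 0.7722, 0.2792, 0.4251). Because
#' `dipolar_prefactor(g1, g2, 0.1) * R == dipolar_prefactor(g1, g2, b0)`
#' exactly, the predicted coupling uses the single effective scale
#' `scale_Hz = 1000 * Dc`, and `D = scale_Hz * P` for a rigid bond at `b0`.
#'
#' @param isotopes Isotope table, see [isotope_table()].
#' @return data.frame with one row per class (`N-HN`, `CA-HA`, `CA-C`, `C-N`)
#'   and columns `class`, `iso1`, `iso2`, `b0` (nm), `r0` (nm, reference for
#'   `R`), `Dc` (kHz at `r0 = b0`), `R`, `scale_Hz`.
#' @export
bond_classes <- function(isotopes = isotope_table()) {
  cls <- data.frame(
    class = c("N-HN", "CA-HA", "CA-C", "C-N"),
    iso1  = c("15N", "13C", "13C", "13C"),
    iso2  = c("1H",  "1H",  "13C", "15N"),
    b0    = c(0.100, 0.109, 0.153, 0.133),
    stringsAsFactors = FALSE
  )
  cls$r0 <- 0.1
  cls$Dc <- dipolar_prefactor(.gamma_of(cls$iso1, isotopes),
                              .gamma_of(cls$iso2, isotopes), cls$b0)
  cls$R  <- radial_factor(cls$b0, cls$r0)
  cls$scale_Hz <- cls$Dc * 1e3
  cls
}

.known_classes <- c("N-HN", "CA-HA", "CA-C", "C-N")

#' Construct an RDC target table
#'
#' @param residue Integer residue numbers (author numbering).
#' @param class Bond class, one of `N-HN`, `CA-HA`, `CA-C`, `C-N`.
#' @param D0 Target coupling(s), Hz; must be finite and smaller in magnitude
#'   than the class prefactor.
#' @param restrained Logical flag(s): does this target enter the fit/restraint?
#' @param provenance One of `measured`, `averaged-duplicate`,
#'   `artificial-inverted`, `synthetic`.
#' @return data.frame of class `rdc_targets`.
#' @export
rdc_targets <- function(residue, class, D0, restrained = FALSE,
                        provenance = "measured") {
  class <- as.character(class)
  bad <- setdiff(unique(class), .known_classes)
  if (length(bad)) stop("unknown bond class(es): ", paste(bad, collapse = ", "))
  if (any(!is.finite(D0))) stop("target RDCs must be finite")
  bc <- bond_classes()
  lim <- abs(bc$scale_Hz[match(class, bc$class)])
  if (any(abs(D0) >= lim)) {
    stop("an RDC cannot exceed the magnitude of its dipolar-coupling prefactor")
  }
  out <- data.frame(residue = as.integer(residue), class = class,
                    D0 = as.numeric(D0),
                    restrained = rep_len(as.logical(restrained), length(D0)),
                    provenance = rep_len(as.character(provenance), length(D0)),
                    stringsAsFactors = FALSE)
  class(out) <- c("rdc_targets", "data.frame")
  out
}
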