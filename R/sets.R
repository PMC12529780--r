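# Restraint-set selection: which targets exert forces (HRS) or enter the
# least-squares objective (AT). All couplings of all four types are always
# retained for prediction and metrics; only the CA-HA and/or N-HN subsets are
# ever restrained (the CA-C and C-N couplings are too small to restrain
# meaningfully).

.restraint_sets <- c("CAH59", "NH101", "NCAH160", "CAH59I", "NCAH160I", "custom")

#' Select a restraint set
#'
#' Flags the restrained subset of a target table by named convention:
#' \describe{
#'   \item{CAH59}{restrain the CA-HA couplings only}
#'   \item{NH101}{restrain the N-HN couplings only}
#'   \item{NCAH160}{restrain the union of CA-HA and N-HN}
#'   \item{CAH59I / NCAH160I}{as above, but the CA-HA target values are first
#'     sequence-inverted along the backbone ([invert_sequence()]) -- the
#'     artificial incompatible sets}
#'   \item{custom}{restrain the (residue, class) pairs given in `restrain`}
#' }
#' The set names carry the counts of the lysozyme case study but apply to any
#' target table: they select by bond class, not by count.
#'
#' @param targets An `rdc_targets` table (all four classes may be present).
#' @param set One of `CAH59`, `NH101`, `NCAH160`, `CAH59I`, `NCAH160I`,
#'   `custom`.
#' @param restrain For `set = "custom"`: data.frame with columns `residue`,
#'   `class` naming the restrained couplings (must be non-empty).
#' @return The targets with updated `restrained` flags (and, for the inverted
#'   sets, modified CA-HA `D0` values).
#' @export
select_restraint_set <- function(targets, set, restrain = NULL) {
  if (!set %in% .restraint_sets) {
    stop("unknown restraint set '", set, "'; valid: ",
         paste(.restraint_sets, collapse = ", "))
  }
  out <- targets
  if (set %in% c("CAH59I", "NCAH160I")) {
    i <- which(out$class == "CA-HA")
    if (!length(i)) stop("no CA-HA couplings to invert")
    out[i, ] <- invert_sequence(out[i, , drop = FALSE])
  }
  out$restrained <- switch(set,
    CAH59    = out$class == "CA-HA",
    NH101    = out$class == "N-HN",
    NCAH160  = out$class %in% c("CA-HA", "N-HN"),
    CAH59I   = out$class == "CA-HA",
    NCAH160I = out$class %in% c("CA-HA", "N-HN"),
    custom   = {
      if (is.null(restrain) || !nrow(restrain)) {
        stop("custom restraint set must name at least one (residue, class) pair")
      }
      paste(out$residue, out$class) %in% paste(restrain$residue, restrain$class)
    })
  if (!any(out$restrained)) stop("restraint set '", set, "' selects no couplings")
  out
}
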