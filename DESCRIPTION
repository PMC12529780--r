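Package: rdcalc
Title: Back-Calculation of Residual Dipolar Couplings from Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Back-calculates residual dipolar couplings (RDCs) for rigid protein
    structures by two routes: a singular-value-decomposition least-squares fit of
    the five independent components of the alignment (Saupe) tensor, and
    magnetic-field rotational sampling (HRS), a stochastic-dynamics simulation of
    a rigid two-particle magnetic-field vector under flat-bottom RDC restraints
    with exponential-memory averaging. Includes PDB reading with amide-proton and
    virtual H-alpha construction, RDC target-table handling, restraint-set
    selection, evaluation metrics (RMSD families, deviation counts, cross-method
    and cross-structure RMSDs), orientation-distribution diagnostics with
    magic-angle detection, backbone superposition, hydrogen-bond detection, and
    synthetic fixture generation (ideal helices, known alignment tensors).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
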