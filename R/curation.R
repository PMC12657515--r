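## Benchmark curation: structure/ligand quality filter stack ------------------

QUALITY_FILTERS <- c("resolution", "dpi", "b_factor", "ediam", "mw-range",
                     "rotatable-bonds", "ghose", "lipinski", "missing-atoms",
                     "altlocs", "crystal-contact")

#' Construct a benchmark metadata record
#'
#' One row of the per-complex quality metadata consumed by
#' [apply_quality_filters()]: crystallographic precision (resolution, DPI),
#' ligand order (average B-factor, EDIAm electron-density support),
#' drug-likeness (MW, rotatable bonds, Ghose/Lipinski pass counts) and
#' structural completeness flags.
#'
#' @param complex_id identifier string.
#' @param resolution A. @param dpi diffraction-component precision index, A.
#' @param ligand_b_factor_avg A^2. @param ediam unitless. @param mw Da.
#' @param n_rotatable_bonds integer. @param ghose_pass_count 0-4.
#' @param lipinski_pass_count 0-4. @param has_missing_atoms logical.
#' @param has_altlocs logical. @param min_crystal_contact A.
#' @return a one-row data.frame of class `BenchmarkRecord`.
#' @export
benchmark_record <- function(complex_id, resolution, dpi,
                             ligand_b_factor_avg, ediam, mw,
                             n_rotatable_bonds, ghose_pass_count,
                             lipinski_pass_count, has_missing_atoms,
                             has_altlocs, min_crystal_contact) {
  rec <- data.frame(
    complex_id = complex_id, resolution = resolution, dpi = dpi,
    ligand_b_factor_avg = ligand_b_factor_avg, ediam = ediam, mw = mw,
    n_rotatable_bonds = as.integer(n_rotatable_bonds),
    ghose_pass_count = as.integer(ghose_pass_count),
    lipinski_pass_count = as.integer(lipinski_pass_count),
    has_missing_atoms = has_missing_atoms, has_altlocs = has_altlocs,
    min_crystal_contact = min_crystal_contact, stringsAsFactors = FALSE)
  num <- vapply(rec, is.numeric, TRUE)
  if (any(unlist(rec[num]) < 0, na.rm = TRUE))
    stop("benchmark_record: numeric fields must be non-negative")
  class(rec) <- c("BenchmarkRecord", class(rec))
  rec
}

#' Apply the benchmark quality-filter stack to a record
#'
#' A record passes iff: resolution <= 2.5 A, DPI <= 0.5 A, average ligand
#' B-factor <= 80 A^2, EDIAm >= 0.4, molecular weight in [50, 500] Da,
#' fewer than 18 rotatable bonds (strict), at least 3 of 4 Ghose filters,
#' at least 3 of 4 Lipinski rules, no missing atoms, no alternative
#' conformations, and no crystal contact with a receptor copy below 4.5 A.
#' A missing (NA) field makes that filter unevaluable and the record fails.
#'
#' @param record a `BenchmarkRecord` (or compatible one-row data.frame).
#' @return list with `pass` (logical) and `violated` (character vector of
#'   filter names, `"<name>:unevaluable"` for missing fields).
#' @export
apply_quality_filters <- function(record) {
  r <- as.list(record)
  checks <- list(
    resolution = function() r$resolution <= 2.5,
    dpi = function() r$dpi <= 0.5,
    b_factor = function() r$ligand_b_factor_avg <= 80,
    ediam = function() r$ediam >= 0.4,
    `mw-range` = function() r$mw >= 50 && r$mw <= 500,
    `rotatable-bonds` = function() r$n_rotatable_bonds < 18,
    ghose = function() r$ghose_pass_count >= 3,
    lipinski = function() r$lipinski_pass_count >= 3,
    `missing-atoms` = function() !r$has_missing_atoms,
    altlocs = function() !r$has_altlocs,
    `crystal-contact` = function() r$min_crystal_contact >= 4.5)
  violated <- character()
  for (nm in names(checks)) {
    ok <- tryCatch(checks[[nm]](), error = function(e) NA)
    if (is.null(ok) || length(ok) == 0 || is.na(ok))
      violated <- c(violated, paste0(nm, ":unevaluable"))
    else if (!ok) violated <- c(violated, nm)
  }
  list(pass = length(violated) == 0, violated = violated)
}

#' Read / write benchmark metadata tables (TSV with header)
#' @param path TSV path.
#' @return data.frame of records.
#' @export
read_benchmark_table <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname read_benchmark_table
#' @param records data.frame of records to write.
#' @export
write_benchmark_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Ghose and Lipinski pass counts for a ligand
#'
#' Computes the two drug-likeness pass counts consumed by the filter stack
#' from a ligand system. The logP estimate (and molar refractivity) have no
#' in-package predictor and are supplied as configuration. Thresholds:
#' Ghose -- MW 160-480, logP -0.4-5.6, atom count 20-70, molar refractivity
#' 40-130; Lipinski -- MW <= 500, logP <= 5, H-bond donors <= 5, acceptors
#' <= 10. Donors are counted as N/O atoms bearing at least one hydrogen,
#' acceptors as all N/O atoms.
#'
#' @param sys ligand `MolecularSystem`.
#' @param logp configured logP estimate.
#' @param molar_refractivity configured molar refractivity.
#' @return list with `ghose_pass_count` and `lipinski_pass_count` (0-4).
#' @export
drug_filter_counts <- function(sys, logp, molar_refractivity) {
  a <- sys$atoms[ligand_atoms(sys), , drop = FALSE]
  mw <- sum(element_mass(a$element))
  natoms <- nrow(a)
  e <- bond_edges(sys)
  no_idx <- which(a$element %in% c("N", "O"))
  hba <- length(no_idx)
  hbd <- sum(vapply(no_idx, function(i) {
    nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
    any(sys$atoms$element[nb] == "H")
  }, TRUE))
  ghose <- sum(mw >= 160 && mw <= 480, logp >= -0.4 && logp <= 5.6,
               natoms >= 20 && natoms <= 70,
               molar_refractivity >= 40 && molar_refractivity <= 130)
  lip <- sum(mw <= 500, logp <= 5, hbd <= 5, hba <= 10)
  list(ghose_pass_count = as.integer(ghose),
       lipinski_pass_count = as.integer(lip))
}
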