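## Molecular data model -------------------------------------------------------
##
## A MolecularSystem is a plain list with class "MolecularSystem":
##   atoms:    data.frame(element, x, y, z, charge, lj_epsilon, lj_rmin_half,
##                        chain, resnum, residue_name, atom_name, is_ligand,
##                        b_factor)
##   bonds:    data.frame(i, j, order, k, r0)       # k kcal/mol/A^2, r0 A
##   angles:   data.frame(i, j, k_, ktheta, theta0) # ktheta kcal/mol/rad^2,
##                                                  # theta0 degrees
##   torsions: data.frame(i, j, k_, l, kphi, n, delta) # kphi kcal/mol,
##                                                     # delta degrees
##   metals:   integer vector of atom indices
##   covalent_link: c(ligand_atom, receptor_atom) or NULL
##   flex_receptor: integer vector of receptor atoms treated as flexible
##   net_charge: integer, multiplicity: positive integer
##
## Atom indices are 1-based throughout (native R convention). Residue identity
## is chain + 1-based residue number; insertion codes are not supported.

#' Construct a molecular system
#'
#' Assembles the container used by every other module: a table of atoms with
#' coordinates (Angstrom), partial charges (elementary charges) and
#' Lennard-Jones parameters, plus bonded-term tables, metal indices and an
#' optional covalent ligand-receptor link.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`, `lj_epsilon`, `lj_rmin_half`, `chain`, `resnum`,
#'   `residue_name`, `atom_name`, `is_ligand`, `b_factor`. Missing optional
#'   columns are filled with defaults (charge 0, LJ 0, chain "A", ligand
#'   FALSE).
#' @param bonds data.frame with columns `i`, `j` and optionally `order`
#'   (default 1), `k` (force constant, kcal/mol/A^2; CHARMM convention
#'   E = k (b - r0)^2) and `r0` (A).
#' @param angles data.frame with columns `i`, `j`, `k_` (central atom `j`)
#'   and optionally `ktheta` (kcal/mol/rad^2) and `theta0` (degrees).
#' @param torsions data.frame with columns `i`, `j`, `k_`, `l` and optionally
#'   `kphi` (kcal/mol), `n` (periodicity) and `delta` (degrees).
#' @param metals integer vector of metal-ion atom indices.
#' @param covalent_link length-2 integer vector `c(ligand_atom,
#'   receptor_atom)` for covalently bound ligands, or `NULL`.
#' @param flex_receptor integer vector of receptor atoms treated as flexible
#'   (empty = rigid receptor).
#' @param net_charge integer total charge (e).
#' @param multiplicity positive integer spin multiplicity.
#' @param validate logical; run [validate_system()].
#' @return An object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, bonds = NULL, angles = NULL,
                             torsions = NULL, metals = integer(),
                             covalent_link = NULL, flex_receptor = integer(),
                             net_charge = 0L, multiplicity = 1L,
                             validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  fill <- function(col, default) {
    if (is.null(atoms[[col]])) atoms[[col]] <<- rep(default, n)
  }
  fill("charge", 0); fill("lj_epsilon", 0); fill("lj_rmin_half", 0)
  fill("chain", "A"); fill("resnum", 1L); fill("residue_name", "UNK")
  fill("b_factor", 0); fill("is_ligand", FALSE)
  if (is.null(atoms$atom_name))
    atoms$atom_name <- paste0(atoms$element, seq_len(n))
  empty_bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                            k = numeric(), r0 = numeric())
  bonds <- if (is.null(bonds) || nrow(bonds) == 0) empty_bonds else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$order)) bonds$order <- 1
    if (is.null(bonds$k)) bonds$k <- 0
    if (is.null(bonds$r0)) bonds$r0 <- 0
    bonds[, c("i", "j", "order", "k", "r0")]
  }
  angles <- if (is.null(angles) || nrow(angles) == 0)
    data.frame(i = integer(), j = integer(), k_ = integer(),
               ktheta = numeric(), theta0 = numeric())
  else {
    angles <- as.data.frame(angles)
    if (is.null(angles$ktheta)) angles$ktheta <- 0
    if (is.null(angles$theta0)) angles$theta0 <- 109.5
    angles[, c("i", "j", "k_", "ktheta", "theta0")]
  }
  torsions <- if (is.null(torsions) || nrow(torsions) == 0)
    data.frame(i = integer(), j = integer(), k_ = integer(), l = integer(),
               kphi = numeric(), n = numeric(), delta = numeric())
  else {
    torsions <- as.data.frame(torsions)
    if (is.null(torsions$kphi)) torsions$kphi <- 0
    if (is.null(torsions$n)) torsions$n <- 3
    if (is.null(torsions$delta)) torsions$delta <- 0
    torsions[, c("i", "j", "k_", "l", "kphi", "n", "delta")]
  }
  sys <- structure(list(
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    metals = as.integer(metals), covalent_link = covalent_link,
    flex_receptor = as.integer(flex_receptor),
    net_charge = as.integer(net_charge),
    multiplicity = as.integer(multiplicity)
  ), class = "MolecularSystem")
  if (validate) validate_system(sys)
  sys
}

#' Validate a molecular system's structural invariants
#'
#' Checks finite coordinates, non-negative LJ well depths, valid bond
#' indices (i != j), ligand bonded connectivity (including the covalent link
#' when present), and -- once parameters are assigned -- that the partial
#' charges sum to the declared net charge within 0.01 e.
#'
#' @param sys a `MolecularSystem`.
#' @param check_charge logical; verify the charge-sum invariant (skipped when
#'   all charges are zero, i.e. parameters not yet assigned).
#' @return `sys`, invisibly. Errors on violation.
#' @export
validate_system <- function(sys, check_charge = TRUE) {
  a <- sys$atoms
  if (nrow(a) == 0) stop("empty-input error: system has zero atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("invalid system: non-finite coordinates")
  if (any(a$lj_epsilon < 0))
    stop("invalid system: negative Lennard-Jones well depth")
  b <- sys$bonds
  if (nrow(b) > 0) {
    if (any(b$i == b$j)) stop("invalid system: bond with i == j")
    if (any(b$i < 1 | b$j < 1 | b$i > nrow(a) | b$j > nrow(a)))
      stop("invalid system: bond index out of range")
  }
  if (sys$multiplicity < 1) stop("invalid system: multiplicity must be >= 1")
  lig <- which(a$is_ligand)
  if (length(lig) > 1) {
    eb <- rbind(as.matrix(b[, c("i", "j")]),
                if (!is.null(sys$covalent_link)) matrix(sys$covalent_link, 1))
    sub <- eb[eb[, 1] %in% lig & eb[, 2] %in% lig, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.integer(sub), lig), ncol = 2), directed = FALSE)
    if (length(igraph::V(g)) < length(lig) ||
        igraph::components(g)$no != 1)
      stop("invalid system: ligand atoms are not a connected bonded component")
  }
  if (check_charge && any(a$charge != 0)) {
    s <- sum(a$charge)
    if (abs(s - sys$net_charge) > 0.01)
      stop(sprintf(
        "invalid system: charge sum %.4f does not match net_charge %d",
        s, sys$net_charge))
  }
  invisible(sys)
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat(sprintf(
    "MolecularSystem: %d atoms (%d ligand), %d bonds, %d metals, charge %+d, mult %d\n",
    nrow(x$atoms), sum(x$atoms$is_ligand), nrow(x$bonds),
    length(x$metals), x$net_charge, x$multiplicity))
  invisible(x)
}

## coordinate matrix (n x 3)
coords <- function(sys) as.matrix(sys$atoms[, c("x", "y", "z")])

set_coords <- function(sys, xyz, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(sys$atoms))
  sys$atoms$x[idx] <- xyz[, 1]
  sys$atoms$y[idx] <- xyz[, 2]
  sys$atoms$z[idx] <- xyz[, 3]
  sys
}

ligand_atoms <- function(sys) which(sys$atoms$is_ligand)
receptor_atoms <- function(sys) which(!sys$atoms$is_ligand)

## residue key "chain:resnum" per atom
residue_key <- function(sys) paste(sys$atoms$chain, sys$atoms$resnum, sep = ":")

## full bond edge list including the covalent ligand-receptor link
## (added only when not already a row of the bond table)
bond_edges <- function(sys) {
  e <- as.matrix(sys$bonds[, c("i", "j")])
  cl <- sys$covalent_link
  if (!is.null(cl) &&
      !any((e[, 1] == cl[1] & e[, 2] == cl[2]) |
             (e[, 1] == cl[2] & e[, 2] == cl[1])))
    e <- rbind(e, cl)
  storage.mode(e) <- "integer"
  e
}

## topological distance classification for nonbonded exclusions:
## returns a list with `excluded` (n x n logical: 1-2 and 1-3 pairs) --
## 1-4 pairs are included at full strength by the toy force field.
exclusion_matrix <- function(sys) {
  n <- nrow(sys$atoms)
  ex <- matrix(FALSE, n, n)
  e <- bond_edges(sys)
  if (nrow(e) == 0) return(ex)
  ex[e] <- TRUE; ex[e[, 2:1, drop = FALSE]] <- TRUE
  adj <- lapply(seq_len(n), function(i)
    c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) > 1) {
      pr <- utils::combn(nb, 2)
      ex[t(pr)] <- TRUE; ex[t(pr[2:1, , drop = FALSE])] <- TRUE
    }
  }
  diag(ex) <- TRUE
  ex
}

## lazy exclusion-matrix cache: energy routines look for sys$excl first;
## with_exclusions() attaches it once before hot loops (topology-invariant)
get_exclusions <- function(sys) sys$excl %||% exclusion_matrix(sys)
with_exclusions <- function(sys) {
  if (is.null(sys$excl)) sys$excl <- exclusion_matrix(sys)
  sys
}

#' Per-atom molecular weight lookup
#' @param elements character vector of element symbols.
#' @return numeric vector of masses (Da); unknown elements error.
#' @export
element_mass <- function(elements) {
  m <- ELEMENT_MASS[elements]
  if (anyNA(m)) stop("unknown element: ",
                     paste(unique(elements[is.na(m)]), collapse = ", "))
  unname(m)
}
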