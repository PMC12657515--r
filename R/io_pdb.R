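## PDB v3.3 reading/writing --------------------------------------------------

## bonded-atom-name pairs for the standard amino acids (heavy atoms),
## heme and water; CONECT records are honored for everything else.
## Backbone N-CA, CA-C, C-O (+ OXT) are implied for every amino acid.
AA_SIDECHAIN_BONDS <- list(
  GLY = list(),
  ALA = list(c("CA", "CB")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE3", "CZ3"), c("CZ3", "CH2"),
             c("CH2", "CZ2"), c("CZ2", "CE2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  HOH = list(c("O", "H1"), c("O", "H2")),
  HEM = local({
    ## porphyrin core: Fe-N x4, each pyrrole NA./NB/NC/ND ring + meso bridges
    core <- list()
    py <- list(c("NA", "C1A", "C2A", "C3A", "C4A", "CHB"),
               c("NB", "C1B", "C2B", "C3B", "C4B", "CHC"),
               c("NC", "C1C", "C2C", "C3C", "C4C", "CHD"),
               c("ND", "C1D", "C2D", "C3D", "C4D", "CHA"))
    for (p in py) {
      core <- c(core, list(
        c("FE", p[1]), c(p[1], p[2]), c(p[2], p[3]), c(p[3], p[4]),
        c(p[4], p[5]), c(p[5], p[1]), c(p[5], p[6])))
    }
    c(core, list(c("CHA", "C1A"), c("CHB", "C1B"), c("CHC", "C1C"),
                 c("CHD", "C1D")))
  })
)
AA_NAMES <- setdiff(names(AA_SIDECHAIN_BONDS), c("HOH", "HEM"))

## guess the heavy-atom partner of a hydrogen from its name (H, HA, HB2...)
hydrogen_partner <- function(hname, res_atom_names) {
  if (hname %in% c("H", "HN", "H1", "H2", "H3")) {
    if ("N" %in% res_atom_names) return("N")
  }
  stem <- sub("^[0-9]*H", "", hname)
  stem <- sub("[0-9]+$", "", stem)
  for (el in c("C", "N", "O", "S")) {
    cand <- paste0(el, stem)
    if (cand %in% res_atom_names) return(cand)
  }
  NA_character_
}

parse_pdb_coords <- function(line, lineno) {
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz))
    stop(sprintf("PDB format error at line %d: unparsable coordinates", lineno))
  xyz
}

#' Read a receptor (or complex) from a PDB file
#'
#' Parses ATOM/HETATM records of a PDB v3.3 file. Bonds are inferred from
#' residue templates (20 amino acids, heme, water; peptide bonds between
#' consecutive residues) plus any CONECT records. Force-field parameters are
#' left unset until [assign_parameters()]. Files with multiple MODEL blocks
#' yield a list of systems, one per model.
#'
#' @param path path to a PDB file.
#' @param multi_model if `TRUE` (default) a file with several MODEL blocks
#'   returns a list of `MolecularSystem`s; a single-model file always
#'   returns one system.
#' @return A `MolecularSystem`, or a list of them for multi-model files.
#' @export
read_receptor <- function(path, multi_model = TRUE) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1 && multi_model) {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) < length(model_starts))
      ends <- c(ends, length(lines))
    return(lapply(seq_along(model_starts), function(m) {
      block <- lines[model_starts[m]:ends[m]]
      conect <- lines[startsWith(lines, "CONECT")]
      parse_pdb_block(c(block, conect), offset = model_starts[m] - 1L)
    }))
  }
  parse_pdb_block(lines, offset = 0L)
}

parse_pdb_block <- function(lines, offset = 0L) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0) stop("empty-input error: PDB contains zero atoms")
  al <- lines[idx]
  icode <- trimws(substr(al, 27, 27))
  if (any(icode != ""))
    stop("PDB format error: insertion codes are not supported (line ",
         offset + idx[which(icode != "")[1]], ")")
  xyz <- t(vapply(seq_along(al),
                  function(i) parse_pdb_coords(al[i], offset + idx[i]),
                  numeric(3)))
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  chain <- trimws(substr(al, 22, 22)); chain[chain == ""] <- "A"
  resnum <- suppressWarnings(as.integer(substr(al, 23, 26)))
  if (anyNA(resnum))
    stop("PDB format error: unparsable residue number (line ",
         offset + idx[which(is.na(resnum))[1]], ")")
  bfac <- suppressWarnings(as.numeric(substr(al, 61, 66)))
  bfac[is.na(bfac)] <- 0
  elem <- trimws(substr(al, 77, 78))
  ## fall back on the atom name when the element column is blank
  guess <- sub("[0-9'].*$", "", sub("^[0-9]+", "", name))
  elem[elem == ""] <- substr(guess[elem == ""], 1, 2)
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  elem <- trimws(elem)
  two_letter <- c("Fe", "Zn", "Mg", "Ca", "Mn", "Na", "Cl", "Br", "Cu", "Ni", "Co")
  elem[!(elem %in% two_letter)] <- substr(elem[!(elem %in% two_letter)], 1, 1)

  ## ligand = HETATM residues outside the template dictionary that are not
  ## water, heme or bare metal ions
  is_het <- rec[idx] == "HETATM"
  is_lig <- is_het & !(resname %in% c(AA_NAMES, "HOH", "HEM")) &
    !(elem %in% METAL_ELEMENTS)
  atoms <- data.frame(
    element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = 0, lj_epsilon = 0, lj_rmin_half = 0,
    chain = chain, resnum = resnum, residue_name = resname,
    atom_name = name, is_ligand = is_lig, b_factor = bfac,
    stringsAsFactors = FALSE)

  bonds <- template_bonds(atoms)
  ## CONECT records (indices are original serials)
  ser_map <- stats::setNames(seq_along(serial), serial)
  for (cl in lines[startsWith(lines, "CONECT")]) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substr(cl, 7, 80)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) >= 2) {
      a <- ser_map[as.character(f[1])]
      for (b in ser_map[as.character(f[-1])]) {
        if (!is.na(a) && !is.na(b) && a != b)
          bonds <- rbind(bonds, data.frame(i = min(a, b), j = max(a, b),
                                           order = 1, k = 0, r0 = 0))
      }
    }
  }
  bonds <- unique(bonds[, c("i", "j", "order", "k", "r0")])
  metals <- which(atoms$element %in% METAL_ELEMENTS &
                    !(atoms$residue_name %in% AA_NAMES))
  molecular_system(atoms, bonds, metals = metals, validate = FALSE)
}

## template-driven bond perception for standard residues
template_bonds <- function(atoms) {
  out <- list()
  key <- paste(atoms$chain, atoms$resnum)
  for (k in unique(key)) {
    sel <- which(key == k)
    rn <- atoms$residue_name[sel[1]]
    nm <- atoms$atom_name[sel]
    pairs <- list()
    if (rn %in% AA_NAMES) {
      pairs <- c(list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT")),
                 AA_SIDECHAIN_BONDS[[rn]])
    } else if (rn %in% c("HOH", "HEM")) {
      pairs <- AA_SIDECHAIN_BONDS[[rn]]
    }
    for (p in pairs) {
      a <- sel[match(p[1], nm)]; b <- sel[match(p[2], nm)]
      if (!is.na(a) && !is.na(b)) out[[length(out) + 1]] <- c(a, b)
    }
    ## hydrogens by name convention
    hs <- sel[startsWith(nm, "H") | grepl("^[0-9]H", nm)]
    if (rn %in% names(AA_SIDECHAIN_BONDS)) {
      for (h in hs) {
        pa <- hydrogen_partner(atoms$atom_name[h], nm)
        if (!is.na(pa)) {
          b <- sel[match(pa, nm)]
          if (atoms$atom_name[h] != pa) out[[length(out) + 1]] <- c(h, b)
        }
      }
    }
  }
  ## peptide bonds between consecutive residues of the same chain
  resdf <- unique(data.frame(chain = atoms$chain, resnum = atoms$resnum))
  for (r in seq_len(nrow(resdf))) {
    ch <- resdf$chain[r]; rn <- resdf$resnum[r]
    c_this <- which(key == paste(ch, rn) & atoms$atom_name == "C" &
                      atoms$residue_name %in% AA_NAMES)
    n_next <- which(key == paste(ch, rn + 1) & atoms$atom_name == "N" &
                      atoms$residue_name %in% AA_NAMES)
    if (length(c_this) == 1 && length(n_next) == 1)
      out[[length(out) + 1]] <- c(c_this, n_next)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), order = numeric(),
                      k = numeric(), r0 = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]),
             order = 1, k = 0, r0 = 0)
}

pdb_atom_line <- function(i, name, resname, chain, resnum, xyz, b, elem,
                          het = FALSE) {
  nm <- if (nchar(name) < 4 && nchar(elem) == 1) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", i %% 100000, substr(nm, 1, 4), " ",
          substr(resname, 1, 3), chain, resnum, " ",
          xyz[1], xyz[2], xyz[3], 1.00, b, toupper(elem))
}

#' Write a molecular system (or poses of it) as a PDB file
#'
#' @param sys a `MolecularSystem`.
#' @param path output path.
#' @param poses optional list of `Pose` objects; each becomes one MODEL block
#'   with its scores embedded in REMARK records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(sys, path, poses = NULL) {
  a <- sys$atoms
  con <- file(path, "w"); on.exit(close(con))
  emit_model <- function(s, remark = NULL) {
    if (!is.null(remark)) writeLines(remark, con)
    for (i in seq_len(nrow(s$atoms))) {
      het <- s$atoms$is_ligand[i] || i %in% s$metals ||
        s$atoms$residue_name[i] %in% c("HOH", "HEM")
      writeLines(pdb_atom_line(
        i, s$atoms$atom_name[i], s$atoms$residue_name[i], s$atoms$chain[i],
        s$atoms$resnum[i], c(s$atoms$x[i], s$atoms$y[i], s$atoms$z[i]),
        s$atoms$b_factor[i], s$atoms$element[i], het), con)
    }
  }
  if (is.null(poses)) {
    emit_model(sys)
  } else {
    for (m in seq_along(poses)) {
      p <- poses[[m]]
      writeLines(sprintf("MODEL     %4d", m), con)
      rem <- c(
        sprintf("REMARK   3 QMMDOCK POSE %d PROVENANCE %s", m,
                p$provenance %||% "sampled"),
        if (!is.null(p$score_class))
          sprintf("REMARK   3 QMMDOCK SCORE_CLASS %.6f", p$score_class),
        if (!is.null(p$score_qmmm))
          sprintf("REMARK   3 QMMDOCK SCORE_QMMM %.6f", p$score_qmmm))
      emit_model(apply_pose(sys, p), remark = rem)
      writeLines("ENDMDL", con)
    }
  }
  ## CONECT for ligand + non-template bonds so read-back reproduces topology
  e <- bond_edges(sys)
  for (r in seq_len(nrow(e)))
    writeLines(sprintf("CONECT%5d%5d", e[r, 1], e[r, 2]), con)
  writeLines("END", con)
  invisible(path)
}
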