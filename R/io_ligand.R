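## Ligand IO: SDF V2000 and MOL2 ---------------------------------------------

#' Read a ligand from an SDF (V2000) or MOL2 file
#'
#' The connection table must carry explicit bonds; bond orders are preserved
#' (they feed the graph-automorphism detection used by symmetry-adapted
#' RMSD). All atoms are flagged `is_ligand`; the net charge is taken from
#' `M  CHG` records (SDF) or the summed partial charges (MOL2).
#'
#' @param path path to a `.sdf`/`.mol` or `.mol2` file.
#' @param record for multi-record SDF files, which record to read (default 1).
#' @return A `MolecularSystem` with `is_ligand = TRUE` for every atom.
#' @export
read_ligand <- function(path, record = 1L) {
  if (grepl("\\.mol2$", path, ignore.case = TRUE)) return(read_mol2(path))
  recs <- split_sdf_records(readLines(path, warn = FALSE))
  if (length(recs) < record) stop("SDF format error: record ", record,
                                  " not present")
  parse_sdf_record(recs[[record]])
}

split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) return(list(lines))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

parse_sdf_record <- function(lines) {
  if (length(lines) < 4) stop("SDF format error: truncated record")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb))
    stop("SDF format error: unparsable counts line")
  if (nb == 0 && na > 1) stop("SDF format error: missing bond block")
  if (length(lines) < 4 + na + nb) stop("SDF format error: truncated blocks")
  at <- lines[5:(4 + na)]
  xyz <- t(vapply(at, function(l)
    as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30))),
    numeric(3), USE.NAMES = FALSE))
  elem <- trimws(substr(at, 32, 34))
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.numeric(substr(bl, 7, 9)))
  }
  chg <- 0L
  fchg <- rep(0L, na)
  for (l in lines[startsWith(lines, "M  CHG")]) {
    f <- as.integer(strsplit(trimws(substr(l, 7, 200)), "\\s+")[[1]])
    nset <- f[1]
    for (k in seq_len(nset)) fchg[f[2 * k]] <- f[2 * k + 1]
  }
  chg <- sum(fchg)
  atoms <- data.frame(
    element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = 0, lj_epsilon = 0, lj_rmin_half = 0,
    chain = "L", resnum = 1L, residue_name = "LIG",
    atom_name = paste0(elem, seq_len(na)), is_ligand = TRUE, b_factor = 0,
    stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, bonds, net_charge = chg, validate = FALSE)
  sys$formal_charges <- fchg
  sys
}

#' Write a ligand system as an SDF (V2000) record
#'
#' @param sys ligand `MolecularSystem`.
#' @param path output path.
#' @param name molecule name (first line of the record).
#' @param tags named list of SDF data tags (`> <tag>` blocks) to append.
#' @param append append as an additional record instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(sys, path, name = "LIG", tags = list(), append = FALSE) {
  a <- sys$atoms
  b <- sys$bonds
  out <- c(name, "  qmmdock", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element))
  if (nrow(b) > 0)
    out <- c(out, sprintf("%3d%3d%3d  0", b$i, b$j, as.integer(b$order)))
  fchg <- sys$formal_charges
  if (!is.null(fchg) && any(fchg != 0)) {
    nz <- which(fchg != 0)
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(nz)),
                         paste0(sprintf("%4d%4d", nz, fchg[nz]),
                                collapse = "")))
  }
  out <- c(out, "M  END")
  for (tg in names(tags))
    out <- c(out, sprintf(">  <%s>", tg), as.character(tags[[tg]]), "")
  out <- c(out, "$$$$")
  if (append) cat(out, file = path, sep = "\n", append = TRUE)
  else writeLines(out, path)
  invisible(path)
}

read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    s <- which(trimws(lines) == paste0("@<TRIPOS>", name))
    if (length(s) == 0) return(NULL)
    e <- which(startsWith(trimws(lines), "@<TRIPOS>"))
    e <- e[e > s[1]]
    lines[(s[1] + 1):(if (length(e)) e[1] - 1 else length(lines))]
  }
  at <- sec("ATOM")
  bd <- sec("BOND")
  if (is.null(at)) stop("MOL2 format error: missing ATOM section")
  if (is.null(bd)) stop("MOL2 format error: missing bond block")
  at <- at[nzchar(trimws(at))]
  f <- lapply(strsplit(trimws(at), "\\s+"), identity)
  elem <- vapply(f, function(x) sub("\\..*$", "", x[6]), "")
  xyz <- t(vapply(f, function(x) as.numeric(x[3:5]), numeric(3)))
  chg <- vapply(f, function(x) if (length(x) >= 9) as.numeric(x[9]) else 0,
                0)
  bd <- bd[nzchar(trimws(bd))]
  bf <- strsplit(trimws(bd), "\\s+")
  ord <- vapply(bf, function(x) {
    o <- x[4]
    if (o %in% c("ar", "Ar")) 1.5 else if (o == "am") 1 else
      suppressWarnings(as.numeric(o)) %||% 1
  }, 0)
  bonds <- data.frame(i = vapply(bf, function(x) as.integer(x[2]), 0L),
                      j = vapply(bf, function(x) as.integer(x[3]), 0L),
                      order = ord)
  atoms <- data.frame(
    element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = chg, lj_epsilon = 0, lj_rmin_half = 0,
    chain = "L", resnum = 1L, residue_name = "LIG",
    atom_name = vapply(f, function(x) x[2], ""),
    is_ligand = TRUE, b_factor = 0, stringsAsFactors = FALSE)
  molecular_system(atoms, bonds, net_charge = round(sum(chg)),
                   validate = FALSE)
}

#' Write a ligand system as MOL2
#' @param sys ligand `MolecularSystem`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(sys, path) {
  a <- sys$atoms; b <- sys$bonds
  out <- c("@<TRIPOS>MOLECULE", "LIG",
           sprintf("%5d %5d 1", nrow(a), nrow(b)),
           "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM")
  out <- c(out, sprintf("%7d %-8s %10.4f %10.4f %10.4f %-5s 1 LIG %10.6f",
                        seq_len(nrow(a)), a$atom_name, a$x, a$y, a$z,
                        a$element, a$charge))
  out <- c(out, "@<TRIPOS>BOND")
  if (nrow(b) > 0) {
    os <- ifelse(b$order == 1.5, "ar", as.character(as.integer(b$order)))
    out <- c(out, sprintf("%6d %5d %5d %s", seq_len(nrow(b)), b$i, b$j, os))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a pose ensemble to disk
#'
#' Emits a multi-record SDF of the ligand poses (scores embedded as data
#' tags) and, optionally, a multi-model PDB of the full complex with scores
#' in REMARK records.
#'
#' @param sys the `MolecularSystem` the poses belong to.
#' @param poses list of `Pose` objects sharing one ligand topology.
#' @param sdf_path output SDF path.
#' @param pdb_path optional output multi-model PDB path.
#' @return `sdf_path`, invisibly.
#' @export
write_poses <- function(sys, poses, sdf_path, pdb_path = NULL) {
  nlig <- length(ligand_atoms(sys))
  for (p in poses) {
    if (length(p$movable) != length(poses[[1]]$movable) ||
        nrow(p$coords) != nrow(poses[[1]]$coords))
      stop("write_poses: heterogeneous pose topologies")
  }
  file.create(sdf_path)
  for (m in seq_along(poses)) {
    p <- poses[[m]]
    ps <- apply_pose(sys, p)
    lig <- subset_system(ps, ligand_atoms(ps))
    tags <- list(pose_id = m,
                 provenance = p$provenance %||% "sampled")
    if (!is.null(p$score_class)) tags$score_class <- sprintf("%.6f", p$score_class)
    if (!is.null(p$score_qmmm)) tags$score_qmmm <- sprintf("%.6f", p$score_qmmm)
    if (!is.null(p$rmsd_to_native))
      tags$rmsd_to_native <- sprintf("%.4f", p$rmsd_to_native)
    write_sdf(lig, sdf_path, name = sprintf("pose_%d", m), tags = tags,
              append = m > 1)
  }
  if (!is.null(pdb_path)) write_pdb(sys, pdb_path, poses = poses)
  invisible(sdf_path)
}

## extract an atom subset as a standalone system (bonded terms wholly inside)
subset_system <- function(sys, idx) {
  idx <- sort(idx)
  map <- rep(NA_integer_, nrow(sys$atoms)); map[idx] <- seq_along(idx)
  b <- sys$bonds[sys$bonds$i %in% idx & sys$bonds$j %in% idx, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  an <- sys$angles[sys$angles$i %in% idx & sys$angles$j %in% idx &
                     sys$angles$k_ %in% idx, , drop = FALSE]
  an$i <- map[an$i]; an$j <- map[an$j]; an$k_ <- map[an$k_]
  to <- sys$torsions[sys$torsions$i %in% idx & sys$torsions$j %in% idx &
                       sys$torsions$k_ %in% idx & sys$torsions$l %in% idx, ,
                     drop = FALSE]
  to$i <- map[to$i]; to$j <- map[to$j]; to$k_ <- map[to$k_]; to$l <- map[to$l]
  out <- molecular_system(sys$atoms[idx, , drop = FALSE], b, an, to,
                          metals = stats::na.omit(map[sys$metals]),
                          net_charge = round(sum(sys$atoms$charge[idx])),
                          multiplicity = sys$multiplicity, validate = FALSE)
  if (!is.null(sys$formal_charges)) {
    fc <- sys$formal_charges[idx]
    out$formal_charges <- fc
    out$net_charge <- as.integer(sum(fc))
  }
  out
}
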