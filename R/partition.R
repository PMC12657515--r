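## PS/SS partitioning, link atoms, embedding charges --------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA", "HA2", "HA3",
                    "H1", "H2", "H3")

#' Select the primary (QM) system
#'
#' Splits a complex into a primary system (PS, treated quantum mechanically)
#' and a secondary system (SS, classical) according to the selection mode:
#'
#' * `"lig"` -- the ligand; for covalent complexes the protein binding
#'   residue is automatically added.
#' * `"lig+MB"` -- additionally every metal ion within `metal_cutoff`
#'   (default 5 A) of a ligand heavy atom, plus its coordinating residues
#'   (any residue with a heavy atom within `coordination_cutoff`, default
#'   2.8 A, of the metal).
#' * `"lig+Box+MB"` (or `"lig+BoxN+MB"` with the edge length N embedded in
#'   the mode string) -- additionally every residue or cofactor with at
#'   least one atom inside a cubic box of edge `box_edge` centered on
#'   `box_center` (default: ligand centroid).
#'
#' With `sidechain_only = TRUE` amino-acid residues contribute only side
#' chains and the boundary is cut at the CA-CB bond; with `FALSE` backbone
#' atoms are included as well and boundaries are shifted so that cuts fall
#' on C-CA bonds of the flanking peptide groups. Glycine selected in
#' side-chain mode is skipped with a warning (no side chain to include).
#'
#' @param sys a `MolecularSystem`.
#' @param mode PS selection mode (see above).
#' @param box_edge cubic box edge length (A); required for Box modes unless
#'   embedded in the mode string.
#' @param sidechain_only cut at CA-CB (`TRUE`) or C-CA (`FALSE`); defaults
#'   to `TRUE` for `lig`/`lig+MB` and `FALSE` for Box modes.
#' @param metal_cutoff metal-to-ligand heavy atom inclusion cutoff (A).
#' @param coordination_cutoff metal-to-residue coordination cutoff (A).
#' @param box_center 3-vector; defaults to the ligand centroid.
#' @return A `Partition` with `ps_atoms`, `ss_atoms`, `cut_bonds`,
#'   `ps_net_charge`, `ps_multiplicity` (link atoms and embedding charges
#'   are added by [build_link_atoms()] and [embedding_charges()]).
#' @export
select_primary_system <- function(sys, mode = "lig", box_edge = NULL,
                                  sidechain_only = NULL, metal_cutoff = 5.0,
                                  coordination_cutoff = 2.8,
                                  box_center = NULL) {
  m <- gsub("\\s", "", mode)
  boxn <- regmatches(m, regexpr("Box[0-9.]+", m))
  if (length(boxn) == 1 && nchar(boxn))
    box_edge <- as.numeric(sub("Box", "", boxn))
  has_box <- grepl("Box", m)
  has_mb <- grepl("MB", m)
  if (has_box && is.null(box_edge))
    stop("config error: Box mode requires ps.box_edge")
  if (is.null(sidechain_only)) sidechain_only <- !has_box
  a <- sys$atoms
  X <- coords(sys)
  key <- residue_key(sys)
  ps <- ligand_atoms(sys)
  heavy_lig <- ps[a$element[ps] != "H"]

  add_residue <- function(ps, sel_key, sc_only) {
    ratoms <- which(key == sel_key)
    rn <- a$residue_name[ratoms[1]]
    if (sc_only) {
      sc <- ratoms[!(a$atom_name[ratoms] %in% BACKBONE_NAMES)]
      if (length(sc) == 0) {
        warning(sprintf("residue %s (%s) has no side chain; skipped in sidechain-only mode",
                        sel_key, rn))
        return(ps)
      }
      union(ps, sc)
    } else union(ps, ratoms)
  }

  ## covalent binding residue is always added
  if (!is.null(sys$covalent_link)) {
    rk <- key[sys$covalent_link[2]]
    ps <- add_residue(ps, rk, sidechain_only)
  }
  if (has_mb && length(sys$metals) > 0) {
    for (mi in sys$metals) {
      dmin <- min(sqrt(rowSums((X[heavy_lig, , drop = FALSE] -
                                  matrix(X[mi, ], length(heavy_lig), 3,
                                         byrow = TRUE))^2)))
      if (dmin <= metal_cutoff) {
        ps <- union(ps, mi)
        heavy <- which(a$element != "H")
        heavy <- setdiff(heavy, c(mi, ligand_atoms(sys)))
        d <- sqrt(rowSums((X[heavy, , drop = FALSE] -
                             matrix(X[mi, ], length(heavy), 3,
                                    byrow = TRUE))^2))
        for (rk in unique(key[heavy[d <= coordination_cutoff]]))
          ps <- add_residue(ps, rk, sc_only = TRUE)
      }
    }
  }
  if (has_box) {
    ctr <- box_center %||% colMeans(X[ligand_atoms(sys), , drop = FALSE])
    half <- box_edge / 2
    inside <- abs(X[, 1] - ctr[1]) <= half & abs(X[, 2] - ctr[2]) <= half &
      abs(X[, 3] - ctr[3]) <= half
    inside[ligand_atoms(sys)] <- FALSE
    for (rk in unique(key[inside]))
      ps <- add_residue(ps, rk, sidechain_only)
    if (!sidechain_only) ps <- adjust_backbone_boundary(sys, ps)
  }
  ps <- sort(unique(ps))
  ss <- setdiff(seq_len(nrow(a)), ps)
  e <- bond_edges(sys)
  in_ps <- seq_len(nrow(a)) %in% ps
  cut <- which(xor(in_ps[e[, 1]], in_ps[e[, 2]]))
  cut_bonds <- if (length(cut)) {
    cb <- e[cut, , drop = FALSE]
    swap <- !in_ps[cb[, 1]]
    cb[swap, ] <- cb[swap, 2:1]
    colnames(cb) <- c("qm_host", "mm_neighbor")
    cb
  } else matrix(integer(), 0, 2,
                dimnames = list(NULL, c("qm_host", "mm_neighbor")))
  check_ring_cuts(sys, cut_bonds)
  structure(list(
    ps_atoms = ps, ss_atoms = ss, cut_bonds = cut_bonds,
    link_atoms = NULL, embedding = NULL,
    ps_net_charge = as.integer(round(sum(a$charge[ps]))),
    ps_multiplicity = sys$multiplicity,
    mode = mode, sidechain_only = sidechain_only
  ), class = "Partition")
}

## shift boundaries of whole-residue selections so that every peptide-bond
## crossing becomes a C-CA cut: pull the preceding residue's carbonyl (C,O)
## into the PS; push the trailing carbonyl out when the next residue is SS.
adjust_backbone_boundary <- function(sys, ps) {
  a <- sys$atoms
  key <- residue_key(sys)
  in_ps <- seq_len(nrow(a)) %in% ps
  e <- bond_edges(sys)
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1]; j <- e[r, 2]
    if (in_ps[i] == in_ps[j]) next
    ## orient: c_at = carbonyl C, n_at = amide N
    if (a$atom_name[i] == "C" && a$atom_name[j] == "N") { c_at <- i; n_at <- j }
    else if (a$atom_name[j] == "C" && a$atom_name[i] == "N") { c_at <- j; n_at <- i }
    else next
    if (key[c_at] == key[n_at]) next
    res_c <- which(key == key[c_at])
    co <- res_c[a$atom_name[res_c] %in% c("C", "O", "OXT")]
    if (in_ps[n_at] && !in_ps[c_at]) {
      in_ps[co] <- TRUE               # pull preceding carbonyl in
    } else if (in_ps[c_at] && !in_ps[n_at]) {
      in_ps[co] <- FALSE              # push trailing carbonyl out
    }
  }
  which(in_ps)
}

## a cut through a ring bond (edge lying on a cycle) is unsupported
check_ring_cuts <- function(sys, cut_bonds) {
  if (nrow(cut_bonds) == 0) return(invisible())
  e <- bond_edges(sys)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  br <- igraph::bridges(g)
  bridge_pairs <- igraph::as_edgelist(g)[as.integer(br), , drop = FALSE]
  bkey <- paste(pmin(bridge_pairs[, 1], bridge_pairs[, 2]),
                pmax(bridge_pairs[, 1], bridge_pairs[, 2]))
  ckey <- paste(pmin(cut_bonds[, 1], cut_bonds[, 2]),
                pmax(cut_bonds[, 1], cut_bonds[, 2]))
  if (!all(ckey %in% bkey))
    stop("unsupported-topology error: PS/SS boundary cuts a ring bond")
  invisible()
}

#' Place hydrogen link atoms on the cut bonds
#'
#' One hydrogen link atom per cut bond, at `link_length` from the QM-side
#' host along the host-to-MM-neighbor direction. Link atoms carry no
#' classical point charge and no Lennard-Jones parameters; the embedding
#' charge of each first classical neighbor is set to zero (recorded in
#' `$zeroed_neighbors`, applied by [embedding_charges()]).
#'
#' @param partition a `Partition` from [select_primary_system()].
#' @param sys the parent `MolecularSystem`.
#' @param link_length H link-atom bond length (A, default 1.10).
#' @return The partition with `link_atoms` populated.
#' @export
build_link_atoms <- function(partition, sys, link_length = 1.10) {
  cb <- partition$cut_bonds
  X <- coords(sys)
  if (nrow(cb) == 0) {
    partition$link_atoms <- data.frame(qm_host = integer(),
                                       mm_neighbor = integer(),
                                       x = numeric(), y = numeric(),
                                       z = numeric())
  } else {
    pos <- t(vapply(seq_len(nrow(cb)), function(r) {
      h <- X[cb[r, "qm_host"], ]; m <- X[cb[r, "mm_neighbor"], ]
      u <- (m - h) / sqrt(sum((m - h)^2))
      h + link_length * u
    }, numeric(3)))
    partition$link_atoms <- data.frame(
      qm_host = cb[, "qm_host"], mm_neighbor = cb[, "mm_neighbor"],
      x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  partition$link_length <- link_length
  partition$zeroed_neighbors <- unique(cb[, "mm_neighbor"])
  partition
}

#' Build the electrostatic-embedding charge set
#'
#' Each SS atom contributes its position and `scale` times its force-field
#' charge; the first classical neighbors of cut bonds contribute exactly
#' zero. PS atoms contribute nothing. The default scale of 0.5 (charges
#' divided by 2) mimics a dielectric constant of 2 and avoids
#' over-polarization of the QM region.
#'
#' @param partition a `Partition` (after [build_link_atoms()]).
#' @param sys the parent `MolecularSystem`.
#' @param scale charge scaling fraction in (0, 1], default 0.5.
#' @return The partition with `embedding` (data.frame `atom,x,y,z,charge`)
#'   and `scale` populated.
#' @export
embedding_charges <- function(partition, sys, scale = 0.5) {
  stopifnot(scale > 0, scale <= 1)
  ss <- partition$ss_atoms
  X <- coords(sys)
  q <- scale * sys$atoms$charge[ss]
  zeroed <- partition$zeroed_neighbors %||% integer()
  q[ss %in% zeroed] <- 0
  partition$embedding <- data.frame(atom = ss, x = X[ss, 1], y = X[ss, 2],
                                    z = X[ss, 3], charge = q)
  partition$scale <- scale
  partition
}

#' One-call partition construction
#'
#' Chains [select_primary_system()], [build_link_atoms()] and
#' [embedding_charges()].
#'
#' @inheritParams select_primary_system
#' @inheritParams build_link_atoms
#' @inheritParams embedding_charges
#' @return a complete `Partition`.
#' @export
make_partition <- function(sys, mode = "lig", box_edge = NULL,
                           sidechain_only = NULL, metal_cutoff = 5.0,
                           coordination_cutoff = 2.8, box_center = NULL,
                           link_length = 1.10, scale = 0.5) {
  p <- select_primary_system(sys, mode, box_edge, sidechain_only,
                             metal_cutoff, coordination_cutoff, box_center)
  p <- build_link_atoms(p, sys, link_length)
  embedding_charges(p, sys, scale)
}

## refresh geometry-dependent parts (link positions, embedding positions)
## after coordinates changed; charges and memberships are kept
refresh_partition <- function(partition, sys) {
  partition <- build_link_atoms(partition, sys,
                                partition$link_length %||% 1.10)
  X <- coords(sys)
  ss <- partition$ss_atoms
  partition$embedding$x <- X[ss, 1]
  partition$embedding$y <- X[ss, 2]
  partition$embedding$z <- X[ss, 3]
  partition
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d PS atoms, %d SS atoms, %d link atoms (mode %s)\n",
              length(x$ps_atoms), length(x$ss_atoms),
              nrow(x$link_atoms %||% data.frame()), x$mode %||% "?"))
  cat(sprintf("  PS net charge %+d, multiplicity %d, embedding scale %s\n",
              x$ps_net_charge, x$ps_multiplicity,
              format(x$scale %||% NA)))
  invisible(x)
}
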