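## Deterministic synthetic complexes -----------------------------------------
##
## The generator emits small ligand-pocket complexes with fully specified
## toy parameters and a known native pose, standing in for curated
## experimental benchmark complexes: a rigid cage of pseudo-residues
## (4-atom chains named CA/CB/CG/CD, CD the inner contact atom) around a
## flexible zig-zag ligand chain, optionally with a divalent metal site, a
## covalent ligand-sidechain bond, and a single water. All randomness flows
## from the single seed; identical seeds give bit-identical output.

#' Generate a toy ligand-pocket complex
#'
#' Builds a parameterized complex whose native pose is a verified local
#' minimum of the classical score: after assembly the ligand is relaxed and
#' the generator asserts that single-atom perturbations of +/-0.2 A raise
#' the score, re-relaxing if needed.
#'
#' @param seed integer; drives every random choice.
#' @param n_pocket_residues number of cage pseudo-residues (>= 1,
#'   default 6).
#' @param with_metal place a divalent ion within 5 A of the ligand with two
#'   coordinating residues at <= 2.4 A.
#' @param with_covalent bond one ligand heavy atom to a pocket side-chain
#'   atom (sets `covalent_link`).
#' @param with_water add one explicit water near the ligand.
#' @param ligand_size ligand heavy-atom count (>= 2, default 4).
#' @param optimize_native relax and verify the native pose (default TRUE;
#'   turn off for speed when only the geometry matters).
#' @return list of class `ToyComplex`: `system` (coordinates at the native
#'   pose), `native` (`Pose`), `params` (parameter table).
#' @export
make_toy_complex <- function(seed, n_pocket_residues = 6L,
                             with_metal = FALSE, with_covalent = FALSE,
                             with_water = FALSE, ligand_size = 4L,
                             optimize_native = TRUE) {
  stopifnot(n_pocket_residues >= 1, ligand_size >= 2)
  if (with_covalent && ligand_size < 2)
    stop("contradictory options: covalent bond needs a >= 2 atom ligand")
  with_seed(seed, {
    ## --- ligand: zig-zag heavy-atom chain ---------------------------------
    ## element-dependent charges and radii: a homogeneous chain is nearly
    ## periodic and produces degenerate register-shifted binding poses;
    ## heteroatomic variation (as in real ligands) breaks that symmetry
    elems <- rep(c("C", "C", "O", "N"), length.out = ligand_size)
    lx <- (seq_len(ligand_size) - 1) * 1.25
    ly <- 0.45 * (-1)^seq_len(ligand_size)
    eps_of <- c(C = 0.12, O = 0.21, N = 0.17)
    rmin_of <- c(C = 1.95, O = 1.70, N = 1.85)
    lig <- data.frame(
      element = elems, x = lx - mean(lx), y = ly - mean(ly), z = 0,
      charge = 0, lj_epsilon = unname(eps_of[elems]),
      lj_rmin_half = unname(rmin_of[elems]),
      chain = "L", resnum = 1L, residue_name = "LIG",
      atom_name = paste0(elems, seq_len(ligand_size)),
      is_ligand = TRUE, b_factor = 10, stringsAsFactors = FALSE)
    ## strongly charged head atom: the complementary pocket contact then
    ## anchors the orientation (end-to-end flips of a quasi-symmetric chain
    ## are otherwise nearly degenerate in score)
    qs <- rep(c(0.45, -0.05, -0.35, -0.05), length.out = ligand_size)
    qs[ligand_size] <- qs[ligand_size] - sum(qs)
    lig$charge <- qs
    lig_bonds <- if (ligand_size > 1)
      data.frame(i = seq_len(ligand_size - 1), j = 2:ligand_size,
                 order = 1, k = 300, r0 = 0) else NULL
    atoms <- lig
    bonds <- lig_bonds

    ## --- pocket cage ------------------------------------------------------
    dirs <- fibonacci_directions(n_pocket_residues)
    R <- random_rotation_matrix()
    dirs <- dirs %*% t(R)
    ligX <- as.matrix(lig[, c("x", "y", "z")])
    res_offsets <- cbind(c(0, 0, 0), c(0.35, 0.15, 0), c(-0.2, 0.3, 0.1),
                         c(0.25, -0.25, 0.15))   # zig-zag, avoids 180 angles
    for (r in seq_len(n_pocket_residues)) {
      u <- dirs[r, ]
      ## lock-and-key: each contact atom (CD) is aimed at one specific
      ## ligand atom, at the exact Lennard-Jones minimum distance for that
      ## pair and with a complementary partial charge -- the constructed
      ## pose is the tailored fit, register-shifted or flipped poses are not
      tgt <- (r - 1L) %% ligand_size + 1L
      d_contact <- lig$lj_rmin_half[tgt] + 2.0
      base <- ligX[tgt, ] + u * d_contact
      ## local frame: u plus two perpendiculars
      perp1 <- pick_perpendicular(u); perp2 <- cross3(u, perp1)
      pos <- t(vapply(1:4, function(k) {
        off <- res_offsets[, k]
        base + u * 1.5 * (k - 1) + perp1 * off[1] + perp2 * off[2]
      }, numeric(3)))
      qcd <- -0.6 * lig$charge[tgt]
      atoms <- rbind(atoms, data.frame(
        element = c("C", "C", "C", "C"),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        charge = c(qcd, -qcd, 0, 0),
        lj_epsilon = 0.30, lj_rmin_half = 2.0,
        chain = "A", resnum = r, residue_name = sprintf("P%02d", r),
        atom_name = c("CD", "CG", "CB", "CA"),
        is_ligand = FALSE, b_factor = 15, stringsAsFactors = FALSE))
      o <- nrow(atoms) - 4
      bonds <- rbind(bonds, data.frame(i = o + 1:3, j = o + 2:4, order = 1,
                                       k = 300, r0 = 0))
    }
    metals <- integer()
    nres <- n_pocket_residues
    if (with_metal) {
      ## metal 4.5 A from its nearest ligand heavy atom, outside the cage
      u <- -dirs[1, ]
      anchor <- which.max(ligX %*% u)
      mpos <- ligX[anchor, ] + u * 4.5
      atoms <- rbind(atoms, data.frame(
        element = "Zn", x = mpos[1], y = mpos[2], z = mpos[3],
        charge = 2, lj_epsilon = 0.25, lj_rmin_half = 1.10,
        chain = "A", resnum = nres + 1L, residue_name = "ZN",
        atom_name = "ZN", is_ligand = FALSE, b_factor = 12,
        stringsAsFactors = FALSE))
      metals <- nrow(atoms)
      perp1 <- pick_perpendicular(u); perp2 <- cross3(u, perp1)
      for (k in 1:2) {
        nres <- nres + 1L
        v <- (if (k == 1) perp1 else perp2)
        ## coordinating residue: contact atom 2.1 A from the metal
        pos <- t(vapply(1:4, function(m)
          mpos + v * (2.1 + 1.5 * (m - 1)) +
            u * 0.3 * (m - 1), numeric(3)))
        atoms <- rbind(atoms, data.frame(
          element = c("O", "C", "C", "C"),
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          charge = c(-0.3, 0.3, 0, 0),
          lj_epsilon = 0.30, lj_rmin_half = c(1.7, 2.0, 2.0, 2.0),
          chain = "A", resnum = nres + 1L,
          residue_name = sprintf("M%02d", k),
          atom_name = c("OD", "CG", "CB", "CA"),
          is_ligand = FALSE, b_factor = 15, stringsAsFactors = FALSE))
        o <- nrow(atoms) - 4
        bonds <- rbind(bonds, data.frame(i = o + 1:3, j = o + 2:4,
                                         order = 1, k = 300, r0 = 0))
      }
    }
    covalent_link <- NULL
    if (with_covalent) {
      ## re-seat residue 1 so its CD sits at covalent distance from atom 1
      cd1 <- which(atoms$residue_name == "P01" & atoms$atom_name == "CD")
      resat <- which(atoms$residue_name == "P01")
      u <- dirs[1, ]
      target <- as.numeric(lig[1, c("x", "y", "z")]) + u * 1.8
      shift <- target - as.numeric(atoms[cd1, c("x", "y", "z")])
      atoms[resat, c("x", "y", "z")] <-
        sweep(atoms[resat, c("x", "y", "z")], 2, shift, "+")
      covalent_link <- c(1L, cd1)
      bonds <- rbind(bonds, data.frame(i = 1L, j = cd1, order = 1,
                                       k = 200, r0 = 1.80))
    }
    if (with_water) {
      u <- if (n_pocket_residues >= 2) dirs[2, ] else -dirs[1, ]
      anchor <- which.max(ligX %*% u)
      wpos <- ligX[anchor, ] + u * 3.0
      perp1 <- pick_perpendicular(u)
      atoms <- rbind(atoms, data.frame(
        element = c("O", "H", "H"),
        x = wpos[1] + c(0, 0.76, -0.76),
        y = wpos[2] + c(0, 0.59, 0.59), z = wpos[3],
        charge = c(-0.834, 0.417, 0.417),
        lj_epsilon = c(0.152, 0.046, 0.046),
        lj_rmin_half = c(1.77, 0.22, 0.22),
        chain = "W", resnum = 1L, residue_name = "HOH",
        atom_name = c("O", "H1", "H2"), is_ligand = FALSE, b_factor = 20,
        stringsAsFactors = FALSE))
      o <- nrow(atoms) - 3
      bonds <- rbind(bonds, data.frame(i = c(o + 1, o + 1), j = c(o + 2, o + 3),
                                       order = 1, k = 450, r0 = 0.9572))
    }
    rownames(atoms) <- NULL
    sys <- molecular_system(atoms, bonds, metals = metals,
                            covalent_link = covalent_link,
                            net_charge = round(sum(atoms$charge)),
                            validate = FALSE)
    ## equilibrium bonded parameters = as-built geometry (strain-free start)
    sys <- set_equilibrium_bonded(sys)
    params <- parameter_table_from_system(sys)
    sys <- assign_parameters(sys, params)
    if (!is.null(covalent_link)) sys$covalent_params <- list(k = 200, r0 = 1.80)

    native <- new_pose(sys, provenance = "native")
    if (optimize_native) {
      nat <- settle_native(sys, native, seed)
      sys <- apply_pose(sys, nat)
      native <- new_pose(sys, provenance = "native")
    }
    structure(list(system = sys, native = native, params = params,
                   seed = seed),
              class = "ToyComplex")
  })
}

## set r0 / theta0 / torsion phase from the current geometry and derive
## angle/torsion records for bonded chains (ligand + pocket residues)
set_equilibrium_bonded <- function(sys) {
  X <- coords(sys)
  b <- sys$bonds
  if (nrow(b) > 0) {
    d <- sqrt(rowSums((X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE])^2))
    fixed <- b$r0 > 0
    b$r0[!fixed] <- round(d[!fixed], 4)
    sys$bonds <- b
  }
  ang <- derive_angles(bond_edges(sys))
  if (nrow(ang) > 0) {
    th <- vapply(seq_len(nrow(ang)), function(r) {
      v1 <- X[ang$i[r], ] - X[ang$j[r], ]
      v2 <- X[ang$k_[r], ] - X[ang$j[r], ]
      acos(pmin(1, pmax(-1, sum(v1 * v2) /
                          sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    }, 0)
    sys$angles <- data.frame(i = ang$i, j = ang$j, k_ = ang$k_, ktheta = 50,
                             theta0 = round(th, 3))
  }
  tor <- derive_torsions(bond_edges(sys))
  if (nrow(tor) > 0) {
    ## phase chosen so the built dihedral sits at the cosine minimum
    ph <- vapply(seq_len(nrow(tor)), function(r)
      dihedral_angle(X[tor$i[r], ], X[tor$j[r], ], X[tor$k_[r], ],
                     X[tor$l[r], ]), 0)
    delta <- round(((3 * ph * 180 / pi - 180) %% 360), 3)
    sys$torsions <- data.frame(i = tor$i, j = tor$j, k_ = tor$k_, l = tor$l,
                               kphi = 0.15, n = 3, delta = delta)
  }
  sys
}

## build the JSON-able parameter table describing exactly this system
parameter_table_from_system <- function(sys) {
  a <- sys$atoms
  keys <- paste0(a$residue_name, ":", a$atom_name)
  stopifnot(!anyDuplicated(keys))
  atoms <- stats::setNames(lapply(seq_len(nrow(a)), function(i)
    list(charge = a$charge[i], epsilon = a$lj_epsilon[i],
         rmin_half = a$lj_rmin_half[i])), keys)
  bonds <- list()
  for (r in seq_len(nrow(sys$bonds))) {
    bonds[[paste(keys[sys$bonds$i[r]], keys[sys$bonds$j[r]], sep = "-")]] <-
      list(k = sys$bonds$k[r], r0 = sys$bonds$r0[r])
  }
  angles <- list()
  for (r in seq_len(nrow(sys$angles))) {
    angles[[paste(keys[sys$angles$i[r]], keys[sys$angles$j[r]],
                  keys[sys$angles$k_[r]], sep = "-")]] <-
      list(ktheta = sys$angles$ktheta[r], theta0 = sys$angles$theta0[r])
  }
  torsions <- list()
  for (r in seq_len(nrow(sys$torsions))) {
    torsions[[paste(keys[sys$torsions$i[r]], keys[sys$torsions$j[r]],
                    keys[sys$torsions$k_[r]], keys[sys$torsions$l[r]],
                    sep = "-")]] <-
      list(kphi = sys$torsions$kphi[r], n = sys$torsions$n[r],
           delta = sys$torsions$delta[r])
  }
  list(atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
       covalent_bond = if (!is.null(sys$covalent_link))
         list(k = 200, r0 = 1.80))
}

## relax the ligand under the classical score, probe neighboring basins so
## the emitted native pose is the locally deepest minimum (the corrugated
## numerical-SASA surface can hide a slightly deeper basin < 1 A away), and
## verify the local-minimum property by a +/-0.2 A single-atom scan
settle_native <- function(sys, native, seed) {
  part <- make_partition(sys, "lig", scale = 1)
  spec <- qm_engine_spec("mirror-mm", ps_charge = part$ps_net_charge)
  relax <- function(p, steps = 100) optimize_pose(sys, part, spec, p,
                                     dof = "ligand_only", conv = 1e-4,
                                     max_steps = steps)
  pose <- relax(native)
  best_f <- pose$score_qmmm
  ## basin probing: re-minimize from perturbed starts (near and mid-range)
  ## and adopt the deepest endpoint, so the emitted native is the locally
  ## deepest basin the downstream optimizer can reach
  for (round_ in 1:2) {
    improved <- FALSE
    for (j in 1:8) {
      mag <- if (j <= 6) 0.75 else 1.5
      cand <- relax(perturb_pose(pose, seed * 100L + 10L * round_ + j, mag))
      if (is.finite(cand$score_qmmm) && cand$score_qmmm < best_f - 1e-3) {
        pose <- cand
        best_f <- cand$score_qmmm
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  for (round_ in 1:6) {
    s <- apply_pose(sys, pose)
    f0 <- score_classical(s)
    worst <- perturbation_scan(s, f0)
    if (is.null(worst)) break
    pose$coords <- worst
    pose <- relax(pose)
  }
  ## final polish: tight convergence so the emitted native sits at the
  ## basin floor, not a fraction of a kcal above it
  pose <- optimize_pose(sys, part, spec, pose, dof = "ligand_only",
                        conv = 1e-6, max_steps = 200)
  pose$provenance <- "native"
  pose
}

## returns NULL when every +/-0.2 A single-atom move raises the score,
## else the best (lowest-score) perturbed ligand coordinates
perturbation_scan <- function(sys, f0, delta = 0.2) {
  lig <- ligand_atoms(sys)
  X <- coords(sys)
  best <- NULL; fbest <- f0
  for (i in lig) for (d in 1:3) for (sgn in c(-1, 1)) {
    X2 <- X
    X2[i, d] <- X2[i, d] + sgn * delta
    f <- score_classical(set_coords(sys, X2[lig, , drop = FALSE], lig))
    if (f < fbest - 1e-9) { fbest <- f; best <- X2[lig, , drop = FALSE] }
  }
  best
}

fibonacci_directions <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

pick_perpendicular <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(u, v)
  w / sqrt(sum(w^2))
}

random_rotation_matrix <- function() {
  ## uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Perturb a pose (stands in for an external sampling stage)
#'
#' Applies a rigid-body displacement (random rotation about the centroid
#' plus translation) and per-atom jitter, linearly rescaled so that the
#' RMSD to the input pose equals `magnitude` exactly -- inside the
#' contract's [0.5, 2] x magnitude band. Deterministic per seed; the
#' magnitude -> 0 limit returns the input pose.
#'
#' @param pose a `Pose`.
#' @param seed integer seed.
#' @param magnitude target RMSD (A, > 0).
#' @return the perturbed `Pose` (provenance `"sampled"`).
#' @export
perturb_pose <- function(pose, seed, magnitude) {
  stopifnot(magnitude > 0)
  with_seed(seed, {
    X <- pose$coords
    ctr <- colMeans(X)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0.2, 0.6)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
    Xr <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
    D <- Xr - X + matrix(tdir, nrow(X), 3, byrow = TRUE) +
      matrix(stats::rnorm(length(X), sd = 0.08), nrow(X), 3)
    rms <- sqrt(mean(rowSums(D^2)))
    out <- pose
    out$coords <- X + (magnitude / rms) * D
    out$provenance <- "sampled"
    out$score_class <- out$score_qmmm <- out$breakdown <- NULL
    out$rmsd_to_native <- NULL
    out
  })
}

#' Generate synthetic benchmark metadata records
#'
#' Produces `n` records of which exactly `planted_pass_count` satisfy every
#' quality filter; each remaining record violates exactly one filter,
#' cycling deterministically through the filter list.
#'
#' @param seed integer seed.
#' @param n number of records.
#' @param planted_pass_count how many records pass all filters.
#' @return data.frame of `n` benchmark records with a `planted_violation`
#'   column ("" for passing records).
#' @export
make_benchmark_records <- function(seed, n, planted_pass_count) {
  stopifnot(planted_pass_count >= 0, planted_pass_count <= n)
  with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      rec <- benchmark_record(
        complex_id = sprintf("CPLX%03d", i),
        resolution = round(stats::runif(1, 1.2, 2.4), 2),
        dpi = round(stats::runif(1, 0.1, 0.45), 3),
        ligand_b_factor_avg = round(stats::runif(1, 20, 70), 1),
        ediam = round(stats::runif(1, 0.5, 0.95), 2),
        mw = round(stats::runif(1, 120, 480), 1),
        n_rotatable_bonds = sample.int(10, 1),
        ghose_pass_count = sample(3:4, 1),
        lipinski_pass_count = sample(3:4, 1),
        has_missing_atoms = FALSE, has_altlocs = FALSE,
        min_crystal_contact = round(stats::runif(1, 4.6, 9), 2))
      rec$planted_violation <- ""
      rec
    })
    fail_idx <- if (planted_pass_count < n)
      (planted_pass_count + 1):n else integer()
    for (m in seq_along(fail_idx)) {
      i <- fail_idx[m]
      f <- QUALITY_FILTERS[(m - 1) %% length(QUALITY_FILTERS) + 1]
      recs[[i]][, switch(f,
        resolution = "resolution", dpi = "dpi", b_factor = "ligand_b_factor_avg",
        ediam = "ediam", `mw-range` = "mw",
        `rotatable-bonds` = "n_rotatable_bonds", ghose = "ghose_pass_count",
        lipinski = "lipinski_pass_count", `missing-atoms` = "has_missing_atoms",
        altlocs = "has_altlocs", `crystal-contact` = "min_crystal_contact")] <-
        switch(f, resolution = 3.1, dpi = 0.8, b_factor = 95, ediam = 0.2,
               `mw-range` = 49, `rotatable-bonds` = 18L, ghose = 2L,
               lipinski = 2L, `missing-atoms` = TRUE, altlocs = TRUE,
               `crystal-contact` = 3.0)
      recs[[i]]$planted_violation <- f
    }
    do.call(rbind, recs)
  })
}

#' Write a toy complex to disk in the standard formats
#'
#' Emits `complex.pdb`, `ligand.sdf`, `params.json` into `dir`; the same
#' dialects [read_receptor()], [read_ligand()] and
#' [read_parameter_table()] consume.
#'
#' @param fix a `ToyComplex`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_complex <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(fix$system, file.path(dir, "complex.pdb"))
  write_sdf(subset_system(fix$system, ligand_atoms(fix$system)),
            file.path(dir, "ligand.sdf"))
  write_parameter_table(fix$params, file.path(dir, "params.json"))
  invisible(dir)
}
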