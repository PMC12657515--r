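## toy system with a metal at a controlled distance from the ligand
metal_probe_system <- function(metal_dist) {
  atoms <- data.frame(
    element = c("C", "C", "Zn", "O", "C", "O", "C"),
    x = c(0, 1.5, metal_dist, metal_dist, metal_dist + 1.4,
          metal_dist, metal_dist + 1.4),
    y = c(0, 0, 0, 2.1, 2.1, -2.1, -2.1),
    z = 0,
    charge = c(0.1, -0.1, 2, -0.3, 0.3, -0.3, 0.3),
    lj_epsilon = 0.1, lj_rmin_half = 1.8,
    chain = c("L", "L", "A", "A", "A", "A", "A"),
    resnum = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    residue_name = c("LIG", "LIG", "ZN", "RE1", "RE1", "RE2", "RE2"),
    atom_name = c("C1", "C2", "ZN", "OD", "CA", "OD", "CA"),
    is_ligand = c(TRUE, TRUE, rep(FALSE, 5)), b_factor = 0)
  molecular_system(atoms,
                   bonds = data.frame(i = c(1, 4, 6), j = c(2, 5, 7),
                                      order = 1),
                   metals = 3L, net_charge = 2L, validate = FALSE)
}

test_that("metal inclusion respects the 5 A boundary and pulls coordinators", {
  sys <- metal_probe_system(4.9 + 1.5)       # nearest ligand atom C2 at 4.9
  p <- select_primary_system(sys, "lig+MB")
  expect_true(3 %in% p$ps_atoms)             # metal in PS
  expect_true(4 %in% p$ps_atoms)             # coordinating side-chain O (2.1 A)
  expect_true(6 %in% p$ps_atoms)
  sys2 <- metal_probe_system(5.1 + 1.5)
  p2 <- select_primary_system(sys2, "lig+MB")
  expect_setequal(p2$ps_atoms, c(1, 2))      # ligand only
})

test_that("covalent binding residue is automatically added in mode lig", {
  fix <- cached_fix(4, with_covalent = TRUE, optimize_native = FALSE)
  p <- select_primary_system(fix$system, "lig")
  bound_res <- fix$system$atoms$resnum[fix$system$covalent_link[2]]
  sc <- which(!fix$system$atoms$is_ligand &
                fix$system$atoms$resnum == bound_res &
                !(fix$system$atoms$atom_name %in% c("CA")))
  expect_true(all(sc %in% p$ps_atoms))
  expect_false(any(fix$system$atoms$atom_name[p$ps_atoms] == "CA"))
  expect_equal(nrow(p$cut_bonds), 1)         # the CB-CA cut
})

test_that("box membership is any-atom-inside, whole residue included", {
  fix <- cached_fix(11, optimize_native = FALSE)
  sys <- fix$system
  ctr <- colMeans(as.matrix(sys$atoms[sys$atoms$is_ligand,
                                      c("x", "y", "z")]))
  ## residue 1's innermost atom distance from center along x sets the edge
  cd <- which(sys$atoms$resnum == 1 & !sys$atoms$is_ligand &
                sys$atoms$atom_name == "CD")
  dx <- max(abs(as.numeric(sys$atoms[cd, c("x", "y", "z")]) - ctr))
  ## edge placing that atom 0.01 A inside the face
  p <- select_primary_system(sys, "lig+Box+MB", box_edge = 2 * (dx + 0.01),
                             box_center = ctr)
  res1 <- which(!sys$atoms$is_ligand & sys$atoms$resnum == 1 &
                  sys$atoms$residue_name == "P01")
  expect_true(all(res1 %in% p$ps_atoms))     # included whole (backbone mode)
  ## edge placing it just outside
  p2 <- select_primary_system(sys, "lig+Box+MB", box_edge = 2 * (dx - 0.01),
                              box_center = ctr)
  expect_false(any(res1 %in% p2$ps_atoms) &&
                 !any(res1 %in% which(sys$atoms$is_ligand)))
})

test_that("every mode yields a true bipartition and monotone PS growth", {
  fix <- cached_fix(12, with_metal = TRUE, optimize_native = FALSE)
  sys <- fix$system
  sizes <- c()
  for (mode in c("lig", "lig+MB", "lig+Box6+MB", "lig+Box8+MB",
                 "lig+Box10+MB", "lig+Box12+MB")) {
    p <- select_primary_system(sys, mode)
    expect_length(intersect(p$ps_atoms, p$ss_atoms), 0)
    expect_setequal(union(p$ps_atoms, p$ss_atoms), seq_len(nrow(sys$atoms)))
    sizes <- c(sizes, length(p$ps_atoms))
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("Box mode without an edge is a config error", {
  fix <- cached_fix(11, optimize_native = FALSE)
  expect_error(select_primary_system(fix$system, "lig+Box+MB"),
               "box_edge")
})

test_that("link atoms: collinear placement at the configured length", {
  ## two bonded atoms across the boundary: Cbeta at origin, Calpha at 1.53
  atoms <- data.frame(
    element = c("C", "C"), x = c(0, 1.53), y = 0, z = 0,
    charge = c(0, -0.2), lj_epsilon = 0.1, lj_rmin_half = 2,
    chain = "A", resnum = 1L, residue_name = "RES",
    atom_name = c("CB", "CA"), is_ligand = c(TRUE, FALSE), b_factor = 0)
  sys <- molecular_system(atoms, bonds = data.frame(i = 1, j = 2, order = 1),
                          validate = FALSE)
  p <- make_partition(sys, "lig", link_length = 1.10, scale = 0.5)
  expect_equal(nrow(p$link_atoms), 1)
  expect_equal(unlist(p$link_atoms[1, c("x", "y", "z")]),
               c(x = 1.10, y = 0, z = 0), tolerance = 1e-12)
  ## the first classical neighbor's embedding charge is exactly zero
  expect_identical(p$embedding$charge[p$embedding$atom == 2], 0)
})

test_that("link geometry is equivariant under rigid motions", {
  fix <- cached_fix(4, with_covalent = TRUE, optimize_native = FALSE)
  for (seed in 1:5) {
    sys <- rigid_motion(fix$system, seed)
    p <- make_partition(sys, "lig", link_length = 1.10)
    X <- as.matrix(sys$atoms[, c("x", "y", "z")])
    for (r in seq_len(nrow(p$link_atoms))) {
      h <- X[p$link_atoms$qm_host[r], ]
      m <- X[p$link_atoms$mm_neighbor[r], ]
      l <- unlist(p$link_atoms[r, c("x", "y", "z")])
      expect_equal(sqrt(sum((l - h)^2)), 1.10, tolerance = 1e-6)
      u <- (m - h) / sqrt(sum((m - h)^2))
      expect_equal(sum(cross_prod(l - h, u)^2), 0, tolerance = 1e-12)
    }
  }
})

test_that("embedding charges scale FF charges, zeroed at boundary neighbors", {
  fix <- cached_fix(4, with_covalent = TRUE, optimize_native = FALSE)
  sys <- fix$system
  for (scale in c(0.5, 1.0)) {
    p <- make_partition(sys, "lig", scale = scale)
    zeroed <- p$zeroed_neighbors
    for (r in seq_len(nrow(p$embedding))) {
      at <- p$embedding$atom[r]
      expected <- if (at %in% zeroed) 0 else scale * sys$atoms$charge[at]
      expect_identical(p$embedding$charge[r], expected)
    }
    ## summation oracle
    ss_q <- sum(sys$atoms$charge[setdiff(p$ss_atoms, zeroed)])
    expect_equal(sum(p$embedding$charge), scale * ss_q, tolerance = 1e-12)
  }
  ## -0.80 e at scale 0.5 -> -0.40 e
  sysq <- sys
  ss1 <- setdiff(which(!sysq$atoms$is_ligand), integer())[10]
  sysq$atoms$charge[ss1] <- -0.80
  p <- make_partition(sysq, "lig", scale = 0.5)
  if (!(ss1 %in% p$zeroed_neighbors) && ss1 %in% p$ss_atoms)
    expect_equal(p$embedding$charge[p$embedding$atom == ss1], -0.40)
  expect_error(embedding_charges(p, sysq, scale = 0), "scale")
})

test_that("cutting a ring bond is an unsupported topology", {
  ## 4-ring with two atoms flagged ligand -> both cut bonds lie on the cycle
  atoms <- data.frame(
    element = "C", x = c(0, 1.5, 1.5, 0), y = c(0, 0, 1.5, 1.5), z = 0,
    charge = 0, lj_epsilon = 0.1, lj_rmin_half = 2,
    chain = "A", resnum = 1L, residue_name = "RNG",
    atom_name = paste0("C", 1:4), is_ligand = c(TRUE, TRUE, FALSE, FALSE),
    b_factor = 0)
  sys <- molecular_system(atoms,
                          bonds = data.frame(i = c(1, 2, 3, 4),
                                             j = c(2, 3, 4, 1), order = 1),
                          validate = FALSE)
  expect_error(select_primary_system(sys, "lig"), "ring")
})

test_that("glycine-like residue without side chain is skipped with warning", {
  atoms <- data.frame(
    element = c("C", "C", "Zn", "C"),
    x = c(0, 1.5, 4.0, 5.5), y = 0, z = 0,
    charge = c(0, 0, 2, 0), lj_epsilon = 0.1, lj_rmin_half = 1.8,
    chain = c("L", "L", "A", "A"), resnum = c(1L, 1L, 2L, 3L),
    residue_name = c("LIG", "LIG", "ZN", "GLY"),
    atom_name = c("C1", "C2", "ZN", "CA"),
    is_ligand = c(TRUE, TRUE, FALSE, FALSE), b_factor = 0)
  sys <- molecular_system(atoms, bonds = data.frame(i = 1, j = 2, order = 1),
                          metals = 3L, net_charge = 2L, validate = FALSE)
  ## metal at 2.5 A from C2, GLY CA at 1.5 A from metal -> coordinator
  expect_warning(p <- select_primary_system(sys, "lig+MB"),
                 "no side chain")
  expect_false(4 %in% p$ps_atoms)
})

test_that("backbone-inclusion mode shifts peptide cuts to C-CA bonds", {
  ## 3-residue peptide backbone, middle residue selected via a box
  mk <- function(rn, x0) data.frame(
    element = c("N", "C", "C", "O", "C"), x = x0 + c(0, 1.4, 2.4, 2.4, 1.4),
    y = c(0, 0.4, -0.4, -1.6, 1.9), z = 0,
    charge = c(-0.3, 0.1, 0.5, -0.5, 0.2), lj_epsilon = 0.1,
    lj_rmin_half = 1.9, chain = "A", resnum = rn, residue_name = "ALA",
    atom_name = c("N", "CA", "C", "O", "CB"), is_ligand = FALSE,
    b_factor = 0)
  lig <- data.frame(element = c("C", "C"), x = c(4.3, 5.8), y = 4, z = 0,
                    charge = c(0.1, -0.1), lj_epsilon = 0.1,
                    lj_rmin_half = 1.9, chain = "L", resnum = 1L,
                    residue_name = "LIG", atom_name = c("C1", "C2"),
                    is_ligand = TRUE, b_factor = 0)
  atoms <- rbind(lig, mk(1L, 0), mk(2L, 3), mk(3L, 6))
  nb <- function(r) 2 + (r - 1) * 5          # offset of residue r block
  bonds <- do.call(rbind, c(
    list(data.frame(i = 1, j = 2, order = 1)),
    lapply(1:3, function(r) data.frame(
      i = nb(r) + c(1, 2, 3, 2), j = nb(r) + c(2, 3, 4, 5), order = 1)),
    lapply(1:2, function(r) data.frame(i = nb(r) + 3, j = nb(r + 1) + 1,
                                       order = 1))))
  sys <- molecular_system(atoms, bonds, validate = FALSE)
  ctr <- c(mean(atoms$x[atoms$resnum == 2 & !atoms$is_ligand]), 0.2, 0)
  p <- select_primary_system(sys, "lig+Box+MB", box_edge = 3.2,
                             sidechain_only = FALSE, box_center = ctr)
  cuts <- p$cut_bonds
  nm <- sys$atoms$atom_name
  cut_names <- apply(cuts, 1, function(r) paste(sort(nm[r]), collapse = "-"))
  expect_true(all(cut_names == "C-CA"))
})
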