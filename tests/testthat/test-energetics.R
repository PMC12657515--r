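test_that("Coulomb, LJ minimum and cutoff behave exactly as specified", {
  ## two +1 e charges at 1.0 A, no LJ -> 332.0637 kcal/mol
  sys <- two_charge_system(1, 1, 1.0)
  bd <- mm_terms(sys)
  expect_equal(bd$e_intra_lig, 332.0637, tolerance = 1e-10)
  ## LJ pair at r = Rmin -> -eps
  sys <- two_charge_system(0, 0, 4.0, eps = 0.2, rmin_half = 2.0)
  sys$atoms$charge <- c(0, 0)
  expect_error(mm_terms(sys), NA)
  expect_equal(mm_terms(sys)$e_intra_lig, -0.2, tolerance = 1e-12)
  ## pair at 12.01 A with 12 A cutoff -> zero nonbonded
  sys <- two_charge_system(1, 1, 12.01, eps = 0.2, rmin_half = 2.0)
  expect_equal(mm_terms(sys, cutoff = 12)$e_intra_lig, 0)
  expect_gt(mm_terms(sys, cutoff = 13)$e_intra_lig, 0)
})

test_that("vectorized nonbonded energies match a naive double loop", {
  for (seed in c(2, 9)) {
    fix <- cached_fix(seed, optimize_native = FALSE)
    sys <- fix$system
    bd <- mm_terms(sys, cutoff = 12)
    ## naive oracle over all pairs with explicit rule re-implementation
    a <- sys$atoms
    X <- as.matrix(a[, c("x", "y", "z")])
    e <- rbind(as.matrix(sys$bonds[, c("i", "j")]))
    n <- nrow(a)
    near <- function(i, j, k) {
      ## topological distance <= 2?
      nb <- function(v) unique(c(e[e[, 1] %in% v, 2], e[e[, 2] %in% v, 1]))
      j %in% nb(i) || j %in% nb(nb(i))
    }
    lj <- elec <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!a$is_ligand[i] && !a$is_ligand[j]) next     # rigid-rigid omitted
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d > 12 || near(i, j)) next
      eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
      rm6 <- ((a$lj_rmin_half[i] + a$lj_rmin_half[j]) / d)^6
      lj <- lj + eps * (rm6^2 - 2 * rm6)
      elec <- elec + 332.0637 * a$charge[i] * a$charge[j] / d
    }
    nb_vec <- bd$e_intra_lig + bd$e_vdw_lig_rec + bd$e_elec_lig_rec -
      sum(qmmdock:::bonded_energy(sys, seq_len(n)))
    expect_equal(nb_vec, lj + elec, tolerance = 1e-10)
  }
})

test_that("every energy term is invariant under rigid motion", {
  fix <- cached_fix(12, with_metal = TRUE, optimize_native = FALSE)
  sys <- fix$system
  bd0 <- mm_terms(sys)
  sv0 <- gb_sa_solvation(sys)
  ss0 <- ss_self_repulsion(make_partition(sys, "lig")$embedding)
  for (seed in 1:3) {
    sys2 <- rigid_motion(sys, seed)
    bd <- mm_terms(sys2)
    for (f in c("e_intra_lig", "e_vdw_lig_rec", "e_elec_lig_rec",
                "e_mm_complex"))
      expect_equal(bd[[f]], bd0[[f]], tolerance = 1e-8)
    sv <- gb_sa_solvation(sys2)
    expect_equal(sv$g_solv_elec, sv0$g_solv_elec, tolerance = 1e-8)
    ## numerical SASA uses a fixed spherical grid: invariant only to
    ## quadrature accuracy (~2-3% at 96 points), unlike the analytic terms
    expect_equal(sv$g_solv_np, sv0$g_solv_np, tolerance = 0.04)
    expect_equal(ss_self_repulsion(make_partition(sys2, "lig")$embedding),
                 ss0, tolerance = 1e-8)
  }
})

test_that("GB matches the closed-form Born ion and behaves at limits", {
  ## single ion: dG = -166.03 q^2 (1/eps_in - 1/eps_out) / R
  for (q in c(-1, 1, 2)) for (R in c(1.5, 2.0)) {
    sys <- molecular_system(data.frame(
      element = "C", x = 0, y = 0, z = 0, charge = q,
      lj_epsilon = 0.1, lj_rmin_half = R, is_ligand = TRUE),
      net_charge = round(q), validate = FALSE)
    sv <- gb_sa_solvation(sys)
    born <- -(332.0637 / 2) * q^2 * (1 / 2 - 1 / 78.5) / R
    expect_equal(sv$g_solv_elec, born, tolerance = 1e-6)
    expect_lt(sv$g_solv_elec, 0)               # favorable for any single charge
  }
  ## all charges zero -> exactly zero polar term
  fix <- cached_fix(11, optimize_native = FALSE)
  sys <- fix$system
  sv <- gb_sa_solvation(sys, charges = rep(0, nrow(sys$atoms)))
  expect_identical(sv$g_solv_elec, 0)
  expect_gte(sv$g_solv_np, 0)
})

test_that("nonpolar term of a single sphere matches the analytic area", {
  sys <- molecular_system(data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 0,
    lj_epsilon = 0.1, lj_rmin_half = 2.0, is_ligand = TRUE),
    validate = FALSE)
  sv <- gb_sa_solvation(sys, gamma = 0.015, probe = 1.4)
  expect_equal(sv$g_solv_np, 0.015 * 4 * pi * 3.4^2, tolerance = 0.01)
  expect_error(gb_sa_solvation(sys, gamma = -1), "negative")
})

test_that("SS self-repulsion: formula oracle and degenerate cases", {
  expect_identical(ss_self_repulsion(data.frame(x = 0, y = 0, z = 0,
                                                charge = 1)), 0)
  emb <- data.frame(x = c(0, 2), y = 0, z = 0, charge = c(0.5, 0.5))
  expect_equal(ss_self_repulsion(emb), 332.0637 * 0.25 / 2.0,
               tolerance = 1e-12)
  ## random set vs direct double loop
  set.seed(5)
  emb <- data.frame(x = runif(8, -4, 4), y = runif(8, -4, 4),
                    z = runif(8, -4, 4), charge = runif(8, -1, 1))
  oracle <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    oracle <- oracle + 332.0637 * emb$charge[i] * emb$charge[j] /
      sqrt(sum((emb[i, 1:3] - emb[j, 1:3])^2))
  }
  expect_equal(ss_self_repulsion(emb), oracle, tolerance = 1e-10)
  dup <- data.frame(x = c(0, 0), y = 0, z = 0, charge = c(1, 1))
  expect_error(ss_self_repulsion(dup), "singularity")
})

test_that("Morse-like metal binding potential", {
  p <- list(D = 30, a = 1.5, r0 = 2.1)
  expect_equal(mmbp_energy(2.1, p), -30)
  expect_equal(mmbp_energy(2.1 + 50 / 1.5, p), 0, tolerance = 1e-6 * 30)
  expect_equal(mmbp_energy(2.6, p), 30 * (1 - exp(-0.75))^2 - 30,
               tolerance = 1e-12)
  expect_error(mmbp_energy(2, list(D = -1, a = 1, r0 = 1)))
  ## hooked into the classical score for a metal fixture
  fix <- cached_fix(12, with_metal = TRUE, optimize_native = FALSE)
  s0 <- score_classical(fix$system)
  s1 <- score_classical(fix$system, mmbp_params = list(
    list(metal_element = "Zn", D = 30, a = 1.5, r0 = 2.1)))
  expect_false(isTRUE(all.equal(s0, s1)))
})

test_that("analytic MM gradient matches central finite differences", {
  fix <- cached_fix(6, optimize_native = FALSE)
  sys <- qmmdock:::with_exclusions(fix$system)
  lig <- which(sys$atoms$is_ligand)
  G <- qmmdock:::mm_gradient(sys, lig)
  h <- 1e-5
  cols <- c("x", "y", "z")
  for (ii in seq_along(lig)) for (d in 1:3) {
    sp <- sys; sp$atoms[[cols[d]]][lig[ii]] <-
        sp$atoms[[cols[d]]][lig[ii]] + h
    sm <- sys; sm$atoms[[cols[d]]][lig[ii]] <-
        sm$atoms[[cols[d]]][lig[ii]] - h
    num <- (mm_terms(sp)$e_mm_complex - mm_terms(sm)$e_mm_complex) / (2 * h)
    expect_equal(G[ii, d], num, tolerance = 1e-5,
                 label = sprintf("atom %d dim %d", ii, d))
  }
})

test_that("EnergyBreakdown totals re-sum from stored components", {
  fix <- cached_fix(2, optimize_native = FALSE)
  bd <- mm_terms(fix$system)
  expect_equal(bd$e_mm_complex,
               bd$e_intra_lig + bd$e_intra_recflex + bd$e_vdw_lig_rec +
                 bd$e_elec_lig_rec, tolerance = 1e-8)
  det <- score_classical(fix$system, details = TRUE)
  b <- det$breakdown
  expect_equal(det$score,
               b$e_intra_lig + b$e_intra_recflex + b$e_vdw_lig_rec +
                 b$e_elec_lig_rec + b$g_solv_elec + b$g_solv_np + b$e_mmbp,
               tolerance = 1e-10)
})
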