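diatomic <- function(els = c("C", "C"), r = 1.5) {
  molecular_system(data.frame(
    element = els, x = c(0, r), y = 0, z = 0, charge = 0,
    lj_epsilon = 0.1, lj_rmin_half = 2, is_ligand = TRUE),
    bonds = data.frame(i = 1, j = 2, order = 1), validate = FALSE)
}

test_that("engine contract holds for every registered built-in engine", {
  fix <- cached_fix(3, optimize_native = FALSE)
  part <- make_partition(fix$system, "lig", scale = 0.5)
  for (name in c("mirror-mm", "eem")) {
    spec <- qm_engine_spec(name, ps_charge = part$ps_net_charge)
    r1 <- compute_qm(fix$system, part, spec)
    r2 <- compute_qm(fix$system, part, spec)
    expect_true(r1$converged, label = name)
    expect_true(all(is.finite(c(r1$e_qm_ps, r1$e_qm_elec_ps_ss))))
    expect_identical(r1$e_qm_ps, r2$e_qm_ps, label = name)  # deterministic
    expect_lt(abs(sum(r1$qm_charges) - spec$ps_charge), 0.01)
  }
})

test_that("mirror engine reproduces the PS MM energy and cross Coulomb", {
  fix <- cached_fix(4, with_covalent = TRUE, optimize_native = FALSE)
  part <- make_partition(fix$system, "lig", scale = 0.5)
  spec <- qm_engine_spec("mirror-mm", ps_charge = part$ps_net_charge)
  r <- compute_qm(fix$system, part, spec)
  expect_equal(r$e_qm_ps,
               qmmdock:::mm_energy_selection(fix$system, part$ps_atoms),
               tolerance = 1e-10)
  expect_equal(r$e_qm_elec_ps_ss,
               qmmdock:::ps_ss_coulomb(fix$system, part), tolerance = 1e-10)
  expect_identical(r$qm_charges, fix$system$atoms$charge[part$ps_atoms])
})

test_that("EEM symmetry: homonuclear diatomic charges", {
  sys <- diatomic()
  part <- make_partition(sys, "lig", scale = 1)
  r0 <- compute_qm(sys, part, qm_engine_spec("eem", ps_charge = 0))
  expect_equal(r0$qm_charges, c(0, 0), tolerance = 1e-10)
  rm1 <- compute_qm(sys, part, qm_engine_spec("eem", ps_charge = -1))
  expect_equal(rm1$qm_charges, c(-0.5, -0.5), tolerance = 1e-10)
})

test_that("embedding response lowers the energy of a polarizable diatomic", {
  sys <- diatomic()
  part <- make_partition(sys, "lig", scale = 1)
  spec <- qm_engine_spec("eem", ps_charge = 0)
  gas <- compute_qm(sys, part, spec)
  e_gas <- gas$e_qm_ps + gas$e_qm_elec_ps_ss
  part$embedding <- data.frame(atom = NA_integer_, x = -2.5, y = 0, z = 0,
                               charge = 1)
  emb <- compute_qm(sys, part, spec)
  e_emb <- emb$e_qm_ps + emb$e_qm_elec_ps_ss
  expect_lt(e_emb, e_gas)
  ## brute-force grid oracle over the single free charge q1 (q2 = -q1)
  tab <- qmmdock:::EEM_TABLE
  chi <- tab$chi[tab$element == "C"] * qmmdock:::EV_TO_KCAL
  eta <- tab$eta[tab$element == "C"] * qmmdock:::EV_TO_KCAL
  k <- 332.0637
  e_of <- function(q1) {
    q <- c(q1, -q1)
    V <- k * 1 / c(2.5, 4.0)
    sum(chi * q + eta * q^2) + k * q[1] * q[2] / 1.5 + sum(q * V)
  }
  qs <- seq(-4, 4, by = 1e-4)
  e_grid <- min(vapply(qs, e_of, 0))
  ## engine energy contains the PS LJ/bonded part; remove it for comparison
  lj <- qmmdock:::nonbonded_energy(sys, 1:2)[["lj"]]
  expect_equal(e_emb - lj, e_grid, tolerance = 1e-4)
})

test_that("EEM energy is invariant under atom reordering and rigid motion", {
  sys <- diatomic(c("C", "O"))
  part <- make_partition(sys, "lig", scale = 1)
  spec <- qm_engine_spec("eem", ps_charge = 0)
  r1 <- compute_qm(sys, part, spec)
  ## reorder atoms
  sys2 <- sys
  sys2$atoms <- sys2$atoms[2:1, ]
  rownames(sys2$atoms) <- NULL
  sys2$bonds$i <- 1; sys2$bonds$j <- 2
  part2 <- make_partition(sys2, "lig", scale = 1)
  r2 <- compute_qm(sys2, part2, spec)
  expect_equal(r2$e_qm_ps, r1$e_qm_ps, tolerance = 1e-9)
  expect_equal(sort(r2$qm_charges), sort(r1$qm_charges), tolerance = 1e-9)
  ## rigid motion
  sys3 <- rigid_motion(sys, 42)
  part3 <- make_partition(sys3, "lig", scale = 1)
  r3 <- compute_qm(sys3, part3, spec)
  expect_equal(r3$e_qm_ps, r1$e_qm_ps, tolerance = 1e-8)
})

test_that("EEM failure modes: duplicate positions, unknown element", {
  sys <- diatomic()
  sys$atoms$x[2] <- 0                     # coincident atoms
  part <- make_partition(sys, "lig", scale = 1)
  r <- compute_qm(sys, part, qm_engine_spec("eem", ps_charge = 0))
  expect_false(r$converged)
  sys2 <- diatomic(c("C", "Xx"))
  part2 <- make_partition(sys2, "lig", scale = 1)
  expect_error(compute_qm(sys2, part2, qm_engine_spec("eem", ps_charge = 0)),
               "parameter error")
})

test_that("numerical gradient matches the analytic MM gradient (mirror)", {
  fix <- cached_fix(5, optimize_native = FALSE)
  sys <- fix$system
  ## zero the receptor LJ so that e_qm_ps + e_qm_elec (which carries no
  ## PS<->SS Lennard-Jones) coincides with e_mm_complex, whose analytic
  ## gradient is the oracle; scale 1 makes the embedding equal FF charges
  sys$atoms$lj_epsilon[!sys$atoms$is_ligand] <- 0
  sys <- qmmdock:::with_exclusions(sys)
  part <- make_partition(sys, "lig", scale = 1)
  spec <- qm_engine_spec("mirror-mm", ps_charge = part$ps_net_charge,
                         nb_cutoff = 1e6)
  gn2 <- numerical_gradient(sys, part, spec, h = 1e-4)
  ga <- qmmdock:::mm_gradient(sys, part$ps_atoms, cutoff = 1e6)
  expect_lt(max(abs(gn2 - ga)), 1e-4)
  ## gradient of an isolated atom is zero
  iso <- molecular_system(data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 1, lj_epsilon = 0.1,
    lj_rmin_half = 2, is_ligand = TRUE), net_charge = 1, validate = FALSE)
  ip <- make_partition(iso, "lig", scale = 1)
  gi <- numerical_gradient(iso, ip, qm_engine_spec("mirror-mm",
                                                   ps_charge = 1))
  expect_equal(gi, matrix(0, 1, 3), tolerance = 1e-8)
})

test_that("net force on an isolated PS with no embedding is ~zero", {
  sys <- diatomic()
  sys$atoms$charge <- c(0.3, -0.3)
  part <- make_partition(sys, "lig", scale = 1)   # SS empty
  g <- numerical_gradient(sys, part,
                          qm_engine_spec("mirror-mm", ps_charge = 0))
  expect_equal(colSums(g), c(0, 0, 0), tolerance = 1e-6)
})

test_that("external adapter exchange files round-trip", {
  fix <- cached_fix(4, with_covalent = TRUE, optimize_native = FALSE)
  part <- make_partition(fix$system, "lig", scale = 0.5)
  spec <- qm_engine_spec("external-test", ps_charge = part$ps_net_charge)
  fin <- withr::local_tempfile()
  write_qm_exchange(fix$system, part, spec, fin)
  txt <- readLines(fin)
  expect_true(any(startsWith(txt, "PSATOMS")))
  expect_equal(sum(startsWith(txt, "H  ")), nrow(part$link_atoms))
  ## fabricate a result file and parse it
  fout <- withr::local_tempfile()
  writeLines(c("E_QM_PS -123.456", "E_QM_ELEC_PS_SS -7.89", "CONVERGED 1",
               "CHARGES", "0.1", "-0.1", "GRADIENT", "0 0 0", "0 0 0"),
             fout)
  r <- read_qm_result(fout)
  expect_equal(r$e_qm_ps, -123.456)
  expect_equal(r$e_qm_elec_ps_ss, -7.89)
  expect_true(r$converged)
  expect_equal(r$qm_charges, c(0.1, -0.1))
  expect_equal(dim(r$gradient), c(2, 3))
})
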