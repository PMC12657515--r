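## symmetric "ring" ligand: 4-membered square with alternating elements
## C-N-C-N has a 2-fold graph automorphism (rotation by 180 degrees)
square_ring <- function() {
  molecular_system(data.frame(
    element = c("C", "N", "C", "N"),
    x = c(0, 1.5, 1.5, 0), y = c(0, 0, 1.5, 1.5), z = 0,
    charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.8,
    chain = "L", resnum = 1L, residue_name = "LIG",
    atom_name = c("C1", "N2", "C3", "N4"), is_ligand = TRUE, b_factor = 0),
    bonds = data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 1), order = 1),
    validate = FALSE)
}

test_that("symmetry RMSD: identity, automorphism, pure translation", {
  sys <- square_ring()
  X <- as.matrix(sys$atoms[, c("x", "y", "z")])
  expect_equal(symmetry_rmsd(sys, X, X), 0)
  ## 180-degree rotation about the ring center maps the graph onto itself:
  ## symmetry RMSD 0 although the identity mapping moves every atom
  ctr <- colMeans(X)
  Xrot <- sweep(-sweep(X, 2, ctr), 2, ctr, "+")   # 180 deg in-plane
  expect_equal(symmetry_rmsd(sys, X, Xrot), 0, tolerance = 1e-10)
  ident <- sqrt(mean(rowSums((X - Xrot)^2)))
  expect_gt(ident, 1)
  ## asymmetric ligand translated by (1,0,0): RMSD exactly 1
  fix <- cached_fix(11, optimize_native = FALSE)
  lsys <- fix$system
  A <- fix$native$coords
  B <- sweep(A, 2, c(1, 0, 0), "+")
  expect_equal(symmetry_rmsd(lsys, A, B), 1.0, tolerance = 1e-10)
  ## symmetry RMSD never exceeds the identity-mapping RMSD
  for (s in 1:5) {
    P <- perturb_pose(fix$native, s, 1.0)$coords
    expect_lte(symmetry_rmsd(lsys, A, P), coord_rmsd_mat(A, P) + 1e-12)
  }
  expect_error(symmetry_rmsd(lsys, A, A[-1, ]), "mismatch")
})

test_that("success judged on the best-scored converged pose, <= inclusive", {
  fix <- cached_fix(11, optimize_native = FALSE)
  sys <- fix$system
  shift <- function(d, score, conv = TRUE) {
    p <- fix$native
    p$coords <- sweep(p$coords, 2, c(d, 0, 0), "+")
    p$score_qmmm <- score; p$converged <- conv
    p
  }
  ## RMSD exactly 1.50 -> success (inclusive boundary)
  r <- judge_success(sys, list(shift(1.50, -10)), fix$native)
  expect_true(r$success)
  expect_equal(r$best_rmsd, 1.50, tolerance = 1e-12)
  ## 1.51 -> failure
  expect_false(judge_success(sys, list(shift(1.51, -10)), fix$native)$success)
  ## only the best-scored pose counts
  r2 <- judge_success(sys, list(shift(3.0, -12), shift(0.2, -10)),
                      fix$native)
  expect_false(r2$success)
  expect_equal(r2$best_rmsd, 3.0, tolerance = 1e-10)
  ## non-converged best is skipped; none converged -> status
  r3 <- judge_success(sys, list(shift(3.0, -12, conv = FALSE),
                                shift(0.2, -10)), fix$native)
  expect_true(r3$success)
  r4 <- judge_success(sys, list(shift(0.2, -10, conv = FALSE)), fix$native)
  expect_equal(r4$status, "non-converged")
  ## monotone in cutoff
  p <- shift(1.2, -10)
  for (c1 in c(1.3, 1.5, 2.0))
    expect_true(judge_success(sys, list(p), fix$native, cutoff = c1)$success ==
                  (1.2 <= c1))
})

test_that("scoring-failure flag follows its definition", {
  fix <- cached_fix(11, optimize_native = FALSE)
  sys <- fix$system
  shift <- function(d, score) {
    p <- fix$native
    p$coords <- sweep(p$coords, 2, c(d, 0, 0), "+")
    p$score_qmmm <- score
    p
  }
  ## a better-scored far pose is a scoring failure
  expect_true(detect_scoring_failure(sys, list(shift(3, -52)), fix$native,
                                     native_score = -50))
  ## all poses worse than native: no failure
  expect_false(detect_scoring_failure(sys, list(shift(3, -48)), fix$native,
                                      native_score = -50))
  ## a better-scored near-native pose is fine
  expect_false(detect_scoring_failure(sys, list(shift(0.4, -52)), fix$native,
                                      native_score = -50))
})

test_that("success_rate aggregates with the converged-only denominator", {
  out <- function(conv, succ) list(converged = conv, success = succ)
  res <- c(replicate(7, out(TRUE, TRUE), simplify = FALSE),
           replicate(3, out(TRUE, FALSE), simplify = FALSE))
  r <- success_rate(res)
  expect_equal(r$succ, 70)
  expect_equal(r$conv, 100)
  res2 <- c(replicate(7, out(TRUE, TRUE), simplify = FALSE),
            replicate(2, out(TRUE, FALSE), simplify = FALSE),
            list(out(FALSE, NA)))
  r2 <- success_rate(res2)
  expect_equal(r2$succ, 100 * 7 / 9, tolerance = 1e-10)
  expect_equal(r2$conv, 90)
  expect_equal(success_rate(list(out(FALSE, NA)))$status,
               "no converged complexes")
})

test_that("success_rate matches a brute-force recount on 50 synthetic outcomes", {
  set.seed(31)
  res <- lapply(1:50, function(i) list(
    converged = runif(1) > 0.1,
    success = runif(1) > 0.4,
    success_ns = runif(1) > 0.5))
  r <- success_rate(res)
  n_conv <- n_succ <- n_ns <- 0
  for (x in res) {
    if (x$converged) {
      n_conv <- n_conv + 1
      if (x$success) n_succ <- n_succ + 1
      if (x$success_ns) n_ns <- n_ns + 1
    }
  }
  expect_equal(r$succ, 100 * n_succ / n_conv, tolerance = 1e-12)
  expect_equal(r$succ_ns, 100 * n_ns / n_conv, tolerance = 1e-12)
  expect_equal(r$conv, 100 * n_conv / 50, tolerance = 1e-12)
})

test_that("quality filters: boundaries and unevaluable fields", {
  base <- benchmark_record("X", 2.0, 0.3, 50, 0.6, 300, 5, 4, 4, FALSE,
                           FALSE, 6.0)
  expect_true(apply_quality_filters(base)$pass)
  tweak <- function(field, value) {
    r <- base; r[[field]] <- value; r
  }
  expect_equal(apply_quality_filters(tweak("mw", 49))$violated, "mw-range")
  expect_equal(apply_quality_filters(tweak("mw", 501))$violated, "mw-range")
  expect_true(apply_quality_filters(tweak("mw", 50))$pass)      # inclusive
  expect_equal(apply_quality_filters(tweak("n_rotatable_bonds", 18))$violated,
               "rotatable-bonds")                               # strict <
  expect_true(apply_quality_filters(tweak("n_rotatable_bonds", 17))$pass)
  expect_true(apply_quality_filters(tweak("resolution", 2.5))$pass)
  expect_false(apply_quality_filters(tweak("resolution", 2.51))$pass)
  expect_false(apply_quality_filters(tweak("ediam", 0.39))$pass)
  expect_false(apply_quality_filters(tweak("min_crystal_contact", 4.49))$pass)
  ## missing field -> unevaluable, record fails
  r <- base; r$dpi <- NA
  out <- apply_quality_filters(r)
  expect_false(out$pass)
  expect_true("dpi:unevaluable" %in% out$violated)
})

test_that("quality filters agree with an independent predicate on 12 records", {
  tab <- make_benchmark_records(9, 12, 5)
  oracle <- function(r) {
    r$resolution <= 2.5 && r$dpi <= 0.5 && r$ligand_b_factor_avg <= 80 &&
      r$ediam >= 0.4 && r$mw >= 50 && r$mw <= 500 &&
      r$n_rotatable_bonds < 18 && r$ghose_pass_count >= 3 &&
      r$lipinski_pass_count >= 3 && !r$has_missing_atoms && !r$has_altlocs &&
      r$min_crystal_contact >= 4.5
  }
  for (i in seq_len(nrow(tab))) {
    expect_identical(apply_quality_filters(tab[i, ])$pass,
                     oracle(as.list(tab[i, ])), label = paste("record", i))
  }
})

test_that("drug filter counts follow the canonical thresholds", {
  fix <- cached_fix(11, optimize_native = FALSE, ligand_size = 6)
  lig <- qmmdock:::subset_system(fix$system,
                                 which(fix$system$atoms$is_ligand))
  ## 6 heavy atoms, MW ~ 80: fails Ghose MW/atom-count, passes Lipinski
  counts <- drug_filter_counts(lig, logp = 1.0, molar_refractivity = 50)
  expect_equal(counts$lipinski_pass_count, 4L)
  expect_equal(counts$ghose_pass_count, 2L)   # logp + MR pass only
})
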