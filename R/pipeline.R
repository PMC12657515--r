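## Hybrid QM/MM scoring pipeline ---------------------------------------------

#' Create a pose
#'
#' A pose is the coordinates of the movable atoms (ligand, plus flexible
#' primary-system atoms when applicable) together with scores and
#' provenance.
#'
#' @param sys parent `MolecularSystem`.
#' @param coords matrix `length(movable) x 3`; default: current coordinates.
#' @param movable atom indices the pose moves; default: the ligand.
#' @param provenance one of `"sampled"`, `"native"`, `"native-relaxed"`,
#'   `"optimized"`, `"refined"`.
#' @return an object of class `Pose`.
#' @export
new_pose <- function(sys, coords = NULL, movable = NULL,
                     provenance = "sampled") {
  if (is.null(movable)) movable <- ligand_atoms(sys)
  if (is.null(coords)) {
    X <- as.matrix(sys$atoms[movable, c("x", "y", "z"), drop = FALSE])
    dimnames(X) <- NULL
    coords <- X
  }
  structure(list(coords = coords, movable = movable,
                 score_class = NULL, score_qmmm = NULL, breakdown = NULL,
                 rmsd_to_native = NULL, provenance = provenance,
                 converged = TRUE),
            class = "Pose")
}

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("Pose [%s]: %d movable atoms", x$provenance, nrow(x$coords)))
  if (!is.null(x$score_class)) cat(sprintf(", Score_class %.3f", x$score_class))
  if (!is.null(x$score_qmmm)) cat(sprintf(", Score_QMMM %.3f", x$score_qmmm))
  if (!is.null(x$rmsd_to_native)) cat(sprintf(", RMSD %.2f A", x$rmsd_to_native))
  cat("\n")
  invisible(x)
}

## write a pose's coordinates into a system copy
apply_pose <- function(sys, pose) {
  if (is.null(pose)) return(sys)
  set_coords(sys, pose$coords, pose$movable)
}

## plain (identity-mapping) RMSD between two coordinate matrices
coord_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

## best available score of a pose (QM/MM when present, else classical)
pose_score <- function(p) p$score_qmmm %||% p$score_class %||% Inf

#' Subtractive QM/MM energy of the complex
#'
#' Assembles the five-term subtractive energy
#' `E_QMMM = E_QM(PS) + E_QM_elec(PS<->SS) + E_MM(Complex) - E_MM(PS)
#'  - E_MM_elec(PS<->SS)`,
#' storing every term separately. When the engine's
#' `includes_ss_self_energy` flag is set (HF/DFT-like codes), the
#' electrostatic self-repulsion of the embedding charge set is subtracted a
#' posteriori (`ss_self_correction` holds the signed applied correction).
#' `E_MM(Complex)` is the score-relevant MM energy; the constant internal
#' energy of the rigid receptor is excluded throughout.
#'
#' @param sys parameterized `MolecularSystem` (coordinates at the pose
#'   being scored).
#' @param partition complete `Partition`.
#' @param qm a converged `QMResult` from [compute_qm()].
#' @param spec the `QMEngineSpec` used.
#' @param cutoff nonbonded cutoff (A).
#' @return an `EnergyBreakdown`; the scalar total is given by
#'   [qmmm_total()].
#' @export
qmmm_energy <- function(sys, partition, qm, spec, cutoff = 12) {
  if (!isTRUE(qm$converged))
    stop("qmmm_energy: QM result not converged")
  mm <- mm_terms(sys, cutoff = cutoff)
  e_mm_ps <- mm_energy_selection(sys, partition$ps_atoms, cutoff = cutoff)
  e_mm_el <- ps_ss_coulomb(sys, partition)
  corr <- if (isTRUE(spec$includes_ss_self_energy))
    -ss_self_repulsion(partition$embedding) else 0
  energy_breakdown(
    e_qm_ps = qm$e_qm_ps, e_qm_elec_ps_ss = qm$e_qm_elec_ps_ss,
    e_mm_complex = mm$e_mm_complex, e_mm_ps = e_mm_ps,
    e_mm_elec_ps_ss = e_mm_el,
    e_intra_lig = mm$e_intra_lig, e_intra_recflex = mm$e_intra_recflex,
    e_vdw_lig_rec = mm$e_vdw_lig_rec, e_elec_lig_rec = mm$e_elec_lig_rec,
    ss_self_correction = corr)
}

#' Scalar subtractive QM/MM energy from a breakdown
#' @param bd an `EnergyBreakdown` from [qmmm_energy()].
#' @return kcal/mol.
#' @export
qmmm_total <- function(bd)
  bd$e_qm_ps + bd$e_qm_elec_ps_ss + bd$e_mm_complex - bd$e_mm_ps -
  bd$e_mm_elec_ps_ss + bd$ss_self_correction

#' Classical MM-GBSA-style score
#'
#' `Score_class = E_intra(Lig) + E_intra(Rec_flex) + E_vdW(Lig<->Rec) +
#'  E_elec(Lig<->Rec) + dG_solv_elec + dG_solv_np` with an optional
#' Morse-like metal binding potential term when `mmbp_params` is given.
#'
#' @param sys parameterized `MolecularSystem`.
#' @param pose optional `Pose`; when given, scoring happens at the pose
#'   coordinates.
#' @param cutoff nonbonded cutoff (A, default 12).
#' @param mmbp_params optional list of MMBP parameter entries (see
#'   [mmbp_energy()]).
#' @param gamma,probe,n_points solvation surrogate parameters (see
#'   [gb_sa_solvation()]).
#' @param details if `TRUE` return `list(score, breakdown)` instead of the
#'   bare number.
#' @return the score (kcal/mol), or a list when `details = TRUE`.
#' @export
score_classical <- function(sys, pose = NULL, cutoff = 12,
                            mmbp_params = NULL, gamma = 0.015, probe = 1.4,
                            n_points = 96, details = FALSE) {
  sys <- apply_pose(sys, pose)
  bd <- mm_terms(sys, cutoff = cutoff)
  sv <- gb_sa_solvation(sys, gamma = gamma, probe = probe, cutoff = cutoff,
                        n_points = n_points)
  bd$g_solv_elec <- sv$g_solv_elec
  bd$g_solv_np <- sv$g_solv_np
  bd$e_mmbp <- mmbp_total(sys, mmbp_params)
  score <- bd$e_intra_lig + bd$e_intra_recflex + bd$e_vdw_lig_rec +
    bd$e_elec_lig_rec + bd$g_solv_elec + bd$g_solv_np + bd$e_mmbp
  if (details) list(score = score, breakdown = bd) else score
}

#' Hybrid QM/MM score
#'
#' `Score_QMMM = E_QMMM(Complex) + dG_solv_elec + dG_solv_np`. Solvation
#' uses force-field charges everywhere except that, with
#' `charge_source = "qm-derived"`, the PS atom charges are replaced by the
#' engine's QM-derived (Mulliken-like) charges, link-atom charge folded
#' into its QM host. A non-converged QM result scores `+Inf` (pose excluded
#' downstream).
#'
#' @param sys,partition,spec as in [qmmm_energy()].
#' @param pose optional `Pose` to score.
#' @param charge_source `"ff"` or `"qm-derived"`.
#' @param qm optional precomputed `QMResult` (computed when `NULL`).
#' @param cutoff,gamma,probe,n_points as in [score_classical()].
#' @param details if `TRUE` return `list(score, breakdown, qm)`.
#' @return the score (kcal/mol; `+Inf` on engine non-convergence), or a
#'   list when `details = TRUE`.
#' @export
score_qmmm <- function(sys, partition, spec, pose = NULL,
                       charge_source = c("ff", "qm-derived"), qm = NULL,
                       cutoff = 12, gamma = 0.015, probe = 1.4,
                       n_points = 96, details = FALSE) {
  charge_source <- match.arg(charge_source)
  sys <- apply_pose(sys, pose)
  partition <- refresh_partition(partition, sys)
  if (is.null(qm)) qm <- compute_qm(sys, partition, spec)
  if (!isTRUE(qm$converged)) {
    message("score_qmmm: QM engine did not converge; pose scored +Inf")
    if (details) return(list(score = Inf, breakdown = NULL, qm = qm))
    return(Inf)
  }
  bd <- qmmm_energy(sys, partition, qm, spec, cutoff = cutoff)
  charges <- sys$atoms$charge
  if (charge_source == "qm-derived" && !is.null(qm$qm_charges))
    charges[partition$ps_atoms] <- qm$qm_charges
  sv <- gb_sa_solvation(sys, charges = charges, gamma = gamma, probe = probe,
                        cutoff = cutoff, n_points = n_points)
  bd$g_solv_elec <- sv$g_solv_elec
  bd$g_solv_np <- sv$g_solv_np
  score <- qmmm_total(bd) + bd$g_solv_elec + bd$g_solv_np
  if (details) list(score = score, breakdown = bd, qm = qm) else score
}

#' Greedy leader clustering of poses
#'
#' Poses are visited by ascending score; a pose joins the first cluster
#' whose representative lies within `radius` (symmetry-adapted ligand RMSD),
#' otherwise it founds a new cluster. Clusters are ordered by representative
#' score.
#'
#' @param sys parent system (supplies the ligand molecular graph).
#' @param poses list of scored `Pose`s sharing one topology.
#' @param radius clustering radius (A, default 2).
#' @return list of `Cluster` objects: `list(representative, members)` with
#'   members sorted by score.
#' @export
cluster_poses <- function(sys, poses, radius = 2.0) {
  if (length(poses) == 0) return(list())
  ord <- order(vapply(poses, pose_score, 0))
  auto <- ligand_automorphisms(sys)
  lig <- ligand_atoms(sys)
  heavy <- which(sys$atoms$element[lig] != "H")
  clusters <- list()
  for (ix in ord) {
    p <- poses[[ix]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_ <- clusters[[ci]]$representative
      r <- symmetry_rmsd_coords(p$coords[heavy, , drop = FALSE],
                                rep_$coords[heavy, , drop = FALSE], auto)
      if (r <= radius) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, list(p))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1]] <-
        structure(list(representative = p, members = list(p)),
                  class = "Cluster")
  }
  clusters
}

#' Select poses for QM/MM treatment
#'
#' `best_of_n`: the representatives of the best `n` clusters. `all_of_n`:
#' every member of the best `n` clusters. When a (relaxed) native pose is
#' supplied it is appended unless an already selected pose lies within
#' 0.01 A of it.
#'
#' @param clusters list from [cluster_poses()].
#' @param mode `"best_of_n"` or `"all_of_n"`.
#' @param n number of clusters to draw from (clamped to the available
#'   count).
#' @param native optional `Pose` to append.
#' @return list of `Pose`s.
#' @export
select_for_qmmm <- function(clusters, mode = c("best_of_n", "all_of_n"),
                            n = 10L, native = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  top <- clusters[seq_len(min(n, length(clusters)))]
  sel <- if (mode == "best_of_n") lapply(top, `[[`, "representative")
  else unlist(lapply(top, `[[`, "members"), recursive = FALSE)
  if (!is.null(native)) {
    dup <- any(vapply(sel, function(p)
      coord_rmsd(p$coords, native$coords) <= 0.01, TRUE))
    if (!dup) sel <- c(sel, list(native))
  }
  sel
}

#' Constrained local optimization of a pose under the QM/MM score
#'
#' Quasi-Newton (BFGS) minimization with a backtracking Armijo line search
#' on the Cartesian coordinates of the movable set: the ligand atoms only,
#' or all primary-system atoms. Accepted steps never increase the score;
#' the run terminates when the energy change between successive accepted
#' steps falls below `conv` or after `max_steps` steps. Gradients are
#' assembled from the analytic MM gradient plus finite differences of the
#' solvation terms for the mirror engine, or full finite differences for
#' engines that provide no gradient.
#'
#' @param sys,partition,spec as in [score_qmmm()].
#' @param pose starting `Pose`.
#' @param dof `"ligand_only"` or `"full_ps"`.
#' @param conv energy convergence criterion (kcal/mol, default 0.05; the
#'   tighter 0.01 is appropriate for covalent/heme work).
#' @param max_steps step cap (default 200).
#' @param charge_source,cutoff,gamma,probe,n_points scoring options.
#' @param solv_mode `"reevaluate"` (default; solvation recomputed every
#'   step) or `"frozen"` (solvation fixed at the starting geometry during
#'   optimization, re-evaluated once at the end).
#' @return the optimized `Pose` with `score_qmmm`, `breakdown`, `converged`
#'   flag, step count (`$steps`) and the accepted-energy trajectory
#'   (`$trajectory`).
#' @export
optimize_pose <- function(sys, partition, spec, pose,
                          dof = c("ligand_only", "full_ps"), conv = 0.05,
                          max_steps = 200L,
                          charge_source = c("ff", "qm-derived"),
                          cutoff = 12, gamma = 0.015, probe = 1.4,
                          n_points = 96,
                          solv_mode = c("reevaluate", "frozen")) {
  dof <- match.arg(dof)
  charge_source <- match.arg(charge_source)
  solv_mode <- match.arg(solv_mode)
  stopifnot(conv > 0)
  sys0 <- with_exclusions(apply_pose(sys, pose))
  movable <- if (dof == "ligand_only") ligand_atoms(sys)
  else partition$ps_atoms
  if (dof == "full_ps")
    sys0$flex_receptor <- setdiff(partition$ps_atoms, ligand_atoms(sys))
  ## objective split: E_QMMM part and solvation part, so each gradient can
  ## use an appropriate finite-difference step (the numerical SASA surface
  ## is piecewise constant; its slope is estimated with a wide step)
  qmmm_part <- function(xvec) {
    s <- set_coords(sys0, matrix(xvec, ncol = 3), movable)
    p2 <- refresh_partition(partition, s)
    qm <- compute_qm(s, p2, spec)
    if (!isTRUE(qm$converged)) return(Inf)
    qmmm_total(qmmm_energy(s, p2, qm, spec, cutoff = cutoff))
  }
  solv_charges <- function(s, p2) {
    charges <- s$atoms$charge
    if (charge_source == "qm-derived") {
      qm <- compute_qm(s, p2, spec)
      if (isTRUE(qm$converged) && !is.null(qm$qm_charges))
        charges[p2$ps_atoms] <- qm$qm_charges
    }
    charges
  }
  solv_part <- function(xvec) {
    s <- set_coords(sys0, matrix(xvec, ncol = 3), movable)
    p2 <- refresh_partition(partition, s)
    sv <- gb_sa_solvation(s, charges = solv_charges(s, p2), gamma = gamma,
                          probe = probe, cutoff = cutoff,
                          n_points = n_points)
    sv$g_solv_elec + sv$g_solv_np
  }
  ## GB polar part alone (the nonpolar term has an analytic gradient)
  gb_part <- function(xvec) {
    s <- set_coords(sys0, matrix(xvec, ncol = 3), movable)
    p2 <- refresh_partition(partition, s)
    X <- coords(s)
    gb_polar_energy(X, pmax(s$atoms$lj_rmin_half, 1.0),
                    solv_charges(s, p2), cutoff = cutoff)
  }
  frozen_solv <- if (solv_mode == "frozen")
    solv_part(as.vector(coords(sys0)[movable, , drop = FALSE])) else NULL
  obj <- function(xvec) {
    q <- qmmm_part(xvec)
    if (!is.finite(q)) return(Inf)
    q + (frozen_solv %||% solv_part(xvec))
  }
  grad <- function(xvec, fx) {
    gq <- if (spec$method == "mirror-mm") {
      s <- set_coords(sys0, matrix(xvec, ncol = 3), movable)
      as.vector(mm_gradient(s, movable, cutoff = cutoff))
    } else {
      numeric_obj_gradient(qmmm_part, xvec, h = 1e-4)
    }
    if (solv_mode == "frozen") return(gq)
    ## nonpolar term: analytic gradient of the smoothed surface area;
    ## polar GB term: central differences (cheap without the area)
    s <- set_coords(sys0, matrix(xvec, ncol = 3), movable)
    X <- coords(s)
    gnp <- gamma * smoothed_sasa_gradient(X, pmax(s$atoms$lj_rmin_half, 1.0),
                                          movable, probe = probe,
                                          n_points = n_points)
    gq + as.vector(gnp) + numeric_obj_gradient(gb_part, xvec, h = 0.01)
  }
  x <- as.vector(coords(sys0)[movable, , drop = FALSE])
  f <- obj(x)
  if (!is.finite(f))
    return(finish_pose(pose, sys0, partition, spec, movable, x, f,
                       converged = FALSE, steps = 0L, traj = f,
                       charge_source, cutoff, gamma, probe, n_points))
  nd <- length(x)
  H <- diag(nd)
  traj <- f
  steps <- 0L
  converged <- FALSE
  g <- tryCatch(grad(x, f), error = function(e) NULL)
  if (is.null(g))
    return(finish_pose(pose, sys0, partition, spec, movable, x, f,
                       converged = FALSE, steps = 0L, traj = traj,
                       charge_source, cutoff, gamma, probe, n_points))
  if (sqrt(sum(g^2)) < 1e-8) converged <- TRUE
  line_search <- function(p) {
    alpha <- 1
    for (ls in 1:40) {
      fn <- tryCatch(obj(x + alpha * p), error = function(e) Inf)
      if (is.finite(fn) && fn <= f + 1e-4 * alpha * sum(g * p))
        return(list(ok = TRUE, alpha = alpha, fn = fn))
      alpha <- alpha / 2
    }
    list(ok = FALSE)
  }
  while (!converged && steps < max_steps) {
    p <- -as.vector(H %*% g)
    if (sum(p * g) >= 0) { H <- diag(nd); p <- -g }
    ls <- line_search(p)
    if (!ls$ok && !identical(p, -g)) {
      ## quasi-Newton direction rejected (e.g. on the corrugated numerical
      ## SASA surface): restart from steepest descent before giving up
      H <- diag(nd); p <- -g
      ls <- line_search(p)
    }
    if (!ls$ok) { converged <- TRUE; break }  # no descent step: local minimum
    alpha <- ls$alpha; fn <- ls$fn
    xn <- x + alpha * p
    gn <- tryCatch(grad(xn, fn), error = function(e) NULL)
    if (is.null(gn)) {                     # engine failure mid-trajectory:
      return(finish_pose(pose, sys0, partition, spec, movable, x, f,
                         converged = FALSE, steps = steps, traj = traj,
                         charge_source, cutoff, gamma, probe, n_points))
    }
    sv_ <- xn - x; yv <- gn - g
    sy <- sum(sv_ * yv)
    if (sy > 1e-10) {                    # damped BFGS update
      rho <- 1 / sy
      I <- diag(nd)
      H <- (I - rho * outer(sv_, yv)) %*% H %*% (I - rho * outer(yv, sv_)) +
        rho * outer(sv_, sv_)
    }
    steps <- steps + 1L
    dE <- f - fn
    x <- xn; f <- fn; g <- gn
    traj <- c(traj, f)
    if (dE < conv) { converged <- TRUE; break }
  }
  finish_pose(pose, sys0, partition, spec, movable, x, f,
              converged = TRUE, steps = steps, traj = traj,
              charge_source, cutoff, gamma, probe, n_points,
              conv_flag = converged || steps < max_steps)
}

## numerical gradient of an arbitrary objective (central differences, or
## one-sided forward differences when speed matters more than accuracy)
numeric_obj_gradient <- function(obj, x, h = 1e-4, forward = FALSE) {
  g <- numeric(length(x))
  f0 <- if (forward) obj(x) else NULL
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    if (forward) {
      g[i] <- (obj(xp) - f0) / h
    } else {
      xm <- x; xm[i] <- xm[i] - h
      g[i] <- (obj(xp) - obj(xm)) / (2 * h)
    }
  }
  g
}

finish_pose <- function(pose, sys0, partition, spec, movable, x, f,
                        converged, steps, traj, charge_source, cutoff,
                        gamma, probe, n_points, conv_flag = converged) {
  out <- pose
  out$coords <- matrix(x, ncol = 3)
  out$movable <- movable
  s <- set_coords(sys0, out$coords, movable)
  det <- score_qmmm(s, partition, spec, charge_source = charge_source,
                    cutoff = cutoff, gamma = gamma, probe = probe,
                    n_points = n_points, details = TRUE)
  out$score_qmmm <- det$score
  out$breakdown <- det$breakdown
  out$converged <- conv_flag && is.finite(det$score)
  out$steps <- steps
  out$trajectory <- traj
  out$provenance <- "optimized"
  out
}

#' Rescore or re-optimize poses with a second (higher-level) engine
#'
#' `single_point`: rescore each pose at its current geometry with
#' `spec2`'s engine. `optimize`: run a short [optimize_pose()] with the
#' second engine. Non-converged poses are flagged and excluded from the
#' ranking (the converged fraction is reported alongside).
#'
#' @param sys,partition as usual.
#' @param poses list of `Pose`s.
#' @param spec2 `QMEngineSpec` of the refinement engine.
#' @param mode `"single_point"` or `"optimize"`.
#' @param max_steps step cap for `"optimize"` mode (default 25).
#' @param ... further scoring options passed through.
#' @return list with `poses` (all, rescored), `ranking` (converged poses by
#'   ascending score) and `conv_fraction`.
#' @export
refine <- function(sys, partition, poses, spec2,
                   mode = c("single_point", "optimize"), max_steps = 25L,
                   ...) {
  mode <- match.arg(mode)
  out <- lapply(poses, function(p) {
    if (mode == "single_point") {
      det <- score_qmmm(sys, partition, spec2, pose = p, details = TRUE, ...)
      p$score_qmmm <- det$score
      p$breakdown <- det$breakdown
      p$converged <- is.finite(det$score)
      p$provenance <- "refined"
      p
    } else {
      p2 <- optimize_pose(sys, partition, spec2, p, max_steps = max_steps,
                          ...)
      p2$provenance <- "refined"
      p2
    }
  })
  conv <- vapply(out, function(p) isTRUE(p$converged), TRUE)
  ranking <- out[conv][order(vapply(out[conv], pose_score, 0))]
  if (!any(conv))
    message("refine: no pose converged; empty ranking")
  list(poses = out, ranking = ranking,
       conv_fraction = mean(conv))
}

#' Relax the native pose
#'
#' Short ligand-only [optimize_pose()] (default cap 50 steps) so the
#' experimental pose can be added to the ensemble on the same footing as
#' sampled poses.
#'
#' @param sys,partition,spec as usual.
#' @param native the native `Pose`.
#' @param max_steps step cap.
#' @param ... further [optimize_pose()] options.
#' @return the relaxed `Pose` with provenance `"native-relaxed"`.
#' @export
relax_native <- function(sys, partition, spec, native, max_steps = 50L,
                         ...) {
  p <- optimize_pose(sys, partition, spec, native, dof = "ligand_only",
                     max_steps = max_steps, ...)
  p$provenance <- "native-relaxed"
  p
}
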