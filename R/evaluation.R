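## Redocking evaluation: symmetry-adapted RMSD, success, scoring failure -----

## graph automorphisms of the ligand heavy-atom graph preserving element
## and bond order; returns a list of permutation vectors (identity first)
ligand_automorphisms <- function(sys) {
  lig <- ligand_atoms(sys)
  heavy <- lig[sys$atoms$element[lig] != "H"]
  if (length(heavy) == 0) stop("ligand has no heavy atoms")
  map <- match(heavy, lig)
  e <- bond_edges(sys)
  sub <- e[e[, 1] %in% heavy & e[, 2] %in% heavy, , drop = FALSE]
  ord <- sys$bonds$order[match(paste(e[, 1], e[, 2]),
                               paste(sys$bonds$i, sys$bonds$j))]
  ord[is.na(ord)] <- 1
  ord <- ord[e[, 1] %in% heavy & e[, 2] %in% heavy]
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(sub) > 0)
    g <- igraph::add_edges(g, t(matrix(match(as.integer(sub), heavy),
                                       ncol = 2)))
  vcol <- as.integer(factor(sys$atoms$element[heavy]))
  ecol <- as.integer(factor(ord))
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol)
  perms <- lapply(maps, as.integer)
  ident <- vapply(perms, function(p) all(p == seq_along(p)), TRUE)
  c(perms[ident], perms[!ident])
}

## minimum RMSD over automorphism mappings; coordinates in the fixed
## receptor frame (no superposition)
symmetry_rmsd_coords <- function(A, B, perms) {
  best <- Inf
  for (p in perms) {
    r <- sqrt(mean(rowSums((A - B[p, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}

#' Symmetry-adapted RMSD between two ligand poses
#'
#' Minimum heavy-atom RMSD over the graph automorphisms of the ligand
#' (mappings preserving element and bond order), computed in the receptor
#' frame without superposition -- the docking convention. A topologically
#' symmetric ligand (e.g. a flipped two-fold symmetric ring) therefore
#' scores 0 where the identity mapping would not.
#'
#' @param sys `MolecularSystem` supplying the ligand molecular graph.
#' @param pose_a,pose_b `Pose` objects (or coordinate matrices over the
#'   ligand atoms in system order).
#' @return RMSD in A.
#' @export
symmetry_rmsd <- function(sys, pose_a, pose_b) {
  lig <- ligand_atoms(sys)
  getc <- function(p) {
    if (inherits(p, "Pose")) {
      if (!identical(as.integer(p$movable[seq_along(lig)]), as.integer(lig)) &&
          !all(lig %in% p$movable))
        stop("graph mismatch: pose does not cover the ligand atoms")
      p$coords[match(lig, p$movable), , drop = FALSE]
    } else as.matrix(p)
  }
  A <- getc(pose_a); B <- getc(pose_b)
  if (!all(dim(A) == dim(B)) || nrow(A) != length(lig))
    stop("graph mismatch: poses have different topologies")
  heavy <- which(sys$atoms$element[lig] != "H")
  perms <- ligand_automorphisms(sys)
  symmetry_rmsd_coords(A[heavy, , drop = FALSE], B[heavy, , drop = FALSE],
                       perms)
}

#' Judge redocking success
#'
#' Success iff the best-scored converged pose lies within `cutoff`
#' (inclusive; default 1.5 A) symmetry-adapted RMSD of the native pose.
#' With no converged pose the complex is counted out of the success-rate
#' denominator (status `"non-converged"`).
#'
#' @param sys system supplying the ligand graph.
#' @param ranked list of scored `Pose`s (any order; ranked internally).
#' @param native native `Pose`.
#' @param cutoff success RMSD cutoff (A).
#' @return list with `success`, `best_rmsd` (RMSD of the best-scored
#'   converged pose), `status` (`"ok"` or `"non-converged"`).
#' @export
judge_success <- function(sys, ranked, native, cutoff = 1.5) {
  conv <- Filter(function(p) isTRUE(p$converged) &&
                   is.finite(pose_score(p)), ranked)
  if (length(conv) == 0)
    return(list(success = NA, best_rmsd = NA_real_,
                status = "non-converged"))
  best <- conv[[which.min(vapply(conv, pose_score, 0))]]
  r <- symmetry_rmsd(sys, best, native)
  list(success = r <= cutoff, best_rmsd = r, status = "ok")
}

#' Detect a scoring failure
#'
#' A scoring failure occurs when some pose scores better than the (relaxed)
#' experimental pose while lying further than `cutoff` from it: the scoring
#' function prefers a wrong pose over the truth.
#'
#' @param sys system supplying the ligand graph.
#' @param ranked list of scored `Pose`s.
#' @param native native `Pose` (reference geometry).
#' @param native_score score of the relaxed native pose (kcal/mol).
#' @param cutoff RMSD cutoff (A, default 1.5).
#' @return logical.
#' @export
detect_scoring_failure <- function(sys, ranked, native, native_score,
                                   cutoff = 1.5) {
  for (p in ranked) {
    s <- pose_score(p)
    if (is.finite(s) && s < native_score &&
        symmetry_rmsd(sys, p, native) > cutoff)
      return(TRUE)
  }
  FALSE
}

#' Aggregate per-complex outcomes into success rates
#'
#' `succ` = successes / converged complexes; `conv` = converged / total;
#' `succ_ns` = the same success ratio computed from rankings with the
#' solvation terms excluded from the score. Zero converged complexes yields
#' a status instead of numbers.
#'
#' @param results list of per-complex outcome records: each a list with
#'   logical fields `converged`, `success` and optionally `success_ns`.
#' @return list with percentages `succ`, `succ_ns`, `conv`, and `status`.
#' @export
success_rate <- function(results) {
  n <- length(results)
  conv <- vapply(results, function(r) isTRUE(r$converged), TRUE)
  if (!any(conv))
    return(list(succ = NA_real_, succ_ns = NA_real_,
                conv = if (n > 0) 0 else NA_real_,
                status = "no converged complexes"))
  succ <- vapply(results[conv], function(r) isTRUE(r$success), TRUE)
  ns <- vapply(results[conv], function(r)
    isTRUE(r$success_ns %||% r$success), TRUE)
  list(succ = 100 * mean(succ), succ_ns = 100 * mean(ns),
       conv = 100 * mean(conv), status = "ok")
}
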