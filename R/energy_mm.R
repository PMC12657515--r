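## Classical (MM) energy terms ------------------------------------------------
##
## Conventions (CHARMM-compatible):
##   bond     E = k (b - r0)^2
##   angle    E = ktheta (theta - theta0)^2        theta0 stored in degrees
##   torsion  E = kphi (1 + cos(n phi - delta))    delta stored in degrees
##   LJ 12-6  E = eps [ (Rmin/r)^12 - 2 (Rmin/r)^6 ],  Rmin = ri + rj,
##            eps = sqrt(ei ej)  (Rmin convention: minimum at r = Rmin, depth -eps)
##   Coulomb  E = 332.0637 qi qj / r
## Nonbonded: 1-2 and 1-3 pairs excluded, 1-4 and beyond at full strength,
## pairs beyond the cutoff excluded.

#' Energy breakdown container
#'
#' Stores every term entering the subtractive QM/MM energy and the classical
#' and hybrid scores separately, so that reported totals can always be
#' re-summed from their components.
#'
#' @param ... named numeric fields overriding the zero defaults.
#' @return An object of class `EnergyBreakdown` (named list, kcal/mol).
#' @export
energy_breakdown <- function(...) {
  fields <- list(
    e_qm_ps = 0, e_qm_elec_ps_ss = 0, e_mm_complex = 0, e_mm_ps = 0,
    e_mm_elec_ps_ss = 0, e_intra_lig = 0, e_intra_recflex = 0,
    e_vdw_lig_rec = 0, e_elec_lig_rec = 0, g_solv_elec = 0, g_solv_np = 0,
    e_mmbp = 0, ss_self_correction = 0)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(fields)))
  fields[names(ov)] <- ov
  structure(fields, class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("EnergyBreakdown (kcal/mol):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %12.6f\n", nm, x[[nm]]))
  invisible(x)
}

## "Score-relevant" convention: every MM energy in the package consistently
## omits terms internal to the rigid receptor (constant for any pose), so
## that E_MM(Complex), E_MM(PS) and the classical score share one zero of
## energy. The `active` mask marks ligand + flexible-receptor atoms; a term
## counts only when it involves at least one active atom.
active_mask <- function(sys) {
  m <- sys$atoms$is_ligand
  m[sys$flex_receptor] <- TRUE
  m
}

## bonded-term energies for records whose atoms all lie in `sel` and that
## touch at least one active atom
bonded_energy <- function(sys, sel, active = NULL) {
  X <- coords(sys)
  if (is.null(active)) active <- active_mask(sys)
  e_bond <- 0; e_angle <- 0; e_torsion <- 0
  b <- sys$bonds
  b <- b[b$i %in% sel & b$j %in% sel & b$k > 0 &
           (active[b$i] | active[b$j]), , drop = FALSE]
  if (nrow(b) > 0) {
    d <- sqrt(rowSums((X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE])^2))
    e_bond <- sum(b$k * (d - b$r0)^2)
  }
  an <- sys$angles
  an <- an[an$i %in% sel & an$j %in% sel & an$k_ %in% sel & an$ktheta > 0 &
             (active[an$i] | active[an$j] | active[an$k_]), , drop = FALSE]
  if (nrow(an) > 0) {
    v1 <- X[an$i, , drop = FALSE] - X[an$j, , drop = FALSE]
    v2 <- X[an$k_, , drop = FALSE] - X[an$j, , drop = FALSE]
    ct <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    th <- acos(pmin(1, pmax(-1, ct)))
    e_angle <- sum(an$ktheta * (th - an$theta0 * pi / 180)^2)
  }
  to <- sys$torsions
  to <- to[to$i %in% sel & to$j %in% sel & to$k_ %in% sel & to$l %in% sel &
             to$kphi != 0 &
             (active[to$i] | active[to$j] | active[to$k_] | active[to$l]), ,
           drop = FALSE]
  if (nrow(to) > 0) {
    phi <- vapply(seq_len(nrow(to)), function(r)
      dihedral_angle(X[to$i[r], ], X[to$j[r], ], X[to$k_[r], ], X[to$l[r], ]),
      0)
    e_torsion <- sum(to$kphi * (1 + cos(to$n * phi - to$delta * pi / 180)))
  }
  c(bond = e_bond, angle = e_angle, torsion = e_torsion)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## nonbonded pair energies between two index sets (or within one set when
## setB is NULL); honors exclusions and the cutoff; returns c(lj, elec)
nonbonded_energy <- function(sys, setA, setB = NULL, cutoff = 12,
                             exclusions = NULL, active = NULL) {
  X <- coords(sys); a <- sys$atoms
  if (is.null(exclusions)) exclusions <- get_exclusions(sys)
  if (is.null(active)) active <- active_mask(sys)
  if (is.null(setB)) {
    if (length(setA) < 2) return(c(lj = 0, elec = 0))
    pr <- utils::combn(setA, 2)
    pi_ <- pr[1, ]; pj <- pr[2, ]
  } else {
    g <- expand.grid(i = setA, j = setB)
    pi_ <- g$i; pj <- g$j
  }
  keep <- !exclusions[cbind(pi_, pj)] & (active[pi_] | active[pj])
  pi_ <- pi_[keep]; pj <- pj[keep]
  if (length(pi_) == 0) return(c(lj = 0, elec = 0))
  d <- sqrt(rowSums((X[pi_, , drop = FALSE] - X[pj, , drop = FALSE])^2))
  keep <- d <= cutoff
  pi_ <- pi_[keep]; pj <- pj[keep]; d <- d[keep]
  if (length(pi_) == 0) return(c(lj = 0, elec = 0))
  eps <- sqrt(a$lj_epsilon[pi_] * a$lj_epsilon[pj])
  rmin <- a$lj_rmin_half[pi_] + a$lj_rmin_half[pj]
  sr6 <- (rmin / d)^6
  lj <- sum(eps * (sr6^2 - 2 * sr6))
  elec <- sum(COULOMB_KCAL * a$charge[pi_] * a$charge[pj] / d)
  c(lj = lj, elec = elec)
}

#' Classical MM energy terms of a system
#'
#' Computes the bonded (bond/angle/torsion), Lennard-Jones and Coulomb
#' energies and reports them split the way the classical score needs them:
#' intra-ligand, intra-flexible-receptor, and ligand-receptor cross terms.
#' Bonded terms spanning the covalent ligand-receptor link are counted in
#' the intra-ligand term. The internal energy of the rigid receptor is
#' constant and never computed.
#'
#' @param sys a parameterized `MolecularSystem`.
#' @param cutoff nonbonded cutoff (A), default 12.
#' @return An `EnergyBreakdown` with `e_intra_lig`, `e_intra_recflex`,
#'   `e_vdw_lig_rec`, `e_elec_lig_rec` and `e_mm_complex` (their sum)
#'   populated.
#' @export
mm_terms <- function(sys, cutoff = 12) {
  if (all(sys$atoms$lj_epsilon == 0) && all(sys$atoms$charge == 0) &&
      all(sys$bonds$k == 0))
    stop("mm_terms: parameters not assigned (run assign_parameters first)")
  ex <- get_exclusions(sys)
  lig <- ligand_atoms(sys)
  rec <- receptor_atoms(sys)
  flex <- sys$flex_receptor
  ## ligand internal: every bonded record touching a ligand atom (this
  ## includes the covalent-anchor bond/angle/torsion terms spanning the
  ## ligand-receptor link)
  lig_act <- logical(nrow(sys$atoms)); lig_act[lig] <- TRUE
  bl <- bonded_energy(sys, seq_len(nrow(sys$atoms)), active = lig_act)
  nb_l <- nonbonded_energy(sys, lig, cutoff = cutoff, exclusions = ex)
  e_intra_lig <- sum(bl) + sum(nb_l)
  e_recflex <- 0
  if (length(flex) > 0) {
    fl_act <- logical(nrow(sys$atoms)); fl_act[flex] <- TRUE
    bf <- bonded_energy(sys, rec, active = fl_act)
    nb_f <- nonbonded_energy(sys, flex, cutoff = cutoff, exclusions = ex)
    nb_fr <- nonbonded_energy(sys, flex, setdiff(rec, flex), cutoff = cutoff,
                              exclusions = ex)
    e_recflex <- sum(bf) + sum(nb_f) + sum(nb_fr)
  }
  cross <- nonbonded_energy(sys, lig, rec, cutoff = cutoff, exclusions = ex)
  energy_breakdown(
    e_intra_lig = e_intra_lig,
    e_intra_recflex = e_recflex,
    e_vdw_lig_rec = unname(cross["lj"]),
    e_elec_lig_rec = unname(cross["elec"]),
    e_mm_complex = e_intra_lig + e_recflex + sum(cross))
}

## MM energy of an atom selection plus link atoms (used for E_MM(PS) and by
## the mirror engine): bonded terms wholly inside, nonbonded within the
## selection, both under the score-relevant convention (rigid-receptor
## internal terms omitted). Link atoms carry no charge/LJ/bonded parameters
## and therefore contribute nothing; they are accepted for interface
## symmetry.
mm_energy_selection <- function(sys, sel, cutoff = 12, exclusions = NULL) {
  b <- bonded_energy(sys, sel)
  nb <- nonbonded_energy(sys, sel, cutoff = cutoff, exclusions = exclusions)
  sum(b) + sum(nb)
}

## Analytic gradient of the score-relevant MM energy (e_mm_complex) with
## respect to the coordinates of `movable` atoms. Returns length(movable) x 3.
mm_gradient <- function(sys, movable, cutoff = 12, exclusions = NULL) {
  X <- coords(sys); a <- sys$atoms
  n <- nrow(a)
  if (is.null(exclusions)) exclusions <- get_exclusions(sys)
  G <- matrix(0, n, 3)
  mov <- logical(n); mov[movable] <- TRUE
  ## bonded terms involving at least one movable atom
  b <- sys$bonds[sys$bonds$k > 0, , drop = FALSE]
  if (!is.null(sys$covalent_link) && !is.null(sys$covalent_params)) {
    cp <- sys$covalent_params
    already <- any(b$i == min(sys$covalent_link) &
                     b$j == max(sys$covalent_link))
    if (!already)
      b <- rbind(b, data.frame(i = sys$covalent_link[1],
                               j = sys$covalent_link[2], order = 1,
                               k = cp$k, r0 = cp$r0))
  }
  if (nrow(b) > 0) {
    use <- mov[b$i] | mov[b$j]
    b <- b[use, , drop = FALSE]
    for (r in seq_len(nrow(b))) {
      dv <- X[b$i[r], ] - X[b$j[r], ]
      d <- sqrt(sum(dv^2))
      f <- 2 * b$k[r] * (d - b$r0[r]) / d
      G[b$i[r], ] <- G[b$i[r], ] + f * dv
      G[b$j[r], ] <- G[b$j[r], ] - f * dv
    }
  }
  an <- sys$angles[sys$angles$ktheta > 0, , drop = FALSE]
  if (nrow(an) > 0) {
    use <- mov[an$i] | mov[an$j] | mov[an$k_]
    an <- an[use, , drop = FALSE]
    for (r in seq_len(nrow(an))) {
      i <- an$i[r]; j <- an$j[r]; k <- an$k_[r]
      v1 <- X[i, ] - X[j, ]; v2 <- X[k, ] - X[j, ]
      d1 <- sqrt(sum(v1^2)); d2 <- sqrt(sum(v2^2))
      ct <- sum(v1 * v2) / (d1 * d2)
      ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, ct))
      th <- acos(ct); st <- sqrt(1 - ct^2)
      pref <- 2 * an$ktheta[r] * (th - an$theta0[r] * pi / 180)
      dci <- v2 / (d1 * d2) - ct * v1 / d1^2
      dck <- v1 / (d1 * d2) - ct * v2 / d2^2
      gi <- -pref / st * dci
      gk <- -pref / st * dck
      G[i, ] <- G[i, ] + gi
      G[k, ] <- G[k, ] + gk
      G[j, ] <- G[j, ] - gi - gk
    }
  }
  to <- sys$torsions[sys$torsions$kphi != 0, , drop = FALSE]
  if (nrow(to) > 0) {
    use <- mov[to$i] | mov[to$j] | mov[to$k_] | mov[to$l]
    to <- to[use, , drop = FALSE]
    for (r in seq_len(nrow(to))) {
      i <- to$i[r]; j <- to$j[r]; k <- to$k_[r]; l <- to$l[r]
      b1 <- X[j, ] - X[i, ]; b2 <- X[k, ] - X[j, ]; b3 <- X[l, ] - X[k, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      nb2 <- sqrt(sum(b2^2))
      phi <- atan2(sum(cross3(n1, b2 / nb2) * n2), sum(n1 * n2))
      dEdphi <- -to$kphi[r] * to$n[r] *
        sin(to$n[r] * phi - to$delta[r] * pi / 180)
      dpi_ <- -nb2 / sum(n1^2) * n1
      dpl <- nb2 / sum(n2^2) * n2
      s12 <- sum(b1 * b2) / nb2^2
      s32 <- sum(b3 * b2) / nb2^2
      dpj <- (s12 - 1) * dpi_ - s32 * dpl
      dpk <- (s32 - 1) * dpl - s12 * dpi_
      G[i, ] <- G[i, ] + dEdphi * dpi_
      G[j, ] <- G[j, ] + dEdphi * dpj
      G[k, ] <- G[k, ] + dEdphi * dpk
      G[l, ] <- G[l, ] + dEdphi * dpl
    }
  }
  ## nonbonded: every non-excluded pair with >= 1 movable atom inside cutoff
  lig <- ligand_atoms(sys); rec <- receptor_atoms(sys)
  flex <- sys$flex_receptor
  relevant <- function(i, j) {
    ## pair classes entering e_mm_complex (rigid-rigid receptor excluded)
    li <- a$is_ligand[i]; lj_ <- a$is_ligand[j]
    fi <- i %in% flex; fj <- j %in% flex
    li || lj_ || fi || fj
  }
  cand <- which(mov)
  others <- seq_len(n)
  for (i in cand) {
    js <- others[others != i]
    keep <- !exclusions[i, js]
    js <- js[keep]
    if (length(js) == 0) next
    ## avoid double-count: when both movable, only i < j contributes,
    ## but we need the force on i from every pair, so keep all and use
    ## pairwise forces directly (force on i from pair (i,j)).
    dv <- X[js, , drop = FALSE] -
      matrix(X[i, ], length(js), 3, byrow = TRUE)
    d <- sqrt(rowSums(dv^2))
    keep <- d <= cutoff & vapply(js, relevant, TRUE, i = i)
    js <- js[keep]; dv <- dv[keep, , drop = FALSE]; d <- d[keep]
    if (length(js) == 0) next
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[js])
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[js]
    sr6 <- (rmin / d)^6
    dljdr <- eps * (-12 * sr6^2 / d + 12 * sr6 / d)
    deldr <- -COULOMB_KCAL * a$charge[i] * a$charge[js] / d^2
    f <- (dljdr + deldr) / d    # dE/dr * (1/r), applied to (xi - xj)
    G[i, ] <- G[i, ] - colSums(f * dv)
  }
  G[movable, , drop = FALSE]
}
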