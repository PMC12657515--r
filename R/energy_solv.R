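## Generalized-Born / surface-area solvation surrogate ------------------------
##
## The original scoring uses the FACTS continuum model; its internal
## equations are not reproduced here. Instead a standard pairwise-descreening
## generalized-Born (Hawkins-Cramer-Truhlar style) expression is used with
## the externally specified parameters: solute dielectric 2, solvent
## dielectric 78.5, nonpolar surface tension 0.015 kcal/mol/A^2, probe
## radius 1.4 A, 12 A nonbonded cutoff. Intrinsic radii come from the LJ
## Rmin/2, clamped to >= 1 A.

#' GB/SA solvation energy
#'
#' Polar term: generalized-Born with pairwise-descreening effective radii,
#' `dG = -1/2 k (1/eps_in - 1/eps_out) sum_ij qi qj / fGB(rij, Ri, Rj)` with
#' the canonical `fGB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))`.
#' Nonpolar term: `gamma x SASA` with Shrake-Rupley numerical surface area.
#' The charge vector is an explicit argument so that the primary-system
#' charges can be force-field charges or QM-derived (Mulliken-like) charges.
#'
#' @param sys a parameterized `MolecularSystem`.
#' @param charges per-atom charge vector (e); defaults to the FF charges.
#' @param dielectric_solute solute dielectric (default 2).
#' @param dielectric_solvent solvent dielectric (default 78.5).
#' @param gamma nonpolar surface-tension coefficient (kcal/mol/A^2,
#'   default 0.015).
#' @param probe solvent probe radius (A, default 1.4).
#' @param cutoff pair cutoff for the GB sum (A, default 12).
#' @param n_points Shrake-Rupley sphere points per atom (default 96).
#' @return list with `g_solv_elec` and `g_solv_np` (kcal/mol).
#' @export
gb_sa_solvation <- function(sys, charges = NULL, dielectric_solute = 2,
                            dielectric_solvent = 78.5, gamma = 0.015,
                            probe = 1.4, cutoff = 12, n_points = 96) {
  if (gamma < 0) stop("config error: negative nonpolar surface tension")
  a <- sys$atoms
  if (is.null(charges)) charges <- a$charge
  if (length(charges) != nrow(a))
    stop("gb_sa_solvation: charge vector length must equal atom count")
  X <- coords(sys)
  rho <- pmax(a$lj_rmin_half, 1.0)
  g_elec <- gb_polar_energy(X, rho, charges, dielectric_solute,
                            dielectric_solvent, cutoff)
  sasa <- shrake_rupley_sasa(X, rho, probe = probe, n_points = n_points)
  list(g_solv_elec = g_elec, g_solv_np = gamma * sum(sasa))
}

## generalized-Born polar term alone (no surface area): cheap enough for
## tight finite-difference gradients
gb_polar_energy <- function(X, rho, charges, dielectric_solute = 2,
                            dielectric_solvent = 78.5, cutoff = 12) {
  R <- born_radii_hct(X, rho)
  n <- nrow(X)
  pref <- -GB_HALF_KCAL * (1 / dielectric_solute - 1 / dielectric_solvent)
  g_elec <- pref * sum(charges^2 / R)
  if (n > 1) {
    pr <- utils::combn(n, 2)
    i <- pr[1, ]; j <- pr[2, ]
    d2 <- rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2)
    keep <- d2 <= cutoff^2 & charges[i] != 0 & charges[j] != 0
    i <- i[keep]; j <- j[keep]; d2 <- d2[keep]
    if (length(i) > 0) {
      RiRj <- R[i] * R[j]
      fgb <- sqrt(d2 + RiRj * exp(-d2 / (4 * RiRj)))
      g_elec <- g_elec + pref * 2 * sum(charges[i] * charges[j] / fgb)
    }
  }
  g_elec
}

## Hawkins-Cramer-Truhlar pairwise-descreening effective Born radii.
## For an isolated atom R = rho (the Born closed form is then exact).
born_radii_hct <- function(X, rho, scale = 0.8) {
  n <- nrow(X)
  inv <- 1 / rho
  if (n > 1) {
    r <- as.matrix(stats::dist(X))
    diag(r) <- 1                       # placeholder, masked below
    SJ <- matrix(scale * rho, n, n, byrow = TRUE)   # column j = s*rho_j
    RI <- matrix(rho, n, n)                          # row i = rho_i
    U <- r + SJ
    L <- pmax(RI, abs(r - SJ))
    H <- (1 / L - 1 / U) + (r / 4) * (1 / U^2 - 1 / L^2) +
      (1 / (2 * r)) * log(L / U) + (SJ^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
    H[(r + SJ) <= RI] <- 0             # neighbor buried inside atom i
    diag(H) <- 0
    inv <- inv - 0.5 * rowSums(H)
  }
  ## descreening can only grow the radius; guard against numerical blowup
  R <- ifelse(inv > 1e-3, 1 / inv, 1000)
  pmax(R, rho)
}

## Shrake-Rupley numerical solvent-accessible surface area per atom (A^2),
## fully vectorized: all test points against all overlapping spheres at
## once. The burial test is smoothed over `smooth` A (logistic weight)
## instead of a hard inside/outside decision: for an isolated sphere the
## result is identical, while for overlapping atoms the area becomes a
## differentiable function of the coordinates -- a requirement for the
## gradient-based pose optimizer (a binary test makes the score a step
## function with ~gamma*4*pi*R^2/n_points corrugation).
shrake_rupley_sasa <- function(X, radii, probe = 1.4, n_points = 96,
                               smooth = 0.1) {
  n <- nrow(X)
  pts <- golden_spiral_points(n_points)
  Rs <- radii + probe
  ## all surface points, n*n_points x 3 (atom-major blocks)
  P <- pts[rep(seq_len(n_points), n), , drop = FALSE] *
    Rs[rep(seq_len(n), each = n_points)] +
    X[rep(seq_len(n), each = n_points), , drop = FALSE]
  W <- matrix(1, n_points, n)
  D2 <- as.matrix(stats::dist(X))^2
  reach <- Rs + 12 * smooth
  for (j in seq_len(n)) {
    ## only atom blocks whose spheres can dip below weight ~1
    blocks <- which(D2[, j] < (Rs + reach[j])^2)
    blocks <- blocks[blocks != j]
    if (length(blocks) == 0) next
    rows <- as.vector(outer(seq_len(n_points), (blocks - 1L) * n_points, "+"))
    d <- sqrt((P[rows, 1] - X[j, 1])^2 + (P[rows, 2] - X[j, 2])^2 +
                (P[rows, 3] - X[j, 3])^2)
    W[, blocks] <- W[, blocks] *
      matrix(stats::plogis((d - Rs[j]) / smooth), n_points)
  }
  frac <- colMeans(W)
  4 * pi * Rs^2 * frac
}

## deterministic quasi-uniform points on the unit sphere (golden spiral)
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Analytic gradient of the total smoothed Shrake-Rupley SASA with respect
## to the coordinates of `movable` atoms (A^2/A). The smoothing makes the
## area differentiable: point p on atom i carries weight prod_j w_pj with
## w_pj = plogis((|P_p - X_j| - Rs_j)/s); its derivative has a term for the
## occluding center j and an equal-and-opposite term for the owner i
## (surface points ride rigidly on their atom).
smoothed_sasa_gradient <- function(X, radii, movable, probe = 1.4,
                                   n_points = 96, smooth = 0.1) {
  n <- nrow(X)
  pts <- golden_spiral_points(n_points)
  Rs <- radii + probe
  P <- pts[rep(seq_len(n_points), n), , drop = FALSE] *
    Rs[rep(seq_len(n), each = n_points)] +
    X[rep(seq_len(n), each = n_points), , drop = FALSE]
  ## weights per point against every overlapping center
  W <- matrix(1, n_points, n)
  D2 <- as.matrix(stats::dist(X))^2
  reach <- Rs + 12 * smooth
  pair_dat <- list()
  for (j in seq_len(n)) {
    blocks <- which(D2[, j] < (Rs + reach[j])^2)
    blocks <- blocks[blocks != j]
    if (length(blocks) == 0) next
    rows <- as.vector(outer(seq_len(n_points), (blocks - 1L) * n_points, "+"))
    dv <- cbind(P[rows, 1] - X[j, 1], P[rows, 2] - X[j, 2],
                P[rows, 3] - X[j, 3])
    d <- sqrt(rowSums(dv^2))
    w <- stats::plogis((d - Rs[j]) / smooth)
    W[, blocks] <- W[, blocks] * matrix(w, n_points)
    pair_dat[[j]] <- list(blocks = blocks, dv = dv, d = d, w = w)
  }
  G <- matrix(0, n, 3)
  scale_i <- 4 * pi * Rs^2 / n_points
  for (j in seq_len(n)) {
    pd <- pair_dat[[j]]
    if (is.null(pd)) next
    nb <- length(pd$blocks)
    ## dlog(w)/dd = (1 - w)/s ; chain through the full product W_p
    Wp <- as.vector(W[, pd$blocks])           # product incl. w itself
    coef <- Wp * (1 - pd$w) / smooth / pd$d   # per point-row
    vec <- pd$dv * coef                       # d(total W_p)/dP along +dv
    own <- rep(scale_i[pd$blocks], each = n_points)
    vec <- vec * own
    ## owner atoms move their points with them (+), center j feels (-)
    block_id <- rep(seq_len(nb), each = n_points)
    gx <- rowsum(vec[, 1], block_id); gy <- rowsum(vec[, 2], block_id)
    gz <- rowsum(vec[, 3], block_id)
    G[pd$blocks, 1] <- G[pd$blocks, 1] + gx
    G[pd$blocks, 2] <- G[pd$blocks, 2] + gy
    G[pd$blocks, 3] <- G[pd$blocks, 3] + gz
    G[j, ] <- G[j, ] - c(sum(vec[, 1]), sum(vec[, 2]), sum(vec[, 3]))
  }
  G[movable, , drop = FALSE]
}
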