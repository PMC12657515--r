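## SS self-repulsion correction and the Morse-like metal binding potential ----

#' Electrostatic self-energy of the embedding charge set
#'
#' `sum_{i<j} k qi qj / rij` over the secondary-system embedding charges.
#' Quantum engines that treat the external point charges like nuclei
#' (Hartree-Fock / DFT-like, `includes_ss_self_energy = TRUE`) fold this
#' charge-charge repulsion into their reported energy although it is a pure
#' MM quantity; the scoring pipeline subtracts it a posteriori to avoid
#' double counting. For engines that do not add it, the correction has no
#' effect.
#'
#' @param embedding data.frame with columns `x`, `y`, `z`, `charge`.
#' @return energy in kcal/mol (0 for fewer than two charges).
#' @export
ss_self_repulsion <- function(embedding) {
  n <- nrow(embedding)
  if (is.null(n) || n < 2) return(0)
  X <- as.matrix(embedding[, c("x", "y", "z")])
  q <- embedding$charge
  pr <- utils::combn(n, 2)
  i <- pr[1, ]; j <- pr[2, ]
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  if (any(d < 1e-9 & q[i] * q[j] != 0))
    stop("singularity error: two embedding charges at identical positions")
  keep <- d >= 1e-9
  sum(COULOMB_KCAL * q[i][keep] * q[j][keep] / d[keep])
}

#' Morse-like metal binding potential
#'
#' `E(r) = D (1 - exp(-a (r - r0)))^2 - D`: minimum of depth `-D` at the
#' equilibrium metal-ligand distance `r0`, dissociating to 0. Used as an
#' optional additive term of the classical score to mimic DFT-level
#' metal-ligand (e.g. heme-iron) energetics; the parameters are
#' user-supplied configuration.
#'
#' @param r metal to ligand-atom distance (A); vectorized.
#' @param params list with `D` (kcal/mol), `a` (1/A), `r0` (A), all > 0.
#' @return energy in kcal/mol.
#' @export
mmbp_energy <- function(r, params) {
  stopifnot(params$D > 0, params$a > 0, params$r0 > 0)
  params$D * (1 - exp(-params$a * (r - params$r0)))^2 - params$D
}

## total MMBP contribution for a system: for each metal, the closest ligand
## heavy atom whose element has a configured parameter triple contributes.
mmbp_total <- function(sys, mmbp_params) {
  if (is.null(mmbp_params) || length(sys$metals) == 0) return(0)
  X <- coords(sys)
  lig <- ligand_atoms(sys)
  lig <- lig[sys$atoms$element[lig] != "H"]
  if (length(lig) == 0) return(0)
  total <- 0
  for (m in sys$metals) {
    mel <- sys$atoms$element[m]
    for (p in mmbp_params) {
      if (!is.null(p$metal_element) && p$metal_element != mel) next
      cand <- lig
      if (!is.null(p$ligand_element))
        cand <- lig[sys$atoms$element[lig] == p$ligand_element]
      if (length(cand) == 0) next
      d <- sqrt(rowSums((X[cand, , drop = FALSE] -
                           matrix(X[m, ], length(cand), 3, byrow = TRUE))^2))
      total <- total + mmbp_energy(min(d), p)
    }
  }
  total
}
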