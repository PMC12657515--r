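## Force-field-lite parameter tables -----------------------------------------
##
## A parameter table is a nested list (serialized as JSON):
##   atoms:    named list "RES:NAME" -> {charge, epsilon, rmin_half}
##   bonds:    named list "RES:NAME-RES:NAME" -> {k, r0}
##   angles:   named list "RES:NAME-RES:NAME-RES:NAME" -> {ktheta, theta0}
##   torsions: named list of 4-atom keys -> {kphi, n, delta}
## This is a deliberately tiny stand-in for a full force field: enough to
## parameterize the synthetic fixtures and any user system with matching
## atom naming.

atom_param_key <- function(sys, i)
  paste0(sys$atoms$residue_name[i], ":", sys$atoms$atom_name[i])

#' Assign force-field parameters to a system from a parameter table
#'
#' Populates per-atom charges and Lennard-Jones parameters and the bonded
#' term parameters (bond/angle/torsion) from a nested parameter table.
#' Angle and torsion records are derived from the bond graph and kept only
#' when the table provides parameters for them. Re-assignment is
#' idempotent.
#'
#' @param sys a `MolecularSystem`.
#' @param params parameter table (nested list, see [read_parameter_table()]).
#' @return The system with parameters populated; `net_charge` is set to the
#'   rounded charge sum and the charge-sum invariant is checked.
#' @export
assign_parameters <- function(sys, params) {
  a <- sys$atoms
  keys <- paste0(a$residue_name, ":", a$atom_name)
  for (i in seq_along(keys)) {
    p <- params$atoms[[keys[i]]]
    if (is.null(p))
      stop(sprintf("parameter error: no parameters for atom %s in residue %s %d",
                   a$atom_name[i], a$residue_name[i], a$resnum[i]))
    a$charge[i] <- p$charge
    a$lj_epsilon[i] <- p$epsilon
    a$lj_rmin_half[i] <- p$rmin_half
  }
  sys$atoms <- a
  e <- bond_edges(sys)
  lookup <- function(tbl, idx_list) {
    key1 <- paste(vapply(idx_list, function(i) keys[i], ""), collapse = "-")
    key2 <- paste(rev(vapply(idx_list, function(i) keys[i], "")),
                  collapse = "-")
    tbl[[key1]] %||% tbl[[key2]]
  }
  if (nrow(sys$bonds) > 0 && length(params$bonds)) {
    for (r in seq_len(nrow(sys$bonds))) {
      bp <- lookup(params$bonds, c(sys$bonds$i[r], sys$bonds$j[r]))
      if (!is.null(bp)) { sys$bonds$k[r] <- bp$k; sys$bonds$r0[r] <- bp$r0 }
    }
  }
  if (length(params$angles)) {
    ang <- derive_angles(e)
    if (nrow(ang) > 0) {
      keep <- list()
      for (r in seq_len(nrow(ang))) {
        ap <- lookup(params$angles, c(ang$i[r], ang$j[r], ang$k_[r]))
        if (!is.null(ap))
          keep[[length(keep) + 1]] <- data.frame(
            i = ang$i[r], j = ang$j[r], k_ = ang$k_[r],
            ktheta = ap$ktheta, theta0 = ap$theta0)
      }
      sys$angles <- if (length(keep)) do.call(rbind, keep) else sys$angles[0, ]
    }
  }
  if (length(params$torsions)) {
    tor <- derive_torsions(e)
    if (nrow(tor) > 0) {
      keep <- list()
      for (r in seq_len(nrow(tor))) {
        tp <- lookup(params$torsions,
                     c(tor$i[r], tor$j[r], tor$k_[r], tor$l[r]))
        if (!is.null(tp))
          keep[[length(keep) + 1]] <- data.frame(
            i = tor$i[r], j = tor$j[r], k_ = tor$k_[r], l = tor$l[r],
            kphi = tp$kphi, n = tp$n, delta = tp$delta)
      }
      sys$torsions <- if (length(keep)) do.call(rbind, keep) else
        sys$torsions[0, ]
    }
  }
  if (!is.null(params$covalent_bond) && !is.null(sys$covalent_link)) {
    sys$covalent_params <- params$covalent_bond
  }
  sys$net_charge <- as.integer(round(sum(sys$atoms$charge)))
  validate_system(sys)
}

## all i-j-k bonded paths (central atom j), canonical i < k
derive_angles <- function(e) {
  if (nrow(e) == 0)
    return(data.frame(i = integer(), j = integer(), k_ = integer()))
  n <- max(e)
  adj <- lapply(seq_len(n), function(i) c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
  out <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) > 1) {
      pr <- utils::combn(sort(nb), 2)
      for (c_ in seq_len(ncol(pr)))
        out[[length(out) + 1]] <- data.frame(i = pr[1, c_], j = j,
                                             k_ = pr[2, c_])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), k_ = integer())
}

## all i-j-k-l bonded paths around central bond j-k
derive_torsions <- function(e) {
  empty <- data.frame(i = integer(), j = integer(), k_ = integer(),
                      l = integer())
  if (nrow(e) == 0) return(empty)
  n <- max(e)
  adj <- lapply(seq_len(n), function(i) c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
  out <- list()
  for (r in seq_len(nrow(e))) {
    j <- e[r, 1]; k <- e[r, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i != l)
        out[[length(out) + 1]] <- data.frame(i = i, j = j, k_ = k, l = l)
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else empty
}

#' Read / write a parameter table (JSON)
#' @param path file path.
#' @return nested parameter list.
#' @export
read_parameter_table <- function(path)
  jsonlite::read_json(path, simplifyVector = FALSE)

#' @rdname read_parameter_table
#' @param params parameter table to write.
#' @export
write_parameter_table <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run-settings config file (nested key-value JSON)
#'
#' Keys are addressed with dotted paths, e.g. `ps.mode`, `embedding.scale`,
#' `solv.gamma`, `nb.cutoff`, `qm.method`.
#'
#' @param path JSON config path.
#' @return nested list.
#' @export
read_run_config <- function(path)
  jsonlite::read_json(path, simplifyVector = FALSE)

#' Look up a dotted key in a nested config with a default
#' @param cfg nested list from [read_run_config()].
#' @param key dotted path such as `"ps.mode"`.
#' @param default value returned when the key is absent.
#' @export
config_get <- function(cfg, key, default = NULL) {
  node <- cfg
  for (part in strsplit(key, ".", fixed = TRUE)[[1]]) {
    node <- node[[part]]
    if (is.null(node)) return(default)
  }
  node
}
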