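## Pluggable QM backends ------------------------------------------------------
##
## An engine is a list(name, compute, includes_ss_self_energy) whose
## `compute(sys, partition, spec)` returns a QMResult:
##   list(e_qm_ps, e_qm_elec_ps_ss, gradient (or NULL), qm_charges,
##        converged)
## Two engines ship with the package:
##   "mirror-mm": returns exactly the MM energy of the PS and the exact MM
##       PS<->SS Coulomb energy (FF charges). By construction the subtractive
##       scheme then collapses to the plain MM energy -- the oracle backbone
##       of the test suite.
##   "eem": a toy electronegativity-equalization model producing polarizable
##       QM-like charges by solving the charge-equilibration linear system
##       (electronegativity + hardness + Coulomb coupling, total-charge
##       constrained) in the field of the embedding charges.
## Method/basis/multiplicity are pass-through metadata for the built-in
## engines (documented as ignored); they matter for external adapters.

#' QM engine specification
#'
#' @param method engine registry key (`"mirror-mm"`, `"eem"`, or an external
#'   adapter name).
#' @param basis basis-set label (metadata; ignored by built-in engines).
#' @param multiplicity spin multiplicity (>= 1; metadata for built-ins --
#'   e.g. 2 for an unrestricted open-shell doublet on ferric heme).
#' @param ps_charge integer net charge of the primary system (e).
#' @param includes_ss_self_energy whether the engine's reported energy
#'   contains the electrostatic repulsion among the SS point charges
#'   (true for HF/DFT-like codes that treat external charges like nuclei);
#'   the scoring pipeline then subtracts [ss_self_repulsion()] a posteriori.
#' @param max_iters solver iteration cap (metadata for built-ins).
#' @param nb_cutoff nonbonded cutoff used by the mirror engine's MM terms.
#' @return an object of class `QMEngineSpec`.
#' @export
qm_engine_spec <- function(method = "mirror-mm", basis = "none",
                           multiplicity = 1L, ps_charge = 0L,
                           includes_ss_self_energy = FALSE,
                           max_iters = 200L, nb_cutoff = 12) {
  stopifnot(multiplicity >= 1)
  structure(list(method = method, basis = basis,
                 multiplicity = as.integer(multiplicity),
                 ps_charge = as.integer(ps_charge),
                 includes_ss_self_energy = includes_ss_self_energy,
                 max_iters = as.integer(max_iters),
                 nb_cutoff = nb_cutoff),
            class = "QMEngineSpec")
}

.qm_registry <- new.env(parent = emptyenv())

#' Register / retrieve QM engines
#'
#' @param name registry key (matched by the `qm.method` config string).
#' @param compute function `(sys, partition, spec) -> QMResult`.
#' @param includes_ss_self_energy engine property (see [qm_engine_spec()]).
#' @export
register_qm_engine <- function(name, compute,
                               includes_ss_self_energy = FALSE) {
  assign(name, list(name = name, compute = compute,
                    includes_ss_self_energy = includes_ss_self_energy),
         envir = .qm_registry)
  invisible(name)
}

#' @rdname register_qm_engine
#' @export
get_qm_engine <- function(name) {
  if (!exists(name, envir = .qm_registry))
    stop("unknown QM engine: ", name)
  get(name, envir = .qm_registry)
}

#' @rdname register_qm_engine
#' @export
list_qm_engines <- function() sort(ls(.qm_registry))

#' Run a QM calculation on the primary system
#'
#' Evaluates the engine named by `spec$method` on the PS geometry (atoms plus
#' hydrogen link atoms) in the field of the embedding point charges.
#'
#' @param sys the full `MolecularSystem` (the engine extracts the PS).
#' @param partition a complete `Partition` (link atoms + embedding built).
#' @param spec a `QMEngineSpec`.
#' @return A `QMResult`: list with `e_qm_ps`, `e_qm_elec_ps_ss` (kcal/mol),
#'   `gradient` (per-PS-atom 3-vectors or `NULL`), `qm_charges` (per-PS-atom
#'   e, link-atom charge folded into its QM host), `converged`.
#' @export
compute_qm <- function(sys, partition, spec) {
  eng <- get_qm_engine(spec$method)
  res <- eng$compute(sys, partition, spec)
  if (isTRUE(res$converged)) {
    if (!all(is.finite(c(res$e_qm_ps, res$e_qm_elec_ps_ss))))
      stop("QM engine returned non-finite energy while claiming convergence")
    if (!is.null(res$qm_charges) &&
        abs(sum(res$qm_charges) - spec$ps_charge) > 0.01)
      stop("QM engine charge sum deviates from ps_charge by > 0.01 e")
  }
  res$engine <- eng$name
  class(res) <- "QMResult"
  res
}

## Coulomb energy between PS atoms (FF charges) and the embedding set;
## shared by the mirror engine and the pipeline's E_MM^elec(PS<->SS)
ps_ss_coulomb <- function(sys, partition, charges = NULL) {
  emb <- partition$embedding
  ps <- partition$ps_atoms
  if (is.null(emb) || nrow(emb) == 0 || length(ps) == 0) return(0)
  if (is.null(charges)) charges <- sys$atoms$charge[ps]
  X <- coords(sys)[ps, , drop = FALSE]
  E <- as.matrix(emb[, c("x", "y", "z")])
  tot <- 0
  for (k in seq_len(nrow(E))) {
    if (emb$charge[k] == 0) next
    d <- sqrt(rowSums((X - matrix(E[k, ], nrow(X), 3, byrow = TRUE))^2))
    tot <- tot + COULOMB_KCAL * emb$charge[k] * sum(charges / d)
  }
  tot
}

mirror_mm_compute <- function(sys, partition, spec) {
  cutoff <- spec$nb_cutoff %||% 12
  e_ps <- mm_energy_selection(sys, partition$ps_atoms, cutoff = cutoff)
  e_el <- ps_ss_coulomb(sys, partition)
  list(e_qm_ps = e_ps, e_qm_elec_ps_ss = e_el, gradient = NULL,
       qm_charges = sys$atoms$charge[partition$ps_atoms], converged = TRUE)
}

## EEM parameter table: electronegativity chi and hardness eta (eV).
## These values are engine configuration, not physics claims.
EEM_TABLE <- data.frame(
  element = c("H", "C", "N", "O", "S", "Fe", "Zn"),
  chi = c(7.17, 6.26, 7.27, 7.54, 6.22, 4.06, 4.45),
  eta = c(6.42, 5.00, 7.23, 6.08, 4.14, 3.81, 4.94))

eem_compute <- function(sys, partition, spec) {
  ps <- partition$ps_atoms
  la <- partition$link_atoms
  elems <- c(sys$atoms$element[ps],
             rep("H", if (is.null(la)) 0 else nrow(la)))
  idx <- match(elems, EEM_TABLE$element)
  if (anyNA(idx))
    stop("parameter error: no EEM parameters for element ",
         paste(unique(elems[is.na(idx)]), collapse = ", "))
  chi <- EEM_TABLE$chi[idx] * EV_TO_KCAL
  eta <- EEM_TABLE$eta[idx] * EV_TO_KCAL
  X <- rbind(coords(sys)[ps, , drop = FALSE],
             if (!is.null(la) && nrow(la) > 0)
               as.matrix(la[, c("x", "y", "z")]))
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (n > 1 && min(D[upper.tri(D)]) < 1e-9)
    return(list(e_qm_ps = NA_real_, e_qm_elec_ps_ss = NA_real_,
                gradient = NULL, qm_charges = NULL, converged = FALSE))
  ## external potential from the embedding charges
  V <- numeric(n)
  emb <- partition$embedding
  if (!is.null(emb) && nrow(emb) > 0) {
    E <- as.matrix(emb[, c("x", "y", "z")])
    for (k in which(emb$charge != 0)) {
      d <- sqrt(rowSums((X - matrix(E[k, ], n, 3, byrow = TRUE))^2))
      V <- V + COULOMB_KCAL * emb$charge[k] / d
    }
  }
  A <- COULOMB_KCAL / D; diag(A) <- 2 * eta
  M <- rbind(cbind(A, 1), c(rep(1, n), 0))
  rhs <- c(-(chi + V), spec$ps_charge)
  q <- tryCatch(unname(solve(M, rhs))[seq_len(n)], error = function(e) NULL)
  if (is.null(q))
    return(list(e_qm_ps = NA_real_, e_qm_elec_ps_ss = NA_real_,
                gradient = NULL, qm_charges = NULL, converged = FALSE))
  coul <- if (n > 1) {
    iu <- which(upper.tri(D), arr.ind = TRUE)
    sum(COULOMB_KCAL * q[iu[, 1]] * q[iu[, 2]] / D[iu])
  } else 0
  e_eem <- sum(chi * q + eta * q^2) + coul
  ## classical short-range terms of the PS (LJ + bonded) keep the toy QM
  ## surface comparable to the MM one; EEM replaces the PS electrostatics
  b <- bonded_energy(sys, ps)
  nb <- nonbonded_energy(sys, ps, cutoff = spec$nb_cutoff %||% 12)
  e_ps <- e_eem + sum(b) + unname(nb["lj"])
  e_el <- sum(q * V)
  ## fold link-atom charges into their QM hosts
  qc <- q[seq_along(ps)]
  if (!is.null(la) && nrow(la) > 0) {
    for (r in seq_len(nrow(la))) {
      h <- match(la$qm_host[r], ps)
      qc[h] <- qc[h] + q[length(ps) + r]
    }
  }
  list(e_qm_ps = e_ps, e_qm_elec_ps_ss = e_el, gradient = NULL,
       qm_charges = qc, converged = TRUE)
}

## built-in engines registered at load time
.onLoad <- function(libname, pkgname) {
  register_qm_engine("mirror-mm", mirror_mm_compute,
                     includes_ss_self_energy = FALSE)
  register_qm_engine("eem", eem_compute, includes_ss_self_energy = FALSE)
}

#' Numerical gradient of the QM energy
#'
#' Central finite differences of `e_qm_ps + e_qm_elec_ps_ss` with respect to
#' the PS atom coordinates; link-atom positions are rebuilt at every
#' displaced geometry. Enables optimization with gradient-free engines.
#'
#' @param sys,partition,spec as in [compute_qm()].
#' @param h finite-difference step (A, default 1e-4).
#' @return matrix `length(ps_atoms) x 3` (kcal/mol/A).
#' @export
numerical_gradient <- function(sys, partition, spec, h = 1e-4) {
  stopifnot(h > 0)
  ps <- partition$ps_atoms
  G <- matrix(0, length(ps), 3)
  e_of <- function(s) {
    p <- refresh_partition(partition, s)
    r <- compute_qm(s, p, spec)
    if (!isTRUE(r$converged))
      stop("numerical_gradient: engine failed to converge at displaced point")
    r$e_qm_ps + r$e_qm_elec_ps_ss
  }
  cols <- c("x", "y", "z")
  for (ii in seq_along(ps)) {
    for (d in 1:3) {
      sp <- sys; sp$atoms[[cols[d]]][ps[ii]] <-
          sp$atoms[[cols[d]]][ps[ii]] + h
      sm <- sys; sm$atoms[[cols[d]]][ps[ii]] <-
          sm$atoms[[cols[d]]][ps[ii]] - h
      G[ii, d] <- (e_of(sp) - e_of(sm)) / (2 * h)
    }
  }
  G
}

## External-adapter exchange format ------------------------------------------
## A real QM program is plugged in by registering an engine built with
## make_external_engine(): the PS + embedding are written to a tagged text
## exchange file, the command is invoked, and a tagged result file is read
## back. No external program ships with the package.

#' Write the PS/embedding exchange file for an external QM adapter
#' @param sys,partition,spec as in [compute_qm()].
#' @param path output path.
#' @export
write_qm_exchange <- function(sys, partition, spec, path) {
  ps <- partition$ps_atoms
  X <- coords(sys)
  out <- c(sprintf("METHOD %s", spec$method),
           sprintf("BASIS %s", spec$basis),
           sprintf("CHARGE %d", spec$ps_charge),
           sprintf("MULTIPLICITY %d", spec$multiplicity),
           "PSATOMS")
  out <- c(out, sprintf("%-2s %14.8f %14.8f %14.8f",
                        sys$atoms$element[ps], X[ps, 1], X[ps, 2], X[ps, 3]))
  la <- partition$link_atoms
  if (!is.null(la) && nrow(la) > 0) {
    out <- c(out, "LINKATOMS",
             sprintf("H  %14.8f %14.8f %14.8f", la$x, la$y, la$z))
  }
  emb <- partition$embedding
  if (!is.null(emb) && nrow(emb) > 0) {
    out <- c(out, "EMBEDDING",
             sprintf("%14.8f %14.8f %14.8f %14.8f",
                     emb$x, emb$y, emb$z, emb$charge))
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a tagged result file written by an external QM adapter
#'
#' Expected tags: `E_QM_PS <kcal/mol>`, `E_QM_ELEC_PS_SS <kcal/mol>`,
#' `CONVERGED 0|1`, optional `CHARGES` block (one charge per PS atom + link
#' atom) and `GRADIENT` block (3 numbers per line).
#'
#' @param path result file path.
#' @return a `QMResult`-shaped list.
#' @export
read_qm_result <- function(path) {
  lines <- readLines(path, warn = FALSE)
  val <- function(tag) {
    l <- lines[startsWith(lines, tag)]
    if (length(l) == 0) return(NULL)
    as.numeric(strsplit(trimws(l[1]), "\\s+")[[1]][2])
  }
  block <- function(tag) {
    s <- which(trimws(lines) == tag)
    if (length(s) == 0) return(NULL)
    e <- s[1] + 1
    out <- list()
    while (e <= length(lines) &&
           !grepl("^[A-Z_]+$", trimws(lines[e])) &&
           nzchar(trimws(lines[e]))) {
      out[[length(out) + 1]] <- as.numeric(
        strsplit(trimws(lines[e]), "\\s+")[[1]])
      e <- e + 1
    }
    out
  }
  ch <- block("CHARGES"); gr <- block("GRADIENT")
  list(e_qm_ps = val("E_QM_PS"),
       e_qm_elec_ps_ss = val("E_QM_ELEC_PS_SS") %||% 0,
       gradient = if (!is.null(gr)) do.call(rbind, gr),
       qm_charges = if (!is.null(ch)) unlist(ch),
       converged = isTRUE(val("CONVERGED") == 1))
}

#' Build an engine backed by an external command
#'
#' The engine writes the exchange file, runs `command input output` and
#' parses the result file. Provided as the adapter contract; no external
#' program is bundled.
#'
#' @param command path to the adapter executable.
#' @param includes_ss_self_energy engine property flag.
#' @param workdir directory for exchange files (default tempdir).
#' @return an engine list suitable for [register_qm_engine()].
#' @export
make_external_engine <- function(command, includes_ss_self_energy = FALSE,
                                 workdir = tempdir()) {
  compute <- function(sys, partition, spec) {
    fin <- file.path(workdir, "qm_input.txt")
    fout <- file.path(workdir, "qm_result.txt")
    write_qm_exchange(sys, partition, spec, fin)
    status <- system2(command, c(fin, fout))
    if (status != 0)
      return(list(e_qm_ps = NA_real_, e_qm_elec_ps_ss = NA_real_,
                  gradient = NULL, qm_charges = NULL, converged = FALSE))
    read_qm_result(fout)
  }
  list(name = basename(command), compute = compute,
       includes_ss_self_energy = includes_ss_self_energy)
}
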