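## shared fixture cache: toy complexes are deterministic per options, so
## tests reuse one instance instead of regenerating
.fix_cache <- new.env(parent = emptyenv())

cached_fix <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!exists(key, envir = .fix_cache))
    assign(key, make_toy_complex(seed, ...), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

## mirror-engine partition/spec pair used across tests
mirror_setup <- function(sys, mode = "lig", scale = 1, ...) {
  part <- make_partition(sys, mode, scale = scale, ...)
  spec <- qm_engine_spec("mirror-mm", ps_charge = part$ps_net_charge)
  list(part = part, spec = spec)
}

## random rigid motion (rotation + translation) applied to a system
rigid_motion <- function(sys, seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
  t <- rnorm(3, sd = 5)
  X <- as.matrix(sys$atoms[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, t, "+")
  sys$atoms$x <- X[, 1]; sys$atoms$y <- X[, 2]; sys$atoms$z <- X[, 3]
  sys
}

cross_prod <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## two-point-charge system helper for energetics unit tests
two_charge_system <- function(q1, q2, r, eps = 0, rmin_half = 0) {
  molecular_system(data.frame(
    element = c("C", "C"), x = c(0, r), y = 0, z = 0,
    charge = c(q1, q2), lj_epsilon = eps, lj_rmin_half = rmin_half,
    is_ligand = TRUE),
    net_charge = round(q1 + q2), validate = FALSE)
}

coord_rmsd_mat <- function(A, B) sqrt(mean(rowSums((A - B)^2)))
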