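# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# PDB atom names of hydrogens: H, HA, 1HB, HD21, ... Heavy atoms never start
# with H or a digit followed by H.
is_hydrogen <- function(elety) {
  grepl("^[0-9]*H", trimws(elety))
}

#' Atom names forming the polypeptide backbone
#'
#' The backbone convention used throughout for "backbone" atom selections is
#' the N, CA, C triplet (the MOLMOL/CYANA convention for NMR ensemble
#' statistics); "heavy" means every non-hydrogen atom.
#'
#' @param atom_set `"backbone"` or `"heavy"`.
#' @param elety Character vector of PDB atom names to filter.
#' @return Logical vector: which atom names belong to the set.
#' @keywords internal
atom_set_mask <- function(atom_set, elety) {
  atom_set <- match.arg(atom_set, c("backbone", "heavy"))
  elety <- trimws(elety)
  if (atom_set == "backbone") {
    elety %in% c("N", "CA", "C")
  } else {
    !is_hydrogen(elety)
  }
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Numerically safe arccos in degrees.
acos_deg <- function(x) deg(acos(pmin(1, pmax(-1, x))))

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) abort("Cannot normalise a zero-length vector.")
  v / n
}

# Rotation matrix about unit axis u by `theta` degrees (Rodrigues form).
rotation_about <- function(u, theta) {
  u <- unit(u)
  th <- rad(theta)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
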