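#' Ideal alpha-helix generator
#'
#' Builds a single-conformer CA (optionally CA+N+C) trace of an ideal
#' alpha-helix: CA atoms on a cylinder of given radius about the axis,
#' advancing by `rise` Angstrom and `twist` degrees per residue (textbook
#' values 1.5 A, 100 deg, 2.3 A are the defaults). Kinks are applied by
#' rotating everything downstream of the kink residue about an axis
#' perpendicular to the local helix axis, so the inter-axis angle across the
#' kink equals the requested angle exactly — the construction is its own
#' ground truth.
#'
#' @param n Number of residues (>= 5).
#' @param rise,twist,radius Helical parameters: rise per residue (A), twist
#'   per residue (deg, in (0, 360)), CA cylinder radius (A).
#' @param kinks Optional tibble/data frame with columns `position` (residue
#'   index counted within the helix, 1-based) and `angle` (deg).
#' @param axis Length-3 direction for the helix axis (default +z).
#' @param start First residue number (absolute numbering).
#' @param origin Length-3 translation applied to the finished helix.
#' @param backbone Also emit N and C atoms (ideal internal coordinates;
#'   useful only for atom-selection plumbing, the CA trace carries the
#'   geometric ground truth).
#' @param chain Chain identifier.
#' @return A one-conformer ensemble tibble (see [as_ensemble()]).
#' @examples
#' helix <- make_helix(18)
#' range(dplyr::filter(helix, elety == "CA")$z)
#' @export
make_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                       kinks = NULL, axis = c(0, 0, 1), start = 1L,
                       origin = c(0, 0, 0), backbone = FALSE, chain = "A") {
  if (n < 5) abort("An ideal helix fixture needs >= 5 residues.")
  if (twist <= 0 || twist >= 360) abort("`twist` must lie in (0, 360) degrees.")
  if (radius <= 0 || rise <= 0) abort("`radius` and `rise` must be positive.")
  k <- seq_len(n) - 1L
  ang <- rad(twist) * k
  pts <- list(
    CA = cbind(radius * cos(ang), radius * sin(ang), rise * k)
  )
  if (backbone) {
    # ideal internal-coordinate placement on companion cylinders
    pts$N <- cbind(1.55 * cos(ang - rad(27)), 1.55 * sin(ang - rad(27)), rise * k - 0.9)
    pts$C <- cbind(1.52 * cos(ang + rad(26)), 1.52 * sin(ang + rad(26)), rise * k + 1.1)
  }
  axis_pts <- cbind(0, 0, rise * k)          # centreline, transforms with the atoms
  dir <- c(0, 0, 1)
  if (!is.null(kinks) && nrow(kinks) > 0) {
    kinks <- arrange(as_tibble(kinks), .data$position)
    for (r in seq_len(nrow(kinks))) {
      p <- kinks$position[r]
      if (p < 2 || p > n - 1) abort("Kink position must be interior to the helix.")
      pivot <- axis_pts[p, ]
      perp <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- unit(pracma_cross(dir, perp))
      R <- rotation_about(u, kinks$angle[r])
      rot_down <- function(M) {
        down <- seq(p, n)
        M[down, ] <- sweep(sweep(M[down, , drop = FALSE], 2, pivot) %*% t(R), 2, pivot, `+`)
        M
      }
      pts <- purrr::map(pts, rot_down)
      axis_pts <- rot_down(axis_pts)
      dir <- as.numeric(R %*% dir)
    }
  }
  # orient the requested global axis and translate to origin
  Rg <- rotation_between(c(0, 0, 1), unit(axis))
  place <- function(M) sweep(M %*% t(Rg), 2, origin, `+`)
  pts <- purrr::map(pts, place)
  atoms <- purrr::imap_dfr(pts, function(M, nm) {
    tibble(model = 1L, chain = chain, resno = start + k, resid = "ALA",
           elety = nm, x = M[, 1], y = M[, 2], z = M[, 3])
  })
  as_ensemble(atoms, quiet = TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Minimal rotation taking unit vector `a` onto unit vector `b`.
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- pracma_cross(a, b)
  c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about(unit(pracma_cross(a, perp)), 180))
  }
  rotation_about(v, deg(atan2(sqrt(sum(v^2)), c_)))
}

#' Two-helix hairpin at an exact inter-axis angle
#'
#' Builds two ideal helices whose construction axes subtend exactly the
#' requested angle, with a 3-residue unmodeled numbering gap between them
#' (the gap is left unbuilt so that the axis ground truth stays exact).
#' The second helix is laterally displaced to avoid steric overlap; if the
#' placement still clashes it is retried with seeded jitter.
#'
#' @param angle Inter-axis angle in degrees, within \[0, 180\].
#' @param n1,n2 Residue counts of the two helices.
#' @param start First residue number of helix 1.
#' @param gap_res Unmodeled numbering gap between the helices (residues).
#' @param spacing Axial clearance between helix 1 end and helix 2 start (A).
#' @param seed Seed for the clash-avoidance jitter.
#' @param ... Further helical parameters passed to [make_helix()].
#' @return A one-conformer ensemble holding both helices; attributes
#'   `"segments"` (tibble of the two residue ranges) and `"angle"` (the
#'   constructed ground-truth angle).
#' @export
make_hairpin <- function(angle, n1 = 18L, n2 = 18L, start = 1L, gap_res = 3L,
                         spacing = 6, seed = 1L, ...) {
  if (angle < 0 || angle > 180) abort("`angle` must lie in [0, 180] degrees.")
  h1 <- make_helix(n1, start = start, ...)
  dir2 <- c(sin(rad(angle)), 0, cos(rad(angle)))
  top <- c(0, 0, 1.5 * (n1 - 1))
  start2 <- start + n1 + gap_res
  build2 <- function(lateral) {
    make_helix(n2, start = start2, axis = dir2,
               origin = top + spacing * dir2 + c(0, lateral, 0), ...)
  }
  lateral <- 7
  for (attempt in 1:20) {
    h2 <- build2(lateral)
    d <- min_interatomic(h1, h2)
    if (d > 2) break
    lateral <- 7 + with_seed(seed + attempt, stats::runif(1, 2, 12))
  }
  if (min_interatomic(h1, h2) <= 2) abort("Could not place the second helix without clashes.")
  ens <- as_ensemble(bind_rows(h1, h2), quiet = TRUE)
  attr(ens, "segments") <- bind_rows(
    helix_segment(start, start + n1 - 1L),
    helix_segment(start2, start2 + n2 - 1L)
  )
  attr(ens, "angle") <- angle
  ens
}

min_interatomic <- function(a, b) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  sqrt(max(0, min(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))))
}

#' Gaussian-noise conformer ensemble around a base structure
#'
#' Replicates the base conformer `n_models` times, adding i.i.d. Gaussian
#' noise of standard deviation `sigma` to every coordinate, and optionally a
#' random rigid-body transform per conformer (which changes nothing any
#' internal-geometry analysis can see — the standard negative control).
#' Reproducible: the output is a pure function of (base, arguments, seed).
#'
#' @param base Ensemble tibble (its first conformer is used as template).
#' @param n_models Number of conformers to emit (>= 2).
#' @param sigma Coordinate noise SD in Angstrom (>= 0).
#' @param seed RNG seed.
#' @param rigid_jitter Apply a random rotation and translation (SD 5 A) per
#'   conformer.
#' @return Ensemble tibble with `n_models` conformers.
#' @export
perturb_ensemble <- function(base, n_models, sigma, seed = 1L, rigid_jitter = FALSE) {
  if (n_models < 2) abort("`n_models` must be >= 2.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  tmpl <- filter(as_tibble(base), .data$model == min(.data$model))
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_models), function(m) {
      M <- as.matrix(tmpl[, c("x", "y", "z")])
      M <- M + matrix(rnorm(length(M), sd = sigma), ncol = 3)
      if (rigid_jitter) {
        M <- sweep(M %*% t(random_rotation()), 2, rnorm(3, sd = 5), `+`)
      }
      mutate(tmpl, model = m, x = M[, 1], y = M[, 2], z = M[, 3])
    })
  }) %>% as_ensemble(quiet = TRUE)
}

#' Shift/peak/assignment fixtures with planted effects
#'
#' Builds the table fixtures every NMR-track analysis consumes, with ground
#' truth planted exactly: a pair of shift tables whose CSPs equal `csp`
#' (realised entirely in the 1H dimension, dN = 0), a peak table whose
#' normalised lipid/water contacts equal `lipid`/`water`, and a proton
#' assignment table in which the residues listed in `overlap_at` carry a
#' methyl proton at 1.30 ppm (inside the lipid CH2 window).
#'
#' @param planted Tibble with column `resno` and any of `csp`, `lipid`,
#'   `water` (missing columns default to 0).
#' @param overlap_at Integer residues given an overlapping methyl proton.
#' @param i_diag Diagonal intensity used for the peak table.
#' @param seed RNG seed (reserved; the planted tables are deterministic).
#' @return List with `shift_a`, `shift_b`, `peaks`, `assignments`.
#' @export
make_tables <- function(planted, overlap_at = integer(0), i_diag = 100, seed = 1L) {
  planted <- as_tibble(planted)
  for (col in c("csp", "lipid", "water")) {
    if (!col %in% names(planted)) planted[[col]] <- 0
  }
  if (!all(is.finite(planted$csp) & is.finite(planted$lipid) & is.finite(planted$water))) {
    abort("Planted effects must be finite.")
  }
  shift_a <- tibble(resno = planted$resno, H_ppm = 8.2, N_ppm = 118)
  shift_b <- mutate(shift_a, H_ppm = .data$H_ppm + planted$csp)
  peaks <- tibble(
    resno = planted$resno,
    I_lipid = i_diag * planted$lipid,
    I_water = i_diag * planted$water,
    I_diag = i_diag,
    excluded = FALSE
  )
  assignments <- bind_rows(
    tibble(resno = rep(planted$resno, each = 2),
           shift_ppm = rep(c(0.90, 4.20), times = nrow(planted))),
    tibble(resno = as.integer(overlap_at), shift_ppm = 1.30)
  ) %>% arrange(.data$resno, .data$shift_ppm)
  list(shift_a = shift_a, shift_b = shift_b, peaks = peaks,
       assignments = assignments)
}

#' Designed TM/JM block sequences
#'
#' Sequence fixtures with the hydropathy architecture of single-pass
#' receptor TM/JM regions: a polar N-terminal lead, a hydrophobic
#' transmembrane run, and either a hydrophilic linker followed by a second
#' hydrophobic juxtamembrane patch (`"separated"`, the common TM/JM
#' architecture) or one contiguous hydrophobic span with a short tail
#' (`"contiguous"`).
#'
#' @param kind `"separated"` or `"contiguous"`.
#' @param start Absolute number of the first residue.
#' @return A one-row sequence record (see [annotated_sequence()]).
#' @export
make_tm_jm_sequence <- function(kind = c("separated", "contiguous"), start = 1L) {
  kind <- match.arg(kind)
  lead <- "SNQTEDRK"
  tm <- "LVIALFIVLLIVAGLFIVLL"
  sequence <- switch(kind,
    separated = paste0(lead, tm, "KRNQSE", "FLIVALFIVLWI", "QNKRDS"),
    contiguous = paste0(lead, tm, "FLIVALFIVL", "QNKRDS")
  )
  annotated_sequence(sequence, start = start, name = paste0("tmjm_", kind))
}
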