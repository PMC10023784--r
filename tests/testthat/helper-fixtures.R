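# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

fixture_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

fixture_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, f)
  f
}

# A small asymmetric 4-point cloud used for Kabsch oracle checks.
asym_points <- function() {
  matrix(c(
    0, 0, 0,
    3, 0, 0,
    0, 2, 0,
    1, 1, 2.5
  ), ncol = 3, byrow = TRUE)
}

# Brute-force rigid superposition: grid search over ZYZ Euler angles
# (translations resolved by centroid matching), refining the best coarse
# candidates so no basin is missed. Independent of kabsch().
grid_superpose_rmsd <- function(mobile, reference, n_coarse = 24,
                                refine = 3, top_k = 12) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  eval_rmsd <- function(a, b, c) {
    R <- rot(a, b, c)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = n_coarse + 1)[-(n_coarse + 1)]
  bgrid <- seq(0, pi, length.out = n_coarse %/% 2 + 1)
  coarse <- expand.grid(a = grid, b = bgrid, c = grid)
  coarse$r <- mapply(eval_rmsd, coarse$a, coarse$b, coarse$c)
  coarse <- coarse[order(coarse$r), ][seq_len(top_k), ]
  best_r <- coarse$r[1]
  for (k in seq_len(nrow(coarse))) {
    cand <- c(coarse$r[k], coarse$a[k], coarse$b[k], coarse$c[k])
    step <- 2 * pi / n_coarse
    for (lev in seq_len(refine)) {
      step <- step / 6
      loc <- expand.grid(a = cand[2] + step * (-7:7),
                         b = cand[3] + step * (-7:7),
                         c = cand[4] + step * (-7:7))
      for (i in seq_len(nrow(loc))) {
        r <- eval_rmsd(loc$a[i], loc$b[i], loc$c[i])
        if (r < cand[1]) cand <- c(r, loc$a[i], loc$b[i], loc$c[i])
      }
    }
    best_r <- min(best_r, cand[1])
  }
  best_r
}

# Apply one rigid transform to every conformer of an ensemble (same or
# per-model transforms), without touching internal geometry.
rigid_move <- function(ens, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(sort(unique(ens$model)), function(m) {
      a <- dplyr::filter(ens, model == m)
      qr_ <- qr(matrix(rnorm(9), 3, 3))
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      M <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% R, 2, rnorm(3, sd = 8), `+`)
      dplyr::mutate(a, x = M[, 1], y = M[, 2], z = M[, 3])
    })
  }) |> memjm::as_ensemble(quiet = TRUE)
}

expect_angle_equal <- function(measured, truth, tol) {
  expect_lt(abs(measured - truth), tol)
}

# angle in degrees between two (not necessarily unit) vectors
acos_dev <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
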