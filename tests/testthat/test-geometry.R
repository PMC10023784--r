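test_that("kabsch returns the identity for self-superposition and zero for rigid copies", {
  P <- asym_points()
  fit <- kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  withr::with_seed(11, {
    for (i in 1:5) {
      R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      moved <- sweep(P %*% R, 2, rnorm(3, sd = 10), `+`)
      expect_lt(kabsch(moved, P)$rmsd, 1e-6)
      expect_equal(det(kabsch(moved, P)$rotation), 1, tolerance = 1e-9)
    }
  })
})

test_that("kabsch matches a grid-search oracle on small point sets", {
  withr::with_seed(21, {
    for (i in 1:3) {
      n <- sample(4:6, 1)
      A <- matrix(rnorm(3 * n, sd = 2), ncol = 3)
      B <- A + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
      expect_equal(kabsch(A, B)$rmsd, grid_superpose_rmsd(A, B), tolerance = 1e-3)
    }
  })
  # the spec case: perturbed copy of a 4-point asymmetric set
  P <- asym_points()
  Q <- P + matrix(c(0.1, -0.2, 0.05, 0, 0.15, -0.1, 0.2, 0, -0.05, 0.1, 0.1, 0), ncol = 3)
  expect_equal(kabsch(P, Q)$rmsd, grid_superpose_rmsd(P, Q), tolerance = 1e-3)
})

test_that("kabsch rejects mismatched and collinear inputs", {
  P <- asym_points()
  expect_error(kabsch(P[1:3, ], P), "equal-size")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 0.1), "collinear")
})

test_that("pairwise RMSD is zero for identical conformers and reproduces symmetric noise", {
  ens <- perturb_ensemble(make_helix(12), n_models = 4, sigma = 0, seed = 1)
  r <- pairwise_rmsd(ens, helix_segment(1, 12))
  expect_equal(nrow(r$pairs), 6L)
  expect_equal(r$mean, 0, tolerance = 1e-9)
  expect_equal(r$sd, 0, tolerance = 1e-9)

  # three conformers displaced by three 120-degree-symmetric displacement
  # patterns orthogonal to all rigid-body modes (so superposition leaves
  # them intact to second order): all pair RMSDs equal s*sqrt(3)/sqrt(n)
  base <- dplyr::filter(make_helix(12), elety == "CA")
  X <- scale(as.matrix(base[, c("x", "y", "z")]), scale = FALSE)
  rigid_modes <- cbind(
    as.vector(matrix(rep(c(1, 0, 0), each = 12), ncol = 3)),
    as.vector(matrix(rep(c(0, 1, 0), each = 12), ncol = 3)),
    as.vector(matrix(rep(c(0, 0, 1), each = 12), ncol = 3)),
    as.vector(cbind(0, -X[, 3], X[, 2])),
    as.vector(cbind(X[, 3], 0, -X[, 1])),
    as.vector(cbind(-X[, 2], X[, 1], 0))
  )
  project_out <- function(v, basis) {
    for (k in seq_len(ncol(basis))) {
      b <- basis[, k]
      v <- v - b * sum(b * v) / sum(b * b)
    }
    v
  }
  withr::with_seed(5, {
    U <- project_out(rnorm(36), rigid_modes)
    V <- project_out(rnorm(36), cbind(rigid_modes, U))
    s <- 0.05
    U <- matrix(s * U / sqrt(sum(U^2)), ncol = 3)
    V <- matrix(s * V / sqrt(sum(V^2)), ncol = 3)
  })
  conf <- purrr::map_dfr(0:2, function(k) {
    D <- cos(2 * pi * k / 3) * U + sin(2 * pi * k / 3) * V
    M <- as.matrix(base[, c("x", "y", "z")]) + D
    dplyr::mutate(base, model = k + 1L, x = M[, 1], y = M[, 2], z = M[, 3])
  })
  r3 <- pairwise_rmsd(as_ensemble(conf), helix_segment(1, 12))
  expected <- s * sqrt(3) / sqrt(12)
  expect_equal(r3$mean, expected, tolerance = 0.02 * expected)
  expect_lt(r3$sd, 0.02 * r3$mean)
})

test_that("pairwise RMSD needs two conformers and all segment atoms", {
  one <- make_helix(12)
  expect_error(pairwise_rmsd(one, helix_segment(1, 12)), "at least 2")
  ens <- perturb_ensemble(make_helix(12), n_models = 3, sigma = 0.1, seed = 2)
  expect_error(pairwise_rmsd(ens, helix_segment(1, 30)), "13")
})

test_that("pairwise RMSD is invariant to conformer order and rigid-body motion", {
  ens <- perturb_ensemble(make_hairpin(70), n_models = 5, sigma = 0.2, seed = 4)
  segs <- attr(make_hairpin(70), "segments")
  r <- pairwise_rmsd(ens, segs)
  reordered <- as_ensemble(dplyr::mutate(tibble::as_tibble(ens), model = 6L - model))
  expect_equal(pairwise_rmsd(reordered, segs)$mean, r$mean, tolerance = 1e-9)
  moved <- rigid_move(ens, seed = 8)
  expect_equal(pairwise_rmsd(moved, segs)$mean, r$mean, tolerance = 1e-6)
})

test_that("the axis fit recovers construction axes including the N->C sign", {
  f <- fit_axis(make_helix(18), helix_segment(1, 18))
  expect_lt(acos_dev(c(f$ax, f$ay, f$az), c(0, 0, 1)), 0.5)

  # reversing the residue order flips the axis
  rev_ens <- make_helix(18)
  rev_ens <- as_ensemble(dplyr::mutate(tibble::as_tibble(rev_ens), resno = 19L - resno),
                         quiet = TRUE)
  fr <- fit_axis(rev_ens, helix_segment(1, 18))
  expect_lt(acos_dev(c(fr$ax, fr$ay, fr$az), c(0, 0, -1)), 0.5)

  # Monte-Carlo: noisy helices stay within 2 degrees on average
  devs <- purrr::map_dbl(1:20, function(s) {
    e <- perturb_ensemble(make_helix(18), n_models = 2, sigma = 0.3, seed = s)
    f <- fit_axis(e, helix_segment(1, 18))
    mean(purrr::map_dbl(seq_len(nrow(f)),
                        ~acos_dev(c(f$ax[.x], f$ay[.x], f$az[.x]), c(0, 0, 1))))
  })
  expect_lt(mean(devs), 2)
})

test_that("axis fitting rejects degenerate input", {
  line <- tibble::tibble(model = 1L, chain = "A", resno = 1:6, resid = "ALA",
                         elety = "CA", x = as.numeric(1:6), y = 0, z = 0)
  expect_error(fit_axis(as_ensemble(line), helix_segment(1, 6)), "rank")
  expect_error(fit_axis(make_helix(18), helix_segment(1, 4)), "5 residues")
})

test_that("interhelical angles recover construction values and are symmetric", {
  # parallel translated copies
  h1 <- make_helix(18)
  h2 <- make_helix(18, start = 30L, origin = c(15, 0, 0))
  both <- as_ensemble(dplyr::bind_rows(h1, h2), quiet = TRUE)
  a0 <- interhelix_angle(both, helix_segment(1, 18), helix_segment(30, 47))
  expect_equal(a0$mean, 0, tolerance = 1e-6)
  expect_equal(a0$sd, 0)

  for (th in c(10, 45, 90, 135, 170)) {
    hp <- make_hairpin(th)
    segs <- attr(hp, "segments")
    a <- interhelix_angle(hp, segs[1, ], segs[2, ])
    expect_angle_equal(a$mean, th, 2)
    b <- interhelix_angle(hp, segs[2, ], segs[1, ])
    expect_equal(a$mean, b$mean, tolerance = 1e-9)
  }

  # rigid motion of whole conformers cannot change an internal angle
  hp <- perturb_ensemble(make_hairpin(65), n_models = 4, sigma = 0.2, seed = 6)
  segs <- attr(make_hairpin(65), "segments")
  a <- interhelix_angle(hp, segs[1, ], segs[2, ])
  moved <- rigid_move(hp, seed = 13)
  expect_equal(interhelix_angle(moved, segs[1, ], segs[2, ])$mean, a$mean,
               tolerance = 1e-6)
})

test_that("the mean-axis convention is available alongside per-conformer averaging", {
  hp <- perturb_ensemble(make_hairpin(65), n_models = 6, sigma = 0.2, seed = 10)
  segs <- attr(make_hairpin(65), "segments")
  per <- interhelix_angle(hp, segs[1, ], segs[2, ])
  mean_ax <- interhelix_angle(hp, segs[1, ], segs[2, ], method = "mean_axis")
  expect_angle_equal(per$mean, 65, 2)
  expect_angle_equal(mean_ax$mean, 65, 2)
})

test_that("bend profiles are flat for straight helices and localise planted kinks", {
  straight <- bend_profile(make_helix(40), helix_segment(1, 40))
  expect_lt(max(straight$mean_deg), 3)

  for (k in c(15, 20, 25)) {
    kinked <- make_helix(40, kinks = data.frame(position = k, angle = 30))
    prof <- bend_profile(kinked, helix_segment(1, 40))
    peak <- prof$resno[which.max(prof$mean_deg)]
    expect_lte(abs(peak - k), 1)
    expect_lt(abs(max(prof$mean_deg) - 30), 5)
  }
  expect_error(bend_profile(make_helix(10), helix_segment(1, 10)), "too short")
})
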