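test_that("ideal helices have the constructed rise, twist and span", {
  h <- make_helix(18)
  ca <- dplyr::filter(tibble::as_tibble(h), elety == "CA")
  expect_equal(diff(range(ca$z)), 17 * 1.5, tolerance = 1e-9)
  # consecutive residues subtend the twist angle about the axis
  ang <- atan2(ca$y, ca$x)
  subtended <- (diff(ang) * 180 / pi) %% 360
  expect_equal(subtended, rep(100, 17), tolerance = 1e-9)
  # constant CA radius
  expect_equal(sqrt(ca$x^2 + ca$y^2), rep(2.3, 18), tolerance = 1e-9)
})

test_that("helix construction validates its parameters", {
  expect_error(make_helix(4), ">= 5")
  expect_error(make_helix(10, twist = 0), "twist")
  expect_error(make_helix(10, radius = -1), "positive")
  expect_error(make_helix(10, kinks = data.frame(position = 1, angle = 30)), "interior")
})

test_that("planted kinks close the loop with the bend profiler", {
  h <- make_helix(24, kinks = data.frame(position = 10, angle = 30))
  prof <- bend_profile(h, helix_segment(1, 24))
  expect_lte(abs(prof$resno[which.max(prof$mean_deg)] - 10), 1)
  expect_lt(abs(max(prof$mean_deg) - 30), 5)
})

test_that("hairpins subtend exactly the requested inter-axis angle", {
  for (th in c(0, 80, 180)) {
    hp <- make_hairpin(th)
    segs <- attr(hp, "segments")
    a <- interhelix_angle(hp, segs[1, ], segs[2, ])
    expect_angle_equal(a$mean, th, 2)
  }
  # numbering: continuous with a 3-residue unmodeled gap
  hp <- make_hairpin(65, n1 = 18, n2 = 12, start = 581L)
  expect_equal(attr(hp, "segments")$start, c(581L, 602L))
  expect_equal(attr(hp, "segments")$end, c(598L, 613L))
  expect_error(make_hairpin(200), "\\[0, 180\\]")
})

test_that("noise-free jittered ensembles look rigid to every analysis", {
  ens <- perturb_ensemble(make_hairpin(65), n_models = 6, sigma = 0,
                          seed = 3, rigid_jitter = TRUE)
  segs <- attr(make_hairpin(65), "segments")
  r <- pairwise_rmsd(ens, segs)
  expect_lt(r$mean, 1e-6)
  expect_lt(max(mobility_map(ens)$map), 1e-9)
})

test_that("noisy ensemble RMSD matches a Monte-Carlo oracle and the sigma*sqrt(6) level", {
  sigma <- 0.3
  ens <- perturb_ensemble(make_helix(18), n_models = 10, sigma = sigma, seed = 11)
  r <- pairwise_rmsd(ens, helix_segment(1, 18))
  # brute-force Monte-Carlo expectation of the same construction
  mc <- purrr::map_dbl(1:30, function(s) {
    e <- perturb_ensemble(make_helix(18), n_models = 2, sigma = sigma, seed = 100 + s)
    pairwise_rmsd(e, helix_segment(1, 18))$mean
  })
  expect_equal(r$mean, mean(mc), tolerance = 0.15 * mean(mc))
  # the no-superposition closed form sqrt(2)*sigma*sqrt(3) is an upper-side
  # approximation (the fit absorbs rigid degrees of freedom); 20% level
  expect_equal(r$mean, sqrt(6) * sigma, tolerance = 0.2 * sqrt(6) * sigma)
})

test_that("generators are pure functions of their arguments and seed", {
  a <- perturb_ensemble(make_hairpin(65), n_models = 5, sigma = 0.3, seed = 42)
  b <- perturb_ensemble(make_hairpin(65), n_models = 5, sigma = 0.3, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c_ <- perturb_ensemble(make_hairpin(65), n_models = 5, sigma = 0.3, seed = 43)
  expect_false(identical(a$x, c_$x))
  # and they do not disturb the caller's RNG stream
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(make_hairpin(30, seed = 9)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("planted table effects close the loop exactly", {
  planted <- tibble::tibble(resno = 1:10, csp = 0, lipid = 0, water = 0)
  planted$csp[5] <- 0.1
  planted$lipid[3] <- 0.2
  planted$water[8] <- 0.4
  tabs <- make_tables(planted, overlap_at = 6L)

  prof <- csp(tabs$shift_a, tabs$shift_b)$profile
  expect_equal(prof$csp, planted$csp, tolerance = 1e-12)

  contacts <- contact_profile(tabs$peaks)
  expect_equal(contacts$lipid, planted$lipid, tolerance = 1e-12)
  expect_equal(contacts$water, planted$water, tolerance = 1e-12)

  expect_equal(flag_overlaps(tabs$assignments), c(6L, 7L))
  expect_error(make_tables(dplyr::mutate(planted, csp = NaN)), "finite")
})

test_that("backbone emission adds N and C atoms without changing the CA ground truth", {
  h <- make_helix(18, backbone = TRUE)
  expect_setequal(unique(h$elety), c("N", "CA", "C"))
  f <- fit_axis(h, helix_segment(1, 18))
  expect_lt(acos_dev(c(f$ax, f$ay, f$az), c(0, 0, 1)), 0.5)
})
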