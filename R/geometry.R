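#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between paired coordinate sets, via the SVD of the cross-covariance
#' matrix with the determinant sign corrected so that only proper rotations
#' (no reflections) are returned. The transform maps `mobile` onto
#' `reference`: `mobile %*% R + t`.
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates
#'   (same n, n >= 3, not collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, after superposition).
#' @examples
#' p <- matrix(rnorm(12), 4, 3)
#' kabsch(p, p)$rmsd
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("`mobile` and `reference` must be equal-size n x 3 matrices.")
  }
  if (nrow(mobile) < 3) abort("Need at least 3 paired points.")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8) {
    abort("Degenerate (collinear) coordinate set; rotation is not determined.")
  }
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- A %*% R
  list(
    rotation = R,
    translation = as.numeric(cr - cm %*% R),
    rmsd = sqrt(mean(rowSums((fitted - B)^2)))
  )
}

#' Helix segment selector
#'
#' @param start,end First and last absolute residue numbers (inclusive).
#' @param chain Optional chain id (default: whatever single chain the
#'   ensemble holds).
#' @return A one-row tibble `start`, `end`, `chain`.
#' @export
helix_segment <- function(start, end, chain = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (end - start + 1L < 5L) {
    abort("A helix segment needs at least 5 residues (about 1.4 turns) for a stable axis fit.")
  }
  tibble(start = start, end = end, chain = chain)
}

segment_resnos <- function(segments) {
  unlist(purrr::map2(segments$start, segments$end, seq), use.names = FALSE)
}

check_segment_atoms <- function(ens, segments, atom_set) {
  idx <- shared_index(ens)
  resnos <- segment_resnos(segments)
  have <- idx %>%
    filter(atom_set_mask(atom_set, .data$elety)) %>%
    pull(.data$resno)
  missing <- setdiff(resnos, unique(have))
  if (length(missing) > 0) {
    abort(sprintf("No shared %s atoms for residue(s): %s.",
                  atom_set, paste(missing, collapse = ", ")))
  }
}

#' Average pairwise RMSD of an ensemble over selected segments
#'
#' For every unordered pair of conformers, the selected atoms of the
#' selected segments are superposed jointly (one Kabsch fit over all
#' segments at once) and the post-fit RMSD recorded. The mean and sample
#' standard deviation (denominator M-1) over all M(M-1)/2 pairs is the
#' standard precision statistic quoted for NMR ensembles.
#'
#' @param ens Ensemble tibble.
#' @param segments Tibble of segments from [helix_segment()] (rows may be
#'   bound together to select several helices jointly).
#' @param atom_set `"backbone"` (N, CA, C) or `"heavy"` (all non-hydrogen).
#' @return Object of class `jm_rmsd`: list with `pairs` (tibble `model_i`,
#'   `model_j`, `rmsd`), `mean`, `sd`, `atom_set`, `segments`, `n_models`.
#' @export
pairwise_rmsd <- function(ens, segments, atom_set = c("backbone", "heavy")) {
  atom_set <- match.arg(atom_set)
  ens <- as_ensemble(ens, quiet = TRUE)
  models <- sort(unique(ens$model))
  if (length(models) < 2) abort("Pairwise RMSD needs at least 2 conformers.")
  check_segment_atoms(ens, segments, atom_set)
  resnos <- segment_resnos(segments)
  coords <- purrr::map(models, shared_coords, ens = ens,
                       resnos = resnos, atom_set = atom_set)
  pairs <- tidyr::expand_grid(i = seq_along(models), j = seq_along(models)) %>%
    filter(.data$i < .data$j) %>%
    mutate(
      model_i = models[.data$i], model_j = models[.data$j],
      rmsd = purrr::map2_dbl(.data$i, .data$j,
                             ~kabsch(coords[[.x]], coords[[.y]])$rmsd)
    ) %>%
    select("model_i", "model_j", "rmsd")
  structure(
    list(pairs = pairs, mean = mean(pairs$rmsd), sd = sd(pairs$rmsd),
         atom_set = atom_set, segments = segments, n_models = length(models)),
    class = "jm_rmsd"
  )
}

#' Fit a helix axis per conformer
#'
#' The axis is obtained by least-squares alignment of the segment's CA
#' atoms onto themselves shifted by one residue: the optimal rigid
#' transform mapping CA(1..n-1) onto CA(2..n) is a screw motion whose
#' rotation axis is the helix axis. The fit is exact for an ideal helix of
#' any length and degrades gracefully under coordinate noise (it uses every
#' CA in one least-squares superposition). A plain principal-component line
#' fit is *not* used: on finite helix arcs with non-integral turn coverage
#' its axis is systematically tilted by several degrees (up to ~18 deg for
#' a 7-residue window), which would swamp the bend and angle analyses. The
#' sign is fixed so the axis points from the N- towards the C-terminus.
#'
#' @param ens Ensemble tibble.
#' @param segment One-row tibble from [helix_segment()].
#' @return Object of class `jm_axis`: tibble with one row per conformer
#'   (`model`, `ax`, `ay`, `az` unit axis components, `cx`, `cy`, `cz`
#'   centroid in Angstrom); the segment is kept as attribute `"segment"`.
#' @export
fit_axis <- function(ens, segment) {
  ens <- as_ensemble(ens, quiet = TRUE)
  if (segment$end - segment$start + 1L < 5L) abort("Axis fit needs >= 5 residues.")
  models <- sort(unique(ens$model))
  resnos <- segment$start:segment$end
  out <- purrr::map_dfr(models, function(m) {
    ca <- shared_coords(ens, m, resnos = resnos, elety = "CA")
    if (nrow(ca) < 5) {
      abort(sprintf("Segment %d-%d has only %d shared CA atoms (>= 5 needed).",
                    segment$start, segment$end, nrow(ca)))
    }
    cen <- colMeans(ca)
    X <- sweep(ca, 2, cen)
    s <- svd(X)
    if (s$d[2] < 1e-8 * max(s$d[1], 1)) {
      abort("Degenerate CA cloud (rank < 2); cannot fit a helix axis.")
    }
    n_ca <- nrow(ca)
    fit <- kabsch(ca[seq_len(n_ca - 1), , drop = FALSE],
                  ca[2:n_ca, , drop = FALSE])
    e <- eigen(fit$rotation)
    v1 <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v1 <- unit(v1)
    # N->C orientation: axis must point with the chain direction
    if (sum(v1 * (ca[n_ca, ] - ca[1, ])) < 0) v1 <- -v1
    tibble(model = m, ax = v1[1], ay = v1[2], az = v1[3],
           cx = cen[1], cy = cen[2], cz = cen[3])
  })
  structure(out, segment = segment, class = c("jm_axis", class(tibble())))
}

axis_matrix <- function(axis_fit) {
  as.matrix(axis_fit[, c("ax", "ay", "az")])
}

#' Interhelical angle between two segments
#'
#' Per conformer, the angle between the N->C directed axes of the two
#' segments, `acos` of their dot product, in degrees within \[0, 180\].
#' Because the axes are directed, parallel helices score 0 and antiparallel
#' ones 180. The summary is the arithmetic mean and sample SD over
#' conformers (adequate away from the 0/180 wrap; no circular statistics).
#'
#' @param ens Ensemble tibble.
#' @param seg1,seg2 Segments from [helix_segment()].
#' @param method `"per_conformer"` (default): fit axes and take the angle in
#'   each conformer, then average. `"mean_axis"`: average the per-conformer
#'   unit axes first and report the single angle between the mean axes.
#' @return Object of class `jm_angle`: list with `angles` (tibble `model`,
#'   `angle_deg`), `mean`, `sd`, `seg1`, `seg2`, `method`.
#' @export
interhelix_angle <- function(ens, seg1, seg2,
                             method = c("per_conformer", "mean_axis")) {
  method <- match.arg(method)
  f1 <- fit_axis(ens, seg1)
  f2 <- fit_axis(ens, seg2)
  a1 <- axis_matrix(f1); a2 <- axis_matrix(f2)
  if (method == "per_conformer") {
    angles <- tibble(
      model = f1$model,
      angle_deg = acos_deg(rowSums(a1 * a2))
    )
    structure(list(angles = angles, mean = mean(angles$angle_deg),
                   sd = if (nrow(angles) > 1) sd(angles$angle_deg) else 0,
                   seg1 = seg1, seg2 = seg2, method = method),
              class = "jm_angle")
  } else {
    m1 <- unit(colMeans(a1)); m2 <- unit(colMeans(a2))
    ang <- acos_deg(sum(m1 * m2))
    structure(list(angles = tibble(model = NA_integer_, angle_deg = ang),
                   mean = ang, sd = NA_real_, seg1 = seg1, seg2 = seg2,
                   method = method),
              class = "jm_angle")
  }
}

#' Local bend-angle profile along a helix
#'
#' Slides two axis-fit windows of `window` residues along the segment, the
#' downstream window displaced by `offset` residues from the upstream one
#' (`offset = window`, the default, makes them adjacent). At each position
#' the angle between the two local axes is recorded, anchored at the first
#' residue of the downstream window. Kinks show up as localised maxima of
#' the mean track; an ideal straight helix stays within a couple of degrees
#' of zero (residual wobble of finite-window axis fits).
#'
#' @param ens Ensemble tibble.
#' @param segment Segment to profile.
#' @param window Axis-fit window length, residues (>= 5; default 7, about
#'   two helical turns, enough for a stable local axis).
#' @param offset Displacement of the downstream window start relative to the
#'   upstream window start (>= window; default equal to `window`).
#' @return Tibble of class `jm_bend`: `resno` (anchor), `mean_deg`, `sd_deg`
#'   plus one `angle_deg` row per conformer in long attribute-free columns
#'   `model`, `angle_deg` accessible via `attr(, "per_conformer")`.
#' @export
bend_profile <- function(ens, segment, window = 7L, offset = 7L) {
  window <- as.integer(window); offset <- as.integer(offset)
  if (window < 5L) abort("`window` must be >= 5 residues.")
  if (offset < window) abort("`offset` must be >= `window` (windows may not overlap).")
  len <- segment$end - segment$start + 1L
  if (len < offset + window) {
    abort(sprintf("Segment %d-%d too short for window %d / offset %d.",
                  segment$start, segment$end, window, offset))
  }
  anchors <- (segment$start + offset):(segment$end - window + 1L)
  per <- purrr::map_dfr(anchors, function(c0) {
    up <- helix_segment(c0 - offset, c0 - offset + window - 1L)
    dn <- helix_segment(c0, c0 + window - 1L)
    a1 <- fit_axis(ens, up); a2 <- fit_axis(ens, dn)
    tibble(resno = c0, model = a1$model,
           angle_deg = acos_deg(rowSums(axis_matrix(a1) * axis_matrix(a2))))
  })
  out <- per %>%
    group_by(.data$resno) %>%
    summarise(mean_deg = mean(.data$angle_deg),
              sd_deg = if (n() > 1) sd(.data$angle_deg) else 0, .groups = "drop")
  structure(out, per_conformer = per, window = window, offset = offset,
            segment = segment, class = c("jm_bend", class(tibble())))
}

#' @export
print.jm_rmsd <- function(x, ...) {
  cat(sprintf("Pairwise RMSD (%s atoms, %d conformers, %d pairs): %.2f +/- %.2f A\n",
              x$atom_set, x$n_models, nrow(x$pairs), x$mean, x$sd))
  invisible(x)
}

#' @export
print.jm_angle <- function(x, ...) {
  cat(sprintf("Interhelical angle %d-%d vs %d-%d (%s): %.1f +/- %.1f deg\n",
              x$seg1$start, x$seg1$end, x$seg2$start, x$seg2$end,
              x$method, x$mean, x$sd))
  invisible(x)
}
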