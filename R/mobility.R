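#' Internal mobility map of a conformer ensemble
#'
#' For every pair of residues, the standard deviation over conformers of the
#' CA-CA Euclidean distance. Distances are invariant under rigid-body
#' motion, so the map isolates *internal* flexibility: rigid structural
#' domains appear as low-deviation blocks on the diagonal, while helices
#' that change their relative position or orientation across the ensemble
#' produce high off-diagonal inter-domain blocks.
#'
#' @param ens Ensemble tibble (>= 2 conformers with CA atoms in the shared
#'   index).
#' @param from,to Optional absolute residue range to map; defaults to every
#'   residue with a shared CA atom.
#' @param units `"nm"` (default, the conventional colour-scale unit for such
#'   maps) or `"angstrom"`.
#' @return Object of class `jm_mobility`: list with `resno` (residue index),
#'   `map` (symmetric matrix, zero diagonal, labelled by residue number),
#'   `units`, `n_models`.
#' @export
mobility_map <- function(ens, from = NULL, to = NULL, units = c("nm", "angstrom")) {
  units <- match.arg(units)
  ens <- as_ensemble(ens, quiet = TRUE)
  models <- sort(unique(ens$model))
  if (length(models) < 2) abort("A mobility map needs at least 2 conformers.")
  idx <- shared_index(ens) %>% filter(.data$elety == "CA")
  resno <- sort(unique(idx$resno))
  if (!is.null(from)) resno <- resno[resno >= from]
  if (!is.null(to)) resno <- resno[resno <= to]
  if (length(resno) < 2) abort("Fewer than 2 residues with shared CA atoms in range.")
  dists <- purrr::map(models, function(m) {
    ca <- shared_coords(ens, m, resnos = resno, elety = "CA")
    as.matrix(dist(ca))
  })
  arr <- simplify2array(dists)                      # n x n x M
  sdm <- apply(arr, c(1, 2), sd)
  diag(sdm) <- 0
  if (units == "nm") sdm <- sdm / 10
  dimnames(sdm) <- list(resno, resno)
  structure(list(resno = resno, map = sdm, units = units,
                 n_models = length(models)),
            class = "jm_mobility")
}

#' Rigid-domain blocks of a mobility map
#'
#' Greedily extracts maximal diagonal intervals within which *every*
#' pairwise distance deviation is below `cutoff`; such intervals behave as
#' rigid bodies across the ensemble. Scanning left to right, each block is
#' extended as far as possible, then the next block starts at the following
#' residue, so blocks partition the mapped residues.
#'
#' @param map A `jm_mobility` object.
#' @param cutoff Deviation cut-off in the map's own units (default 0.1, i.e.
#'   0.1 nm for the default map).
#' @return Tibble with one row per block: `start`, `end`, `n_residues`,
#'   `max_internal` (largest deviation inside the block).
#' @export
rigid_blocks <- function(map, cutoff = 0.1) {
  stopifnot(inherits(map, "jm_mobility"))
  M <- map$map
  res <- map$resno
  n <- length(res)
  blocks <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && all(M[i:(j + 1L), i:(j + 1L)] < cutoff | diag(j - i + 2L) == 1)) {
      j <- j + 1L
    }
    sub <- M[i:j, i:j, drop = FALSE]
    blocks[[length(blocks) + 1L]] <- tibble(
      start = res[i], end = res[j], n_residues = j - i + 1L,
      max_internal = if (j > i) max(sub[upper.tri(sub)]) else 0
    )
    i <- j + 1L
  }
  bind_rows(blocks)
}

#' @export
print.jm_mobility <- function(x, ...) {
  cat(sprintf("Mobility map: %d residues (%d-%d), %d conformers, units %s; max deviation %.3f\n",
              length(x$resno), min(x$resno), max(x$resno), x$n_models, x$units,
              max(x$map)))
  invisible(x)
}
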