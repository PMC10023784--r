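#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-conformer detail of geometry results
#'
#' `tidy()` returns the per-observation detail (one row per conformer pair,
#' conformer, or residue pair); `glance()` returns a one-row summary.
#'
#' @param x A `jm_angle`, `jm_rmsd`, `jm_mobility` or `jm_csp` object.
#' @param ... Unused.
#' @return A tibble.
#' @name memjm-tidiers
NULL

#' @rdname memjm-tidiers
#' @method tidy jm_angle
#' @export
tidy.jm_angle <- function(x, ...) x$angles

#' @rdname memjm-tidiers
#' @method glance jm_angle
#' @export
glance.jm_angle <- function(x, ...) {
  tibble(
    mean_deg = x$mean, sd_deg = x$sd, n_conformers = nrow(x$angles),
    seg1 = sprintf("%d-%d", x$seg1$start, x$seg1$end),
    seg2 = sprintf("%d-%d", x$seg2$start, x$seg2$end),
    method = x$method
  )
}

#' @rdname memjm-tidiers
#' @method tidy jm_rmsd
#' @export
tidy.jm_rmsd <- function(x, ...) x$pairs

#' @rdname memjm-tidiers
#' @method glance jm_rmsd
#' @export
glance.jm_rmsd <- function(x, ...) {
  tibble(
    mean_rmsd = x$mean, sd_rmsd = x$sd, n_pairs = nrow(x$pairs),
    n_conformers = x$n_models, atom_set = x$atom_set,
    segments = paste(sprintf("%d-%d", x$segments$start, x$segments$end),
                     collapse = ",")
  )
}

#' @rdname memjm-tidiers
#' @method tidy jm_mobility
#' @export
tidy.jm_mobility <- function(x, ...) {
  m <- x$map
  tidyr::expand_grid(resno_i = x$resno, resno_j = x$resno) %>%
    mutate(deviation = as.vector(t(m)))
}

#' @rdname memjm-tidiers
#' @method glance jm_mobility
#' @export
glance.jm_mobility <- function(x, ...) {
  off <- x$map[upper.tri(x$map)]
  tibble(n_residues = length(x$resno), n_conformers = x$n_models,
         units = x$units, max_deviation = max(off), median_deviation = stats::median(off))
}

#' @rdname memjm-tidiers
#' @method tidy jm_csp
#' @export
tidy.jm_csp <- function(x, ...) x$profile

#' @rdname memjm-tidiers
#' @method glance jm_csp
#' @export
glance.jm_csp <- function(x, ...) {
  tibble(
    n_residues = nrow(x$profile),
    max_csp = max(x$profile$csp),
    argmax_resno = x$profile$resno[which.max(x$profile$csp)],
    n_unmatched = length(x$only_a) + length(x$only_b)
  )
}
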