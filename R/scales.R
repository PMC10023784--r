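#' Amino-acid hydropathy and interfacial scales
#'
#' Two per-residue scales ship with the package:
#'
#' * `"kd"` — the Kyte-Doolittle hydropathy index (dimensionless; hydrophobic
#'   positive). The canonical default for sliding-window hydropathy plots.
#' * `"ww_interface"` — the Wimley-White water-to-POPC-interface transfer
#'   free energies (kcal/mol; partitioning into the lipid/water interface is
#'   favourable when negative). Asp and Glu carry their charged-form values
#'   and His its neutral-form value, the scale's standard presentation.
#'
#' @param scale Scale identifier, one of `names(aa_scales())`.
#' @return `aa_scales()` returns the named list of all shipped scales;
#'   `aa_scale(scale)` returns one scale as a named numeric vector over the
#'   20 canonical one-letter codes.
#' @examples
#' aa_scale("kd")[["L"]]
#' @export
aa_scales <- function() {
  list(
    kd = c(
      A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
    ),
    ww_interface = c(
      A =  0.17, R =  0.81, N =  0.42, D =  1.23, C = -0.24,
      Q =  0.58, E =  2.02, G =  0.01, H =  0.17, I = -0.31,
      L = -0.56, K =  0.99, M = -0.23, F = -1.13, P =  0.45,
      S =  0.13, T =  0.14, W = -1.85, Y = -0.94, V =  0.07
    )
  )
}

#' @rdname aa_scales
#' @export
aa_scale <- function(scale) {
  scales <- aa_scales()
  if (!scale %in% names(scales)) {
    abort(sprintf(
      "Unknown scale '%s'. Shipped scales: %s.",
      scale, paste(names(scales), collapse = ", ")
    ))
  }
  scales[[scale]]
}

aa_canonical <- function() names(aa_scales()$kd)
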