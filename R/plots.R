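#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for analysis results
#'
#' Each result type draws its conventional display: hydropathy profiles as
#' bars coloured by hydrophobic/hydrophilic label, bend profiles as a mean
#' line with an SD ribbon, mobility maps as a heat map, CSP and contact
#' profiles as per-residue bars.
#'
#' @param object A result object (`jm_profile`, `jm_bend`, `jm_mobility`,
#'   `jm_csp`, `jm_contacts`).
#' @param threshold Hydrophobicity threshold used to colour profile bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @name memjm-plots
NULL

#' @rdname memjm-plots
#' @method autoplot jm_profile
#' @export
autoplot.jm_profile <- function(object, threshold = 0, ...) {
  df <- mutate(as_tibble(object),
               label = ifelse(.data$value > threshold, "hydrophobic", "hydrophilic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$value, fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(hydrophobic = "#E6C229", hydrophilic = "#1B5E20")) +
    ggplot2::labs(x = "residue", fill = NULL,
                  y = sprintf("windowed mean (%s, frame %d)",
                              attr(object, "scale"), attr(object, "frame")))
}

#' @rdname memjm-plots
#' @method autoplot jm_bend
#' @export
autoplot.jm_bend <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$mean_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean_deg - .data$sd_deg),
                                      ymax = .data$mean_deg + .data$sd_deg),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "local bend angle (deg)")
}

#' @rdname memjm-plots
#' @method autoplot jm_mobility
#' @export
autoplot.jm_mobility <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$resno_i, y = .data$resno_j, fill = .data$deviation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = max(object$map) / 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue",
                  fill = sprintf("deviation (%s)", object$units))
}

#' @rdname memjm-plots
#' @method autoplot jm_csp
#' @export
autoplot.jm_csp <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$resno, y = .data$csp)) +
    ggplot2::geom_col(fill = "#4575B4") +
    ggplot2::labs(x = "residue", y = "CSP (ppm)")
}

#' @rdname memjm-plots
#' @method autoplot jm_contacts
#' @export
autoplot.jm_contacts <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("lipid", "water"),
                            names_to = "track", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$intensity, fill = .data$track)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(lipid = "#E6C229", water = "#4575B4")) +
    ggplot2::labs(x = "residue", y = "normalised NOE intensity", fill = NULL)
}
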