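#' Amide chemical-shift perturbations between two conditions
#'
#' Combines the backbone amide 1H and 15N shift changes per residue into the
#' weighted perturbation
#' \deqn{CSP = \sqrt{\Delta H^2 + \Delta N^2 / 10^2}}
#' where the 15N change is scaled down by a factor of 10 to account for the
#' different gyromagnetic ratios of the two nuclei. Residues present in only
#' one table are reported, never imputed.
#'
#' @param a,b Shift tables (tibbles with `resno`, `H_ppm`, `N_ppm`; see
#'   [read_shift_table()]).
#' @return Object of class `jm_csp`: list with `profile` (tibble `resno`,
#'   `dH`, `dN`, `csp` in ppm), `only_a`, `only_b` (residue numbers
#'   unmatched in the other table).
#' @examples
#' a <- tibble::tibble(resno = 1:2, H_ppm = c(8.0, 8.2), N_ppm = c(120, 118))
#' b <- dplyr::mutate(a, H_ppm = H_ppm + c(0, 0.1), N_ppm = N_ppm + c(0, 1))
#' csp(a, b)$profile
#' @export
csp <- function(a, b) {
  shared <- inner_join(a, b, by = "resno", suffix = c("_a", "_b"))
  if (nrow(shared) == 0) abort("The two shift tables share no residue.")
  profile <- shared %>%
    mutate(
      dH = .data$H_ppm_b - .data$H_ppm_a,
      dN = .data$N_ppm_b - .data$N_ppm_a,
      csp = sqrt(.data$dH^2 + .data$dN^2 / 100)
    ) %>%
    select("resno", "dH", "dN", "csp") %>%
    arrange(.data$resno)
  structure(
    list(profile = profile,
         only_a = sort(setdiff(a$resno, b$resno)),
         only_b = sort(setdiff(b$resno, a$resno))),
    class = "jm_csp"
  )
}

#' Lipid- and water-contact profile from NOESY peak intensities
#'
#' Normalises per-residue NOE cross-peak intensities towards the lipid CH2
#' region and towards water by the residue's own diagonal-peak intensity,
#' and classifies residues by the resulting contact strengths. Residues
#' flagged as excluded (their own protons, or those of the preceding
#' residue, resonate inside the lipid window, so the "lipid" cross-peak is
#' contaminated; see [flag_overlaps()]) are passed through with class
#' `"excluded"` and no normalised lipid value.
#'
#' @param peaks Peak table (see [read_peak_table()]).
#' @param exclusions Optional integer vector of residue numbers to exclude
#'   from the lipid track, merged with any `excluded` flags in `peaks`.
#' @param t_lipid,t_water Classification thresholds on the normalised
#'   intensities (defaults 0.05 each; the class boundaries used for surface
#'   colouring are a presentation choice, not a measurement).
#' @return Object of class `jm_contacts`: tibble `resno`, `lipid`, `water`
#'   (normalised intensities), `class` in
#'   `{"lipid", "water", "both", "none", "excluded"}`.
#' @export
contact_profile <- function(peaks, exclusions = NULL,
                            t_lipid = 0.05, t_water = 0.05) {
  excl <- peaks$excluded | peaks$resno %in% (exclusions %||% integer(0))
  bad <- peaks$resno[!excl & peaks$I_diag <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Missing/non-positive diagonal intensity for residue(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  out <- peaks %>%
    mutate(
      excluded = excl,
      lipid = ifelse(.data$excluded, NA_real_, .data$I_lipid / .data$I_diag),
      water = ifelse(.data$I_diag > 0, .data$I_water / .data$I_diag, NA_real_),
      class = case_when(
        .data$excluded ~ "excluded",
        .data$lipid >= t_lipid & .data$water >= t_water ~ "both",
        .data$lipid >= t_lipid ~ "lipid",
        .data$water >= t_water ~ "water",
        TRUE ~ "none"
      )
    ) %>%
    select("resno", "lipid", "water", "class") %>%
    arrange(.data$resno)
  structure(out, t_lipid = t_lipid, t_water = t_water,
            class = c("jm_contacts", class(tibble())))
}

#' Flag residues whose protons overlap a spectral window
#'
#' A residue's lipid cross-peak is unusable when any proton of the residue
#' itself or of its predecessor (residue i-1) resonates at a chemical shift
#' close to the lipid CH2 window, because intra- and sequential NOEs then
#' masquerade as protein-lipid contacts. This returns the residues to
#' exclude: every residue owning such a proton, and the residue following
#' it.
#'
#' @param assignments Tibble with columns `resno` and `shift_ppm`, one row
#'   per assigned proton (side-chain and backbone alike).
#' @param window Length-2 numeric, the spectral window in ppm (default
#'   `c(1.25, 1.35)`, the lipid CH2 region).
#' @param margin Extra margin in ppm added on both sides ("close" shifts;
#'   default 0.05). `margin = 0` gives strict-window behaviour.
#' @return Sorted integer vector of residue numbers to exclude.
#' @export
flag_overlaps <- function(assignments, window = c(1.25, 1.35), margin = 0.05) {
  lo <- min(window) - margin
  hi <- max(window) + margin
  own <- assignments %>%
    filter(.data$shift_ppm >= lo, .data$shift_ppm <= hi) %>%
    pull(.data$resno) %>%
    unique()
  sort(unique(c(own, own + 1L)))
}

#' @export
print.jm_csp <- function(x, ...) {
  cat(sprintf("CSP profile: %d residues; max %.3f ppm at residue %s\n",
              nrow(x$profile), max(x$profile$csp),
              x$profile$resno[which.max(x$profile$csp)]))
  if (length(x$only_a) + length(x$only_b) > 0) {
    cat(sprintf("  unmatched residues: %d only in `a`, %d only in `b`\n",
                length(x$only_a), length(x$only_b)))
  }
  invisible(x)
}
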