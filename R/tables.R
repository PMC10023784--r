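#' Read chemical-shift and NOE peak tables
#'
#' Both readers consume tab-separated files with a header row.
#'
#' * Shift tables need columns `residue`, `H_ppm`, `N_ppm` — the backbone
#'   amide 1H and 15N chemical shifts per residue.
#' * Peak tables need columns `residue`, `I_lipid`, `I_water`, `I_diag` —
#'   NOESY cross-peak intensities towards the lipid CH2 region and towards
#'   water, plus the residue's diagonal-peak intensity used for
#'   normalisation. An optional logical `excluded` column pre-flags residues
#'   whose lipid cross-peaks are unusable (spectral overlap).
#'
#' Rows with a blank required field are skipped with a message; duplicated
#' residue numbers and non-positive diagonal intensities are rejected.
#'
#' @param path Path to a TSV file.
#' @return A tibble, columns renamed to `resno`, `H_ppm`, `N_ppm` (shifts) or
#'   `resno`, `I_lipid`, `I_water`, `I_diag`, `excluded` (peaks).
#' @export
read_shift_table <- function(path) {
  tab <- read_tsv_checked(path, c("residue", "H_ppm", "N_ppm"))
  tab %>%
    rename(resno = "residue") %>%
    mutate(resno = as.integer(.data$resno))
}

#' @rdname read_shift_table
#' @export
read_peak_table <- function(path) {
  tab <- read_tsv_checked(path, c("residue", "I_lipid", "I_water", "I_diag"))
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  tab$excluded <- as.logical(tab$excluded) %|NA|% FALSE
  bad <- tab$residue[!tab$excluded & tab$I_diag <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Non-positive diagonal intensity for residue(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (any(tab$I_lipid < 0 | tab$I_water < 0)) abort("Negative cross-peak intensities.")
  tab %>%
    rename(resno = "residue") %>%
    mutate(resno = as.integer(.data$resno))
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    abort(sprintf("%s lacks required column(s): %s.", path, paste(miss, collapse = ", ")))
  }
  ok <- stats::complete.cases(tab[required])
  if (any(!ok)) {
    inform(sprintf("Skipped %d row(s) with blank required fields in %s.", sum(!ok), path))
    tab <- tab[ok, , drop = FALSE]
  }
  if (anyDuplicated(tab$residue)) {
    abort(sprintf("Duplicated residue number(s) in %s: %s.", path,
                  paste(unique(tab$residue[duplicated(tab$residue)]), collapse = ", ")))
  }
  tab
}
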