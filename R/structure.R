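#' Conformer-ensemble atom tables
#'
#' A structure ensemble is a long tibble with one row per atom per conformer:
#' columns `model` (1-based conformer index), `chain`, `resno` (absolute
#' residue number), `resid` (3-letter residue name), `elety` (PDB atom name)
#' and `x`, `y`, `z` coordinates in Angstrom. All geometry operations work on
#' the *shared index* — the set of `(chain, resno, elety)` keys present in
#' every conformer — so ensembles whose models differ in terminal atoms are
#' usable without manual pruning.
#'
#' `as_ensemble()` validates a tibble of this shape: at least one conformer,
#' finite coordinates, no duplicate atom key within a conformer, non-empty
#' shared index.
#'
#' @param atoms Tibble (or data frame) with the columns listed above.
#' @param quiet Suppress the warning listing atoms dropped from the shared
#'   index.
#' @return A validated ensemble tibble (class `jm_ensemble`) carrying the
#'   shared index as attribute `"shared_index"` and the conformer count as
#'   `"n_models"`.
#' @export
as_ensemble <- function(atoms, quiet = FALSE) {
  need <- c("model", "chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(sprintf("Ensemble table lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  atoms$elety <- trimws(atoms$elety)
  if (nrow(atoms) == 0) abort("Ensemble contains no atoms.")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("Ensemble contains non-finite coordinates.")
  }
  dup <- atoms %>%
    dplyr::count(.data$model, .data$chain, .data$resno, .data$elety) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate atom key(s) within a conformer, e.g. model %d %s%d %s.",
      dup$model[1], dup$chain[1], dup$resno[1], dup$elety[1]
    ))
  }
  m <- length(unique(atoms$model))
  counts <- atoms %>%
    dplyr::count(.data$chain, .data$resno, .data$elety, name = "n_present")
  shared <- counts %>% filter(.data$n_present == m) %>% select(-"n_present")
  if (nrow(shared) == 0) abort("No atom is present in every conformer (empty shared index).")
  dropped <- counts %>% filter(.data$n_present < m)
  if (nrow(dropped) > 0 && !quiet) {
    warn(sprintf(
      "%d atom(s) absent from some conformers dropped from the shared index: %s",
      nrow(dropped),
      paste(sprintf("%s%d/%s", dropped$chain, dropped$resno, dropped$elety)[
        seq_len(min(8, nrow(dropped)))], collapse = ", ")
    ))
  }
  atoms <- arrange(atoms, .data$model, .data$chain, .data$resno,
                   match(.data$elety, c("N", "CA", "C", "O")), .data$elety)
  structure(atoms,
    shared_index = arrange(shared, .data$chain, .data$resno, .data$elety),
    n_models = m,
    class = c("jm_ensemble", class(tibble())))
}

#' @rdname as_ensemble
#' @param ens An ensemble tibble.
#' @export
n_models <- function(ens) {
  attr(ens, "n_models") %||% length(unique(ens$model))
}

#' @rdname as_ensemble
#' @export
shared_index <- function(ens) {
  attr(ens, "shared_index") %||% shared_index(as_ensemble(ens, quiet = TRUE))
}

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' MODEL/ENDMDL blocks become conformers in file order; a single-model file
#' yields a one-conformer ensemble. Alternate locations are resolved per
#' conformer by keeping the highest-occupancy altloc (ties broken towards
#' altloc `A`). Atoms missing from any conformer are dropped from the shared
#' index with a warning.
#'
#' @param path Path to a PDB file with ATOM records.
#' @param chain Chain identifier to keep. Default: the first chain
#'   encountered (depositions of single-chain peptides need no choice).
#' @return An ensemble tibble (see [as_ensemble()]).
#' @export
read_pdb_ensemble <- function(path, chain = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) ends <- c(ends, length(lines))
    purrr::map2(starts, ends[seq_along(starts)], ~lines[.x:.y])
  }
  atoms <- purrr::imap_dfr(blocks, function(block, i) {
    if (!any(grepl("^ATOM", block))) return(tibble())
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(block[grepl("^(ATOM|TER)", block)], "END"), tmp)
    a <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE))$atom
    a <- a[a$type == "ATOM", , drop = FALSE]
    tibble(
      model = i, chain = a$chain %|NA|% "A", resno = a$resno, resid = a$resid,
      elety = a$elety, alt = a$alt, o = a$o %|NA|% 1,
      x = a$x, y = a$y, z = a$z
    )
  })
  if (nrow(atoms) == 0) abort(sprintf("No ATOM records in %s", path))
  if (is.null(chain)) {
    chain <- atoms$chain[1]
  } else if (!chain %in% atoms$chain) {
    abort(sprintf("Chain '%s' not found; available: %s.",
                  chain, paste(unique(atoms$chain), collapse = ", ")))
  }
  atoms <- filter(atoms, .data$chain == !!chain)
  # altloc resolution: highest occupancy, tie -> 'A' (NA altloc sorts first)
  atoms <- atoms %>%
    group_by(.data$model, .data$chain, .data$resno, .data$elety) %>%
    arrange(dplyr::desc(.data$o), !is.na(.data$alt), .data$alt, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"alt", -"o")
  as_ensemble(atoms)
}

`%|NA|%` <- function(x, fill) {
  x[is.na(x)] <- fill
  x
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Coordinates are written in the fixed-width PDB dialect (three decimals),
#' so a read/write round trip reproduces them to 1e-3 Angstrom.
#'
#' @param ens Ensemble tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  ens <- as_ensemble(ens, quiet = TRUE)
  out <- character(0)
  for (m in sort(unique(ens$model))) {
    a <- filter(ens, .data$model == m)
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
      elety = a$elety, chain = a$chain
    )
    body <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    body <- body[grepl("^(ATOM|TER)", body)]
    out <- c(out, sprintf("MODEL     %4d", m), body, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# Coordinates of the selected shared atoms of one conformer, as an n x 3
# matrix in a model-independent row order.
shared_coords <- function(ens, model, resnos = NULL, atom_set = NULL, elety = NULL) {
  idx <- shared_index(ens)
  if (!is.null(resnos)) idx <- filter(idx, .data$resno %in% !!resnos)
  if (!is.null(elety)) idx <- filter(idx, .data$elety %in% !!elety)
  if (!is.null(atom_set)) idx <- filter(idx, atom_set_mask(atom_set, .data$elety))
  a <- inner_join(filter(ens, .data$model == !!model), idx,
                  by = c("chain", "resno", "elety"))
  a <- arrange(a, .data$chain, .data$resno, .data$elety)
  as.matrix(a[, c("x", "y", "z")])
}
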