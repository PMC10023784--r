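#' Annotated amino-acid sequences
#'
#' Sequences are represented as a tibble with one row per record and columns
#' `name`, `start` (absolute number of the first residue, UniProt convention)
#' and `sequence` (one-letter codes). Membrane-construct numbering is taken
#' verbatim from the source; no renumbering is ever applied, so residue
#' ranges quoted in absolute coordinates (e.g. a TM helix at 586-606) address
#' the data directly.
#'
#' @param sequence One-letter amino-acid string (20 canonical codes).
#' @param start Absolute residue number of the first residue (>= 1).
#' @param name Record name.
#' @return A one-row tibble with columns `name`, `start`, `sequence`, `end`.
#' @examples
#' annotated_sequence("MLLWVPIV", start = 581, name = "tm-fragment")
#' @export
annotated_sequence <- function(sequence, start = 1L, name = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 1L) abort("Sequence must contain at least one residue.")
  start <- as.integer(start)
  if (is.na(start) || start < 1L) abort("`start` must be an integer >= 1.")
  bad <- which(!strsplit(sequence, "")[[1]] %in% aa_canonical())
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-canonical residue code(s) in '%s' at position(s): %s.",
      name, paste(bad, collapse = ", ")
    ))
  }
  tibble(
    name = name, start = start, sequence = sequence,
    end = start + nchar(sequence) - 1L
  )
}

#' Read annotated sequences from a FASTA file
#'
#' Parses a FASTA file and returns one record per entry. An optional
#' `start=N` token anywhere in a header sets the absolute number of the first
#' residue (UniProt numbering convention); otherwise numbering starts at 1.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with one row per record: `name`, `start`, `sequence`, `end`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">jm start=581", "MLLWVPIV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(sprintf("No FASTA records in %s", path))
  purrr::map_dfr(seq_along(set), function(i) {
    header <- names(set)[i]
    tok <- stringr::str_match(header, "start=(\\d+)")[, 2]
    start <- if (is.na(tok)) 1L else as.integer(tok)
    name <- stringr::str_split_1(header, "\\s+")[1]
    annotated_sequence(as.character(set[[i]]), start = start, name = name)
  })
}

#' Expand sequence records to one row per residue
#'
#' @param seqs Tibble of records from [read_fasta()] or [annotated_sequence()].
#' @return Tibble with columns `name`, `resno` (absolute), `aa`.
#' @export
seq_residues <- function(seqs) {
  purrr::pmap_dfr(seqs[c("name", "start", "sequence")], function(name, start, sequence) {
    aa <- strsplit(sequence, "")[[1]]
    tibble(name = name, resno = start + seq_along(aa) - 1L, aa = aa)
  })
}

# Coerce a one-row record / bare string into a validated record.
as_seq_record <- function(seq, start = 1L, name = "seq") {
  if (is.character(seq)) return(annotated_sequence(seq, start = start, name = name))
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1L) {
      abort("Expected a single sequence record; got a multi-row table. Filter to one row first.")
    }
    return(annotated_sequence(seq$sequence, start = seq$start, name = seq$name))
  }
  abort("`seq` must be a one-letter string or a one-row sequence record.")
}
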