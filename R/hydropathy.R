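#' Sliding-window hydropathy profile
#'
#' Computes the moving average of a per-residue hydropathy scale over windows
#' of `frame` consecutive residues. A 4-residue frame is the default because
#' it is close to the step of an alpha-helix, so hydrophobic faces of helical
#' segments show up as contiguous high-value runs; this is the standard way
#' to locate transmembrane runs and membrane-associated juxtamembrane patches
#' from sequence alone.
#'
#' @param seq A one-row sequence record (see [annotated_sequence()]) or a
#'   bare one-letter string.
#' @param scale Scale name; see [aa_scales()]. Default Kyte-Doolittle.
#' @param frame Window length in residues (>= 1, <= sequence length).
#' @param anchor Report each window at its `"first"` residue (default, keeps
#'   the left edge of the TM run aligned with the raw sequence) or at its
#'   `"center"` residue.
#' @return A tibble of class `jm_profile` with one row per window: `window`
#'   (1-based index), `resno` (absolute anchor residue), `value` (windowed
#'   mean, scale units). Attributes `scale`, `frame`, `anchor` record the
#'   configuration.
#' @examples
#' window_hydropathy("LLLLKKKK", frame = 4)
#' @export
window_hydropathy <- function(seq, scale = "kd", frame = 4L,
                              anchor = c("first", "center")) {
  anchor <- match.arg(anchor)
  rec <- as_seq_record(seq)
  sc <- aa_scale(scale)
  aa <- strsplit(rec$sequence, "")[[1]]
  frame <- as.integer(frame)
  if (frame < 1L) abort("`frame` must be >= 1.")
  if (frame > length(aa)) {
    abort(sprintf("`frame` (%d) exceeds sequence length (%d).", frame, length(aa)))
  }
  vals <- zoo::rollmean(unname(sc[aa]), k = frame, align = "left")
  shift <- if (anchor == "first") 0L else (frame - 1L) %/% 2L
  out <- tibble(
    window = seq_along(vals),
    resno = rec$start + seq_along(vals) - 1L + shift,
    value = as.numeric(vals)
  )
  structure(out, scale = scale, frame = frame, anchor = anchor,
            name = rec$name, class = c("jm_profile", class(out)))
}

#' Label hydrophobic and hydrophilic runs of a hydropathy profile
#'
#' Maximal runs of windows whose value exceeds `threshold` are labelled
#' `hydrophobic`, the rest `hydrophilic`. Segments partition the profiled
#' window positions; because adjacent windows overlap by `frame - 1`
#' residues, the residue span actually covered by each run
#' (`res_first`..`res_last`) extends `frame - 1` residues past the last
#' anchored window.
#'
#' @param profile Output of [window_hydropathy()].
#' @param threshold Cut-off in scale units (default 0, i.e. the hydrophobic /
#'   hydrophilic sign boundary of the Kyte-Doolittle scale).
#' @return Tibble with one row per segment: `start`, `end` (anchor residue
#'   numbers, disjoint and exhaustive), `res_first`, `res_last` (residues
#'   covered), `n_windows`, `label`.
#' @export
annotate_regions <- function(profile, threshold = 0) {
  if (nrow(profile) == 0) abort("Empty profile.")
  frame <- attr(profile, "frame") %||% 1L
  r <- rle(profile$value > threshold)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  tibble(
    start = profile$resno[idx_start],
    end = profile$resno[idx_end],
    res_first = profile$resno[idx_start],
    res_last = profile$resno[idx_end] + frame - 1L,
    n_windows = r$lengths,
    label = ifelse(r$values, "hydrophobic", "hydrophilic")
  )
}

#' Interfacial partitioning propensity of a sequence range
#'
#' Scores a residue range on the Wimley-White water-to-bilayer-interface
#' transfer free-energy scale (kcal/mol; negative favours partitioning into
#' the lipid/water interface). Juxtamembrane segments of membrane receptors
#' that sit flat on the bilayer surface are typically rich in aromatic and
#' aliphatic residues and score more favourably (lower mean) than polar
#' controls.
#'
#' @param seq Sequence record or one-letter string.
#' @param from,to Absolute residue range to score; defaults to the whole
#'   sequence.
#' @return List with `track` (tibble: `resno`, `aa`, `value` in kcal/mol) and
#'   `mean` (mean transfer free energy over the range); metadata fields
#'   `scale` and `sign_convention`.
#' @export
interface_propensity <- function(seq, from = NULL, to = NULL) {
  rec <- as_seq_record(seq)
  from <- from %||% rec$start
  to <- to %||% rec$end
  if (from < rec$start || to > rec$end || from > to) {
    abort(sprintf("Range %d-%d outside sequence %d-%d.", from, to, rec$start, rec$end))
  }
  sc <- aa_scale("ww_interface")
  aa <- strsplit(rec$sequence, "")[[1]]
  keep <- seq(from - rec$start + 1L, to - rec$start + 1L)
  track <- tibble(resno = from:to, aa = aa[keep], value = unname(sc[aa[keep]]))
  list(
    track = track,
    mean = mean(track$value),
    scale = "ww_interface",
    sign_convention = "kcal/mol; negative = favourable interface partitioning"
  )
}
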