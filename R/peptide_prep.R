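#' Build the docking peptide window around a cleavage site
#'
#' Joins the two digestion fragments flanking one scissile bond,
#' truncated to at most `flank` residues on each side (default 10, i.e.
#' a 20-mer for interior sites, the scissile bond at its centre). The
#' window never crosses a recorded numbering break and never wraps a
#' terminus; sites closer than `flank` to a terminus give shorter
#' windows.
#'
#' @param seq character string or one-row sequence tibble.
#' @param p1_pos P1 position, in the sequence's author numbering.
#' @param flank maximum residues kept on each side of the bond (>= 1).
#' @return one-row tibble: `seq_id`, `p1_pos`, `start_pos`, `end_pos`
#'   (author numbering), `n_flank`, `c_flank`, `residues`.
#' @export
make_window <- function(seq, p1_pos, flank = 10L) {
  if (flank < 1) abort("flank must be >= 1")
  s <- as_seq_input(seq)
  i <- match(p1_pos, s$numbering)
  if (is.na(i) || i >= nchar(s$seq)) {
    abort(paste0("P1 position ", p1_pos, " does not lie inside the sequence"))
  }
  # nearest break (or terminus) on each side; break b splits b | b+1, so a
  # P1 sitting on a break has nothing C-terminal of its bond
  if (i %in% s$breaks) {
    abort(paste0("no residues on the C-terminal side of the bond at ", p1_pos))
  }
  lo <- max(c(1L, s$breaks[s$breaks < i] + 1L))
  hi <- min(c(nchar(s$seq), s$breaks[s$breaks > i]))
  start <- max(lo, i - flank + 1L)
  end <- min(hi, i + flank)
  residues <- substr(s$seq, start, end)
  tibble(
    seq_id = s$id,
    p1_pos = p1_pos,
    start_pos = s$numbering[start],
    end_pos = s$numbering[end],
    n_flank = i - start + 1L,
    c_flank = end - i,
    residues = residues
  )
}

#' Windows for every site in a site table
#'
#' @param seq character string or one-row sequence tibble.
#' @param sites site tibble from [scan_sequence()] (uses `p1_pos`).
#' @param flank as in [make_window()].
#' @return tibble with one row per site.
#' @export
make_windows <- function(seq, sites, flank = 10L) {
  purrr::map_dfr(sites$p1_pos, function(p) make_window(seq, p, flank))
}

#' Write peptide windows to FASTA for docking
#'
#' Record ids encode the source sequence, the P1 position and the flank
#' counts, e.g. `Bb_346_n10c10` for the B-beta site at 346.
#'
#' @param windows tibble from [make_windows()].
#' @param path output FASTA path.
#' @param label optional per-window label; defaults to `seq_id`.
#' @return tibble of `id`, `seq` written, invisibly.
#' @export
windows_to_fasta <- function(windows, path, label = NULL) {
  if (nrow(windows) == 0) abort("windows must be non-empty")
  lab <- label %||% windows$seq_id
  ids <- sprintf("%s_%d_n%dc%d", lab, windows$p1_pos,
                 windows$n_flank, windows$c_flank)
  recs <- tibble(id = ids, seq = windows$residues)
  write_fasta(recs, path)
  invisible(recs)
}
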