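POSITION_TAGS <- c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'")
POSITION_OFFSETS <- setNames(c(-3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L), POSITION_TAGS)

#' Load a positional protease-specificity model
#'
#' A model is a set of evidence sources; each source constrains some of
#' the Schechter-Berger positions P4..P4' around the scissile (P1-P1')
#' bond with a set of allowed one-letter residues. Positions a source
#' does not mention are unconstrained for that source. Under the default
#' `any_source` combination a sequence position is a cleavage site as
#' soon as one source matches completely.
#'
#' @param config `NULL` for the bundled actinidin definition, a path to a
#'   YAML file with fields `name`, `combination` and `sources`, or an
#'   equivalent named list.
#' @return an object of class `specificity_model`.
#' @export
#' @examples
#' m <- load_specificity()
#' m$sources$insulin[["P2'"]]
load_specificity <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "actinidin.yaml", package = "fibrintools")
  }
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$sources) || length(cfg$sources) < 1) {
    abort("specificity config must declare at least one source")
  }
  combination <- tolower(cfg$combination %||% "any_source")
  if (!combination %in% c("any_source", "all_sources")) {
    abort(paste0("unknown combination rule: ", combination))
  }
  sources <- lapply(cfg$sources, function(src) {
    tags <- names(src)
    bad <- setdiff(tags, POSITION_TAGS)
    if (length(bad)) abort(paste0("unknown position tag: ", bad[1]))
    src <- lapply(src, function(v) {
      # unquoted T/F/Y/N in YAML arrive as logicals; map them back
      if (is.logical(v)) v <- ifelse(v, "T", "F")
      v <- toupper(as.character(v))
      badres <- setdiff(v, AA_LETTERS)
      if (length(badres)) abort(paste0("invalid residue letter: ", badres[1]))
      v
    })
    src
  })
  for (lab in names(sources)) {
    if (!all(c("P1", "P1'") %in% names(sources[[lab]]))) {
      abort(paste0("source '", lab, "' must constrain both P1 and P1'"))
    }
  }
  structure(
    list(name = cfg$name %||% "unnamed", combination = combination,
         sources = sources),
    class = "specificity_model"
  )
}

#' @export
print.specificity_model <- function(x, ...) {
  cat("<specificity_model>", x$name, "- combination:", x$combination, "\n")
  for (lab in names(x$sources)) {
    src <- x$sources[[lab]]
    cat("  ", lab, ": ", paste0(names(src), "={", vapply(src, paste,
        character(1), collapse = ""), "}", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# normalise the different sequence inputs to list(id, seq, numbering, breaks)
as_seq_input <- function(seq) {
  if (is.character(seq) && length(seq) == 1) {
    return(list(id = "seq", seq = toupper(seq),
                numbering = seq_len(nchar(seq)), breaks = integer()))
  }
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1) abort("expected a single sequence (one row)")
    numbering <- if ("numbering" %in% names(seq)) seq$numbering[[1]] else
      seq_len(nchar(seq$seq))
    breaks <- if ("breaks" %in% names(seq)) seq$breaks[[1]] else
      which(diff(numbering) != 1L)
    return(list(id = seq$id, seq = toupper(seq$seq),
                numbering = numbering, breaks = breaks))
  }
  abort("seq must be a character string or a one-row sequence tibble")
}

match_source_at <- function(residues, i, src, n, breaks) {
  # returns "match", "fail" or "indeterminate" for P1 at sequence index i
  offs <- POSITION_OFFSETS[names(src)]
  span <- i + range(offs)
  if (span[1] < 1 || span[2] > n) return("fail")
  # a numbering break after index b splits b | b+1; the tested span must
  # not straddle one
  if (any(breaks >= span[1] & breaks < span[2])) return("fail")
  indet <- FALSE
  for (tag in names(src)) {
    r <- residues[i + POSITION_OFFSETS[[tag]]]
    if (r == "X") { indet <- TRUE; next }
    if (!r %in% src[[tag]]) return("fail")
  }
  if (indet) "indeterminate" else "match"
}

#' Scan a sequence for predicted cleavage sites
#'
#' Tests every position P1 = i (scissile bond between i and i+1) against
#' each evidence source of the model. A source matches when every
#' position it constrains falls inside the sequence, does not cross a
#' recorded numbering break, and carries an allowed residue. Windows
#' containing `X` at a constrained position are reported as indeterminate
#' rather than matched.
#'
#' @param seq a character string, or a one-row tibble as produced by
#'   [extract_sequence()] / [read_fasta()].
#' @param model a `specificity_model`.
#' @return tibble of sites: `seq_id`, `p1_pos` (author numbering),
#'   `p1_res`, `p1prime_res`, `source`, `window` (the 8-residue P4..P4'
#'   context, `-` where outside the sequence). Positions that were
#'   indeterminate are in `attr(, "indeterminate")` (author numbering).
#' @export
scan_sequence <- function(seq, model) {
  s <- as_seq_input(seq)
  n <- nchar(s$seq)
  if (n < 2) abort("sequence must have length >= 2")
  residues <- strsplit(s$seq, "")[[1]]
  hits <- list()
  indeterminate <- integer()
  for (i in seq_len(n - 1L)) {
    verdicts <- vapply(model$sources, function(src)
      match_source_at(residues, i, src, n, s$breaks), character(1))
    matched <- if (model$combination == "any_source") {
      any(verdicts == "match")
    } else {
      all(verdicts == "match")
    }
    if (matched) {
      lab <- names(model$sources)[which(verdicts == "match")[1]]
      win_idx <- (i - 3L):(i + 4L)
      win <- ifelse(win_idx >= 1 & win_idx <= n, residues[pmax(pmin(win_idx, n), 1)], "-")
      hits[[length(hits) + 1L]] <- tibble(
        seq_id = s$id, p1_pos = s$numbering[i],
        p1_res = residues[i], p1prime_res = residues[i + 1L],
        source = lab, window = paste(win, collapse = "")
      )
    } else if (any(verdicts == "indeterminate")) {
      indeterminate <- c(indeterminate, s$numbering[i])
    }
  }
  out <- if (length(hits)) bind_rows(hits) else
    tibble(seq_id = character(), p1_pos = integer(), p1_res = character(),
           p1prime_res = character(), source = character(), window = character())
  out <- out[order(out$p1_pos), ]
  attr(out, "indeterminate") <- indeterminate
  out
}

#' Percent identity between two sequences
#'
#' Equal-length sequences are compared position by position. Unequal
#' lengths are first globally aligned (Needleman-Wunsch; match +1,
#' mismatch 0, linear gap -1; on score ties the traceback prefers a
#' residue pair, then a gap in `b`, then a gap in `a` - a deterministic
#' leftmost-gap rule). The identity denominator is the aligned length
#' including gap columns.
#'
#' @param a,b character strings or one-row sequence tibbles.
#' @return object of class `identity_report`: `percent` (1 decimal),
#'   `matches`, `aligned_length`, `mismatches` (tibble of 1-based aligned
#'   position, residue_a, residue_b), and the two aligned strings.
#' @export
#' @examples
#' pairwise_identity("ACDEFG", "ACDKFG")$percent # 83.3
pairwise_identity <- function(a, b) {
  sa <- as_seq_input(a); sb <- as_seq_input(b)
  if (nchar(sa$seq) == 0 || nchar(sb$seq) == 0) abort("empty sequence")
  ra <- strsplit(sa$seq, "")[[1]]
  rb <- strsplit(sb$seq, "")[[1]]
  if (length(ra) == length(rb)) {
    aln_a <- ra; aln_b <- rb
  } else {
    aln <- nw_align(ra, rb)
    aln_a <- aln$a; aln_b <- aln$b
  }
  L <- length(aln_a)
  is_match <- aln_a == aln_b & aln_a != "-"
  mism <- which(aln_a != aln_b & aln_a != "-" & aln_b != "-")
  structure(
    list(
      percent = round(100 * sum(is_match) / L, 1),
      matches = sum(is_match),
      aligned_length = L,
      mismatches = tibble(position = mism, residue_a = aln_a[mism],
                          residue_b = aln_b[mism]),
      aligned_a = paste(aln_a, collapse = ""),
      aligned_b = paste(aln_b, collapse = "")
    ),
    class = "identity_report"
  )
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("<identity_report> %.1f%% over %d aligned positions (%d mismatches)\n",
              x$percent, x$aligned_length, nrow(x$mismatches)))
  invisible(x)
}

nw_align <- function(ra, rb, match = 1, mismatch = 0, gap = -1) {
  n <- length(ra); m <- length(rb)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sub <- ifelse(ra[i] == rb, match, mismatch)
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j], S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  # traceback, tie order: diagonal > up (gap in b) > left (gap in a)
  i <- n; j <- m
  aa <- character(); ab <- character()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (ra[i] == rb[j]) match else mismatch)) {
      aa <- c(ra[i], aa); ab <- c(rb[j], ab); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      aa <- c(ra[i], aa); ab <- c("-", ab); i <- i - 1
    } else {
      aa <- c("-", aa); ab <- c(rb[j], ab); j <- j - 1
    }
  }
  list(a = aa, b = ab)
}

#' Assign structure chains to reference sequences
#'
#' Greedy best-score bijective assignment: repeatedly take the
#' (chain, reference) pair with the highest percent identity (ties broken
#' by chain id, then reference order), until chains or references are
#' exhausted. Chains whose best identity is below `min_identity` stay
#' unassigned with a warning.
#'
#' @param struct atom tibble.
#' @param references tibble with `id` and `seq` columns.
#' @param min_identity assignment floor, percent (default 30).
#' @return tibble `chain`, `ref_id` (NA if unassigned), `identity`.
#' @export
map_chains <- function(struct, references, min_identity = 30) {
  if (nrow(references) == 0) abort("references must be non-empty")
  chains <- sort(unique(struct$chain[!struct$hetero]))
  seqs <- lapply(chains, function(ch) extract_sequence(struct, ch))
  score <- matrix(0, length(chains), nrow(references),
                  dimnames = list(chains, references$id))
  for (i in seq_along(chains)) {
    for (j in seq_len(nrow(references))) {
      score[i, j] <- pairwise_identity(seqs[[i]], references[j, ])$percent
    }
  }
  res <- tibble(chain = chains, ref_id = NA_character_, identity = NA_real_)
  avail_c <- seq_along(chains); avail_r <- seq_len(nrow(references))
  while (length(avail_c) && length(avail_r)) {
    sub <- score[avail_c, avail_r, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    ci <- avail_c[best[1]]; rj <- avail_r[best[2]]
    if (score[ci, rj] < min_identity) break
    res$ref_id[ci] <- references$id[rj]
    res$identity[ci] <- score[ci, rj]
    avail_c <- setdiff(avail_c, ci); avail_r <- setdiff(avail_r, rj)
  }
  if (anyNA(res$ref_id)) {
    warn(paste0("unassigned chain(s) below ", min_identity, "% identity: ",
                paste(res$chain[is.na(res$ref_id)], collapse = ", ")))
  }
  res
}
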