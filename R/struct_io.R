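#' Read a PDB file into an atom tibble
#'
#' Parses ATOM/HETATM records by the fixed columns of PDB format v3.3.
#' MODEL/ENDMDL blocks become consecutive frame numbers in the `model`
#' column (a file without MODEL records is a single implicit model 1).
#' Insertion codes are preserved: residue identity throughout the package
#' is (chain, res_seq, ins), in author numbering.
#'
#' @param path path to a PDB file.
#' @param id structure identifier stored in the `"id"` attribute;
#'   defaults to the file name.
#' @return a tibble of class `pdb_tbl` with columns `model`, `serial`,
#'   `name`, `alt`, `res_name`, `chain`, `res_seq`, `ins`, `x`, `y`, `z`,
#'   `element`, `hetero`.
#' @export
read_pdb <- function(path, id = basename(path)) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_no <- 0L
  cur <- 1L
  seen_model <- FALSE
  models <- integer(length(lines))
  for (i in seq_along(lines)) {
    if (startsWith(rec[i], "MODEL")) {
      seen_model <- TRUE
      model_no <- model_no + 1L
      cur <- model_no
    }
    models[i] <- cur
  }
  keep <- rec == "ATOM  " | rec == "HETATM"
  if (!any(keep)) abort(paste0("no ATOM/HETATM records in ", path))
  al <- lines[keep]
  am <- models[keep]
  if (!seen_model) am <- rep(1L, length(al))

  num <- function(s, line_idx, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("malformed %s field in ATOM record at line %d: '%s'",
                    what, which(keep)[line_idx[bad[1]]], trimws(s[bad[1]])))
    }
    v
  }
  idx <- seq_along(al)
  out <- tibble(
    model = am,
    serial = as.integer(num(substr(al, 7, 11), idx, "serial")),
    name = trimws(substr(al, 13, 16)),
    alt = substr(al, 17, 17),
    res_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    res_seq = as.integer(num(substr(al, 23, 26), idx, "residue number")),
    ins = substr(al, 27, 27),
    x = num(substr(al, 31, 38), idx, "x coordinate"),
    y = num(substr(al, 39, 46), idx, "y coordinate"),
    z = num(substr(al, 47, 54), idx, "z coordinate"),
    element = trimws(substr(al, 77, 78)),
    hetero = substr(al, 1, 6) == "HETATM"
  )
  # fall back on the first letter of the atom name when the element
  # column is blank (common in minimised/docked files)
  blank <- out$element == ""
  if (any(blank)) {
    out$element[blank] <- substr(gsub("[^A-Za-z].*$", "", out$name[blank]), 1, 1)
  }
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("non-finite coordinates in PDB file")
  }
  structure(out, id = id, class = c("pdb_tbl", class(out)))
}

#' Write an atom tibble to a PDB file
#'
#' Inverse of [read_pdb()]: multi-model structures get MODEL/ENDMDL
#' blocks; coordinates are written with 3 decimals (the format's own
#' precision, and the round-trip tolerance).
#'
#' @param struct atom tibble as returned by [read_pdb()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  multi <- length(unique(struct$model)) > 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt_line <- function(a) {
    name <- a$name
    # atom-name column convention: 1-letter elements start in column 14
    pname <- if (nchar(name) < 4 && nchar(a$element) == 1) {
      formatC(paste0(" ", name), width = -4)
    } else {
      formatC(name, width = -4)
    }
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$hetero) "HETATM" else "ATOM", a$serial %% 100000L, pname,
            a$alt, a$res_name, a$chain, a$res_seq, a$ins,
            a$x, a$y, a$z, 1, 0, a$element)
  }
  for (m in sort(unique(struct$model))) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    sub <- struct[struct$model == m, ]
    writeLines(vapply(seq_len(nrow(sub)), function(i) fmt_line(sub[i, ]),
                      character(1)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are taken in author-numbering order from CA atoms of the
#' first model. Unknown residue codes become `X` with a warning. Jumps in
#' author numbering are recorded so downstream window logic never spans a
#' physical chain break.
#'
#' @param struct atom tibble.
#' @param chain_id single chain identifier.
#' @param model model number to use (default first).
#' @return one-row tibble with columns `id`, `seq` and list-columns
#'   `numbering` (author residue number per sequence position) and
#'   `breaks` (sequence indices after which the numbering jumps).
#' @export
extract_sequence <- function(struct, chain_id, model = min(struct$model)) {
  ca <- struct[struct$model == model & struct$chain == chain_id &
                 struct$name == "CA" & !struct$hetero, ]
  if (nrow(ca) == 0) abort(paste0("chain not present (no CA atoms): ", chain_id))
  ca <- ca[!duplicated(ca[, c("res_seq", "ins")]), ]
  ca <- ca[order(ca$res_seq, ca$ins), ]
  letters1 <- unname(AA3TO1[ca$res_name])
  if (anyNA(letters1)) {
    unk <- unique(ca$res_name[is.na(letters1)])
    warn(paste0("unknown residue code(s) mapped to 'X': ",
                paste(unk, collapse = ", ")))
    letters1[is.na(letters1)] <- "X"
  }
  numbering <- ca$res_seq
  brk <- which(diff(numbering) != 1L)
  tibble(
    id = paste0(attr(struct, "id") %||% "structure", "_", chain_id),
    chain = chain_id,
    seq = paste(letters1, collapse = ""),
    numbering = list(numbering),
    breaks = list(brk)
  )
}

#' Read a FASTA file
#'
#' @param path FASTA file; arbitrary line wrapping is accepted.
#' @return tibble with columns `id` (first word of the header) and `seq`.
#'   Duplicate ids or empty sequences are errors; an empty file gives a
#'   zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) return(tibble(id = character(), seq = character()))
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- as.character(set)
  if (any(seqs == "")) {
    abort(paste0("empty sequence for record: ", ids[which(seqs == "")[1]]))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param records tibble with `id` and `seq` columns.
#' @param path output path; sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (anyDuplicated(records$id)) {
    abort(paste0("duplicate FASTA id: ", records$id[duplicated(records$id)][1]))
  }
  set <- Biostrings::AAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Select atoms from a structure
#'
#' Convenience filter on the atom tibble; `NULL` arguments are
#' unconstrained.
#'
#' @param struct atom tibble.
#' @param chain,res_seq,name,element,model optional filters (vectors allowed).
#' @return the matching rows.
#' @export
atom_select <- function(struct, chain = NULL, res_seq = NULL, name = NULL,
                        element = NULL, model = NULL) {
  out <- struct
  if (!is.null(model)) out <- out[out$model %in% model, ]
  if (!is.null(chain)) out <- out[out$chain %in% chain, ]
  if (!is.null(res_seq)) out <- out[out$res_seq %in% res_seq, ]
  if (!is.null(name)) out <- out[out$name %in% name, ]
  if (!is.null(element)) out <- out[out$element %in% element, ]
  out
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
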