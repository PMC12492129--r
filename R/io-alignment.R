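# FASTA amino-acid alignments, via Biostrings

ALN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Read a FASTA multiple amino-acid alignment
#'
#' All records must share one length (the alignment width); the alphabet is
#' the 20 standard amino acids plus the gap character `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `sequence`, plus attribute
#'   `n_columns` (the alignment width).
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) abort("empty alignment: no FASTA records")
  # validate before parsing: the backend silently drops illegal codes
  seq_text <- toupper(paste(raw[!startsWith(raw, ">")], collapse = ""))
  bad <- setdiff(unique(strsplit(seq_text, "")[[1]]), ALN_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("illegal alignment character(s): ", paste(bad, collapse = " ")))
  }
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("FASTA parse error: ", conditionMessage(e)))
  )
  if (length(seqs) == 0) abort("empty alignment: no FASTA records")
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "ragged alignment: sequence lengths %s differ",
      paste(unique(lens), collapse = ", ")
    ))
  }
  txt <- toupper(as.character(seqs))
  out <- tibble(id = names(seqs), sequence = unname(txt))
  attr(out, "n_columns") <- unique(lens)
  out
}

#' Write a FASTA alignment
#'
#' @param alignment A tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  x <- Biostrings::AAStringSet(setNames(alignment$sequence, alignment$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Number of columns in an alignment
#' @param alignment Result of [read_fasta_alignment()].
#' @return Integer alignment width.
#' @export
alignment_width <- function(alignment) {
  w <- attr(alignment, "n_columns")
  if (is.null(w)) w <- unique(nchar(alignment$sequence))
  if (length(w) != 1) abort("ragged alignment")
  as.integer(w)
}

#' Map ungapped residue positions to 1-based alignment columns
#'
#' @param row One gapped alignment row (character scalar).
#' @return Integer vector: element `i` is the alignment column of the `i`-th
#'   non-gap residue.
#' @export
alignment_column_map <- function(row) {
  chars <- strsplit(row, "")[[1]]
  which(chars != "-")
}
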