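#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that returns sequences
#' in the package's canonical tabular form: one row per record, uppercase
#' residues over the alphabet A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (uppercase residue string).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  txt <- readLines(path, warn = FALSE)
  if (!any(startsWith(txt, ">"))) {
    abort(paste0("not FASTA (no '>' header line) in ", path))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    abort(paste0("empty FASTA: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(as.character(set))
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad) > 0) {
    # DNAStringSet already admits IUPAC ambiguity codes; we restrict further
    abort(paste0(
      "non-ACGTN residues in record(s): ", paste(ids[bad], collapse = ", ")
    ))
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param records A tibble with columns `id` and `seq` (as from
#'   [read_fasta()]), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- tibble(id = names(records), seq = unname(records))
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (nrow(records) == 0) abort("no records to write")
  set <- Biostrings::DNAStringSet(toupper(records$seq))
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Reverse complement of a plain character vector of DNA strings.
# Goes through Biostrings so the complement table is the canonical one.
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# split a sequence string into a character vector of single residues
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}
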