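#' Vertebrate mitochondrial genetic code
#'
#' Returns the genetic code used throughout the package as a list with the
#' codon-to-amino-acid map, the start- and stop-codon sets, and the
#' synonymous-family assignment used for RSCU.  The default is NCBI
#' translation table 2 (vertebrate mitochondrial), under which ATA encodes
#' Met, TGA encodes Trp, and AGA/AGG are termination codons -- the code in
#' force for avian mitochondrial protein-coding genes.
#'
#' Synonymous families group sense codons that encode the same amino acid,
#' except that the six leucine codons are split into the four-fold CTN family
#' (`Leu`) and the two-fold TTR family (`Leu2`), and serine into TCN (`Ser`)
#' and AGY (`Ser2`), following the usual presentation of mitochondrial codon
#' usage.  Stop codons carry family `Stop` and are excluded from RSCU.
#'
#' @param id NCBI genetic-code table identifier passed to
#'   [Biostrings::getGeneticCode()]. Default `"2"`.
#' @return A list of class `genetic_code` with elements `id`, `codons`
#'   (the 64 codons), `aa` (named character, codon to one-letter amino acid,
#'   `*` for stop), `starts`, `stops`, and `family` (named character,
#'   codon to synonymous-family label).
#' @examples
#' code <- mito_genetic_code()
#' code$aa[["ATA"]]   # "M" under the mitochondrial code
#' code$stops         # TAA TAG AGA AGG
#' @export
mito_genetic_code <- function(id = "2") {
  key <- paste0("genetic_code_", id)
  if (!is.null(.mitochar_cache[[key]])) {
    return(.mitochar_cache[[key]])
  }
  aa <- Biostrings::getGeneticCode(id)
  aa <- setNames(as.character(aa), names(aa))
  stops <- names(aa)[aa == "*"]
  fam <- vapply(names(aa), function(codon) {
    a <- aa[[codon]]
    if (a == "*") return("Stop")
    if (a == "L") {
      return(if (startsWith(codon, "CT")) "Leu" else "Leu2")
    }
    if (a == "S") {
      return(if (startsWith(codon, "TC")) "Ser" else "Ser2")
    }
    aa_three(a)
  }, character(1))
  code <- structure(
    list(
      id = id,
      codons = names(aa),
      aa = aa,
      starts = c("ATG", "GTG"),
      stops = stops,
      family = fam
    ),
    class = "genetic_code"
  )
  stopifnot(length(code$aa) == 64, !any(code$starts %in% code$stops))
  .mitochar_cache[[key]] <- code
  code
}

# one-letter -> three-letter amino-acid labels (for family names / plots)
aa_three <- function(a) {
  map <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val", `*` = "Stop"
  )
  unname(map[a])
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$id, "\n")
  cat("  starts:", paste(x$starts, collapse = " "), "\n")
  cat("  stops: ", paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

translate_codons <- function(codons, code = mito_genetic_code()) {
  unname(code$aa[codons])
}
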