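#' Codon profile of a single coding sequence
#'
#' Splits a coding-strand CDS into complete codons plus an incomplete tail
#' of 0-2 residues.  Mitochondrial CDSs frequently end on such a tail: the
#' termination codon is completed by post-transcriptional polyadenylation
#' and is conventionally printed as `T--` or `TA-`.
#'
#' @param cds A coding-strand sequence string, length >= 3.
#' @param gene Gene label.
#' @param code A [mito_genetic_code()].
#' @return A list of class `cds_codon_profile`: `gene`, `codons` (character
#'   vector of complete codons), `start_codon`, `stop_codon` (a stop 3-mer,
#'   an incomplete token `T--`/`TA-`, or `none`), `start_canonical` (is the
#'   start in the code's start set?), `incomplete_tail` (0-2 residues).
#' @export
cds_codon_profile <- function(cds, gene = "cds", code = mito_genetic_code()) {
  stopifnot(is.character(cds), length(cds) == 1)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3) abort("CDS shorter than one codon")
  ncod <- n %/% 3
  codons <- substring(cds, seq(1, 3 * ncod, by = 3), seq(3, 3 * ncod, by = 3))
  tail_res <- if (n %% 3 > 0) substr(cds, 3 * ncod + 1, n) else ""
  last <- codons[ncod]
  stop_codon <- if (last %in% code$stops) {
    last
  } else if (tail_res == "T") {
    "T--"
  } else if (tail_res == "TA") {
    "TA-"
  } else {
    "none"
  }
  structure(
    list(
      gene = gene,
      codons = codons,
      start_codon = codons[1],
      stop_codon = stop_codon,
      start_canonical = codons[1] %in% code$starts,
      incomplete_tail = tail_res
    ),
    class = "cds_codon_profile"
  )
}

#' Classify the start and stop codon of a CDS
#'
#' @inheritParams cds_codon_profile
#' @return A one-row tibble: `gene`, `start_codon`, `start_canonical`,
#'   `stop_codon` (stop 3-mer, incomplete `T--`/`TA-` token, or `none`).
#' @examples
#' start_stop_classify("GTGAAATAA")             # GTG start (canonical), TAA stop
#' start_stop_classify(paste0("ATGAAACCC", "T")) # incomplete stop "T--"
#' @export
start_stop_classify <- function(cds, gene = "cds", code = mito_genetic_code()) {
  p <- cds_codon_profile(cds, gene, code)
  tibble(
    gene = p$gene,
    start_codon = p$start_codon,
    start_canonical = p$start_canonical,
    stop_codon = p$stop_codon
  )
}

#' Tally codon usage over coding sequences
#'
#' Counts every complete codon (including complete termination codons) of
#' one or more coding-strand CDSs under the given genetic code; incomplete
#' 1-2 nt tails are excluded, so the total equals the sum of
#' `floor(length/3)` over the input.
#'
#' @param cds A character vector of coding-strand CDSs, or a data frame with
#'   a `seq` column.
#' @param code A [mito_genetic_code()].
#' @return A 64-row tibble of class `codon_usage`: `codon`, `amino_acid`,
#'   `family` (synonymous family label, `Stop` for terminators), `count`.
#'   `sum(count)` is the total codon count.
#' @examples
#' tab <- codon_tally("ATGTAA")
#' sum(tab$count)  # 2
#' @export
codon_tally <- function(cds, code = mito_genetic_code()) {
  if (is.data.frame(cds)) cds <- cds$seq
  stopifnot(is.character(cds), length(cds) >= 1)
  all_codons <- unlist(lapply(cds, function(s) {
    cds_codon_profile(s, code = code)$codons
  }))
  bad <- grepl("[^ACGT]", all_codons)
  counts <- table(factor(all_codons[!bad], levels = code$codons))
  tibble(
    codon = code$codons,
    amino_acid = unname(code$aa),
    family = unname(code$family),
    count = as.integer(counts)
  ) |>
    structure(class = c("codon_usage", class(tibble())))
}

#' Relative synonymous codon usage
#'
#' Adds the RSCU column to a [codon_tally()] table.  Within each synonymous
#' family of sense codons, `RSCU(c) = count(c) / (family total / family
#' size)`: the observed count divided by the count expected under uniform
#' usage, so RSCU sums to the family size whenever the family is used.
#' Termination codons are not part of any family and get `NA`; families with
#' zero total get RSCU 0 for all members and `family_used = FALSE`.
#'
#' @param table A `codon_usage` tibble from [codon_tally()].
#' @return The table with `rscu` and `family_used` columns.
#' @export
rscu <- function(table) {
  stopifnot(all(c("codon", "family", "count") %in% names(table)))
  out <- table |>
    group_by(.data$family) |>
    mutate(
      family_used = sum(.data$count) > 0,
      rscu = dplyr::case_when(
        family == "Stop" ~ NA_real_,
        !family_used ~ 0,
        TRUE ~ .data$count / (sum(.data$count) / n())
      )
    ) |>
    ungroup()
  out$family_used[out$family == "Stop"] <- NA
  structure(out, class = c("codon_usage", class(tibble())))
}

#' Amino-acid usage from a codon table
#'
#' @param table A `codon_usage` tibble.
#' @return A tibble `amino_acid`, `count`, sense codons only.
#' @export
amino_acid_usage <- function(table) {
  table |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$amino_acid) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count))
}
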