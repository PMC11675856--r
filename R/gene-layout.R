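#' Circular adjacency ledger of intergenic spacers and overlaps
#'
#' Walks the features of a genome in start order and reports, for every
#' ordered adjacent pair (including the closing last-to-first pair on a
#' circular genome), the signed intergenic spacer
#' `igs = downstream_start - upstream_end - 1` on the deposited-strand
#' coordinate (wrapped modulo the genome length for the closing pair):
#' positive values are gaps in nucleotides, negative values are overlaps,
#' zero means abutting genes.  This is the convention of published
#' mitogenome annotation tables, which mix strands in a single coordinate
#' ledger.
#'
#' The ledger satisfies the closure identity
#' `sum(feature lengths) + sum(igs) == genome length` exactly on any
#' circular genome whose features do not doubly cover a position.
#'
#' @param genome A `mito_genome` (sequence optional; overlap motifs are only
#'   extracted when a sequence is present).
#' @return A tibble with one row per adjacent pair: `upstream`,
#'   `downstream`, `igs`, and `overlap_motif` (the shared H-strand
#'   subsequence when `igs < 0`, otherwise `NA`).
#' @examples
#' g <- read_feature_table(pheasant_feature_table())
#' ledger <- adjacency_ledger(g)
#' ledger[ledger$upstream == "ATP8", ]  # 10-bp ATP8/ATP6 overlap: igs -10
#' @export
adjacency_ledger <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  feats <- genome$features
  if (nrow(feats) < 2) abort("need at least two features for a ledger")
  if (is.unsorted(feats$start)) abort("features must be sorted by start")
  L <- genome$length
  n <- nrow(feats)
  # linearized end (start + length - 1) handles origin-wrapping features
  end_eff <- feats$start + feats$length - 1L
  if (genome$circular) {
    down <- c(2:n, 1L)
    down_start <- feats$start[down]
    down_start[n] <- down_start[n] + L
  } else {
    down <- 2:n
    down_start <- feats$start[down]
    end_eff <- end_eff[1:(n - 1)]
  }
  up_idx <- if (genome$circular) 1:n else 1:(n - 1)
  igs <- as.integer(down_start - end_eff - 1L)
  ledger <- tibble(
    upstream = feats$gene[up_idx],
    downstream = feats$gene[down],
    igs = igs,
    overlap_motif = NA_character_
  )
  if (!is.null(genome$seq)) {
    for (k in which(igs < 0)) {
      ledger$overlap_motif[k] <- overlap_motif(genome, ledger[k, ])
    }
  }
  ledger
}

#' Extract the shared sequence of an overlapping gene pair
#'
#' For a ledger row with `igs < 0`, returns the overlap region -- the
#' H-strand (deposited) subsequence shared by the two features, 5' to 3' on
#' the deposited strand.  Its length equals `-igs`.
#'
#' @param genome A `mito_genome` with a sequence.
#' @param record A one-row ledger tibble (see [adjacency_ledger()]) with
#'   `upstream`, `downstream`, `igs`.
#' @return A character string of length `-igs`.
#' @export
overlap_motif <- function(genome, record) {
  stopifnot(inherits(genome, "mito_genome"), nrow(record) == 1)
  if (is.null(genome$seq)) abort("genome has no sequence")
  if (record$igs >= 0) abort("pair does not overlap (igs >= 0)")
  up <- resolve_feature(genome, record$upstream)
  down <- resolve_feature(genome, record$downstream)
  L <- genome$length
  from <- ((down$start - 1L) %% L) + 1L
  to_lin <- down$start - record$igs - 1L      # = upstream effective end
  to <- ((to_lin - 1L) %% L) + 1L
  extract_interval(genome$seq, from, to, genome$circular)
}

#' Conserved columns of an alignment
#'
#' Marks alignment columns carrying a single residue state across all
#' sequences (a gap character counts as a state of its own), the usual
#' definition behind the `*` conservation row of pairwise/multiple alignment
#' displays.
#'
#' @param aligned A character vector of two or more equal-length aligned
#'   sequences.
#' @return A logical vector, one element per column, `TRUE` where the column
#'   is invariant.
#' @export
conserved_sites <- function(aligned) {
  if (length(aligned) < 2) abort("need at least two sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) abort("ragged alignment (unequal lengths)")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  apply(mat, 2, function(col) length(unique(col)) == 1)
}

#' Classify base pairs of an RNA secondary structure
#'
#' Given a sequence and a list of paired positions (for a tRNA, annotated
#' with the arm each pair belongs to), classifies every pair exactly once as
#' Watson-Crick (A-U or G-C), G-U wobble, or a named mismatch (e.g. U-U,
#' A-C).  DNA input is read as RNA: T is treated as U, and classification is
#' orientation-insensitive (G-U and U-G are one class).
#'
#' @param seq A sequence string.
#' @param pairs A data frame with columns `i`, `j` (1-based paired
#'   positions) and optionally `arm` (e.g. `acceptor`, `DHU`, `anticodon`,
#'   `TpsiC`); a single `structure` arm is assumed when absent.
#' @return A tibble `arm`, `pair_class`, `count`; counts sum to
#'   `nrow(pairs)`.
#' @examples
#' pairing_stats("GATC", data.frame(i = 1, j = 4, arm = "acceptor"))
#' @export
pairing_stats <- function(seq, pairs) {
  stopifnot(is.character(seq), length(seq) == 1)
  pairs <- as_tibble(pairs)
  if (!all(c("i", "j") %in% names(pairs))) abort("pairs need columns i, j")
  if (!"arm" %in% names(pairs)) pairs$arm <- "structure"
  v <- seq_chars(toupper(seq))
  n <- length(v)
  if (any(pairs$i < 1 | pairs$i > n | pairs$j < 1 | pairs$j > n)) {
    abort("paired position out of range")
  }
  if (any(pairs$i == pairs$j)) abort("a position cannot pair with itself")
  as_rna <- function(b) ifelse(b == "T", "U", b)
  b1 <- as_rna(v[pairs$i])
  b2 <- as_rna(v[pairs$j])
  lo <- pmin(b1, b2)
  hi <- pmax(b1, b2)
  cls <- dplyr::case_when(
    (lo == "A" & hi == "U") | (lo == "C" & hi == "G") ~ "Watson-Crick",
    lo == "G" & hi == "U" ~ "G-U wobble",
    TRUE ~ paste0(lo, "-", hi, " mismatch")
  )
  tibble(arm = pairs$arm, pair_class = cls) |>
    dplyr::count(.data$arm, .data$pair_class, name = "count")
}
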