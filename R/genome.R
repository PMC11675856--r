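feature_types <- c("PCG", "tRNA", "rRNA", "control_region")

#' Construct an annotated mitogenome
#'
#' Bundles a (usually circular) nucleotide sequence with an ordered feature
#' table.  Coordinates are 1-based inclusive, exactly as printed in standard
#' mitogenome annotation tables; features whose `end` is smaller than their
#' `start` wrap around the origin and are legal only on a circular genome.
#' Strands are labelled `H` (heavy, the deposited strand) and `L` (light);
#' `+`/`-` are accepted as aliases on input.
#'
#' @param seq Genome sequence as a single uppercase string over A,C,G,T,N, or
#'   `NULL` for a layout-only genome (composition and extraction unavailable).
#' @param features A data frame with columns `gene`, `type` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control_region`), `strand` (`H`/`L`), `start`, `end`.
#'   Extra columns are preserved.
#' @param circular Is the genome circular? Default `TRUE` (mitogenome).
#' @param id Genome label.
#' @param length Genome length; defaults to `nchar(seq)` or, for layout-only
#'   genomes, the maximum feature `end`.
#' @return An object of class `mito_genome`: a list with elements `id`,
#'   `seq`, `length`, `circular`, and `features` (a tibble sorted by `start`,
#'   with a computed `length` column).
#' @examples
#' g <- annotated_genome(
#'   "ACGTACGTAA",
#'   data.frame(gene = "g1", type = "PCG", strand = "H", start = 2, end = 7)
#' )
#' g$features
#' @export
annotated_genome <- function(seq, features, circular = TRUE, id = "genome",
                             length = NULL) {
  if (!is.null(seq)) {
    stopifnot(is.character(seq), length(seq) == 1)
    seq <- toupper(seq)
    if (nchar(seq) == 0) abort("genome sequence is empty")
    if (grepl("[^ACGTN]", seq)) abort("genome sequence has non-ACGTN residues")
    glen <- nchar(seq)
    if (!is.null(length) && length != glen) {
      abort("`length` disagrees with nchar(seq)")
    }
  } else {
    glen <- length
  }
  features <- as_tibble(features)
  required <- c("gene", "type", "strand", "start", "end")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  features$strand <- c(`+` = "H", `-` = "L", H = "H", L = "L")[features$strand]
  if (anyNA(features$strand)) abort("unknown strand symbol (use H/L or +/-)")
  bad_type <- setdiff(unique(features$type), feature_types)
  if (length(bad_type) > 0) {
    abort(paste0("unknown feature type(s): ", paste(bad_type, collapse = ", ")))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (is.null(glen)) glen <- max(features$end)
  if (any(features$start < 1 | features$start > glen |
            features$end < 1 | features$end > glen)) {
    abort("feature coordinates out of range [1, genome length]")
  }
  wraps <- features$end < features$start
  if (any(wraps) && !circular) {
    abort("wrap-around feature on a linear genome")
  }
  features <- arrange(features, .data$start)
  features$length <- feature_length(features$start, features$end, glen)
  dup <- features |>
    group_by(.data$gene) |>
    filter(n() > 1) |>
    ungroup()
  if (nrow(dup) > 0) {
    # duplicate names are legal (e.g. two leucine tRNAs) unless they overlap
    for (g in unique(dup$gene)) {
      rows <- dup[dup$gene == g, ]
      if (any(rows$start[-1] <= rows$end[-nrow(rows)])) {
        abort(paste0("overlapping features share the name: ", g))
      }
    }
  }
  structure(
    list(id = id, seq = seq, length = as.integer(glen),
         circular = isTRUE(circular), features = features),
    class = "mito_genome"
  )
}

# coordinate-derived feature length, honouring circular wrap (end < start)
feature_length <- function(start, end, genome_length) {
  ifelse(end >= start, end - start + 1L,
         (genome_length - start + 1L) + end)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$id, ": ", x$length, " bp, ",
      nrow(x$features), " features",
      if (x$circular) " (circular)" else " (linear)",
      if (is.null(x$seq)) ", layout-only" else "", "\n", sep = "")
  print(x$features, n = 5)
  invisible(x)
}

#' Read a tab-delimited feature table
#'
#' Parses an annotation table with columns `gene`, `type`, `strand`, `start`,
#' `end` (1-based inclusive; extra columns kept) into a [annotated_genome()].
#' Typographic minus signs (U+2212) and thousands separators in coordinates
#' are normalized on ingestion.
#'
#' @param path Path to a TSV file.
#' @param seq Optional genome sequence string; when absent the genome length
#'   is taken as the maximum feature `end` and the genome is layout-only.
#' @param circular,id Passed to [annotated_genome()].
#' @return A `mito_genome`.
#' @export
read_feature_table <- function(path, seq = NULL, circular = TRUE,
                               id = basename(path)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (nrow(tab) == 0) abort(paste0("empty feature table: ", path))
  for (col in c("start", "end")) {
    if (is.character(tab[[col]])) {
      tab[[col]] <- as.integer(gsub("[,−]", "", tab[[col]]))
    }
  }
  annotated_genome(seq, tab, circular = circular, id = id)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: emits `gene`, `type`, `strand`,
#' `start`, `end` plus any extra columns carried on the feature tibble
#' (the computed `length` column is dropped).
#'
#' @param genome A `mito_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  stopifnot(inherits(genome, "mito_genome"))
  tab <- select(genome$features, -"length")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Extract a feature's sequence from a genome
#'
#' Returns the feature's sequence on its coding strand: H-strand features are
#' the subsequence as deposited, L-strand features are reverse complemented.
#' Features wrapping the origin (`end < start`) are supported on circular
#' genomes.
#'
#' @param genome A `mito_genome` with a sequence.
#' @param feature A feature: a gene name (must be unique in the table), a row
#'   index into `genome$features`, or a one-row data frame with `strand`,
#'   `start`, `end`.
#' @param as_deposited If `TRUE`, return the H-strand subsequence even for
#'   L-strand features.
#' @return A single character string.
#' @examples
#' g <- annotated_genome(
#'   "ACGTAC",
#'   data.frame(gene = "f", type = "tRNA", strand = "L", start = 1, end = 3)
#' )
#' extract_feature_sequence(g, "f")  # reverse complement of "ACG"
#' @export
extract_feature_sequence <- function(genome, feature, as_deposited = FALSE) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.null(genome$seq)) abort("genome has no sequence")
  feat <- resolve_feature(genome, feature)
  s <- extract_interval(genome$seq, feat$start, feat$end, genome$circular)
  if (!as_deposited && feat$strand == "L") s <- revcomp(s)
  s
}

resolve_feature <- function(genome, feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1)
    return(feature)
  }
  if (is.numeric(feature)) {
    return(genome$features[feature, ])
  }
  hit <- genome$features[genome$features$gene == feature, ]
  if (nrow(hit) == 0) abort(paste0("no feature named: ", feature))
  if (nrow(hit) > 1) abort(paste0("feature name is ambiguous: ", feature))
  hit
}

# substring honouring circular wrap
extract_interval <- function(seq, start, end, circular) {
  n <- nchar(seq)
  if (start < 1 || end < 1 || start > n || end > n) {
    abort("interval out of range")
  }
  if (end >= start) {
    substr(seq, start, end)
  } else {
    if (!circular) abort("wrap-around interval on a linear genome")
    paste0(substr(seq, start, n), substr(seq, 1, end))
  }
}

#' Bundled annotation fixtures
#'
#' `pheasant_feature_table()` returns the path to the bundled ring-necked
#' pheasant (*Phasianus colchicus*) mitogenome annotation shipped with the
#' package: 38 features (13 protein-coding genes, 22 tRNAs, 2 rRNAs, and the
#' control region) over a 16,696 bp circular genome, together with the
#' published per-row sizes, intergenic-spacer (IGS) values, and start/stop
#' codons in `size_printed`, `igs_printed`, `start_codon`, `stop_codon`
#' columns.  `pheasant_composition_table()` returns the path to the matching
#' published per-partition nucleotide composition table (percentages and
#' AT/GC skews).
#'
#' @return A file path.
#' @examples
#' g <- read_feature_table(pheasant_feature_table())
#' nrow(g$features)  # 38
#' @export
pheasant_feature_table <- function() {
  system.file("extdata", "pcolchicus_table1.tsv", package = "mitochar",
              mustWork = TRUE)
}

#' @rdname pheasant_feature_table
#' @export
pheasant_composition_table <- function() {
  system.file("extdata", "pcolchicus_table2_composition.tsv",
              package = "mitochar", mustWork = TRUE)
}
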