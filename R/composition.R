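#' Strand skew
#'
#' The strand-asymmetry statistic `(x - y) / (x + y)`, used with `x = A,
#' y = T` counts or percentages for the AT skew and `x = G, y = C` for the
#' GC skew.  Being a ratio it is invariant to whether counts or percentages
#' are supplied.  Antisymmetric: `skew(x, y) == -skew(y, x)`.
#'
#' @param x,y Non-negative counts or percentages (vectorized).
#' @return `(x - y)/(x + y)`, with `NA_real_` (an undefined-skew sentinel,
#'   not an error) wherever `x + y == 0`.
#' @examples
#' skew(30.61, 25.26)  # AT skew of a pheasant mitogenome, 0.0958
#' skew(13.28, 30.85)  # GC skew, -0.3981
#' @export
skew <- function(x, y) {
  out <- (x - y) / (x + y)
  out[(x + y) == 0] <- NA_real_
  out
}

# tabulate A/C/G/T over non-N residues of a single sequence string
count_bases <- function(s) {
  v <- seq_chars(s)
  c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"), T = sum(v == "T"))
}

#' Nucleotide composition of a sequence
#'
#' Percentages of A, T, C, G over the non-N residues of a sequence, with the
#' derived A+T and G+C contents and the AT/GC strand skews
#' (`AT skew = (A - T)/(A + T)`, `GC skew = (G - C)/(G + C)`).
#'
#' @param seq A single sequence string (A/C/G/T/N), or a `mito_genome`
#'   (whose deposited-strand sequence is used).
#' @param partition Label for the `partition` column of the result.
#' @return A one-row tibble: `partition`, `n_sites` (non-N residues),
#'   `pct_a`, `pct_t`, `pct_c`, `pct_g`, `pct_at`, `pct_gc`, `at_skew`,
#'   `gc_skew`.  Values are unrounded; see [round_composition()] for the
#'   conventional report precision.
#' @examples
#' base_composition("AATT")  # 50% A, 50% T, AT skew 0
#' @export
base_composition <- function(seq, partition = "sequence") {
  if (inherits(seq, "mito_genome")) {
    if (is.null(seq$seq)) abort("genome has no sequence")
    seq <- seq$seq
  }
  stopifnot(is.character(seq), length(seq) == 1)
  cnt <- count_bases(toupper(seq))
  n <- sum(cnt)
  if (n == 0) abort("sequence has no A/C/G/T residues")
  pct <- 100 * cnt / n
  tibble(
    partition = partition,
    n_sites = n,
    pct_a = pct[["A"]], pct_t = pct[["T"]],
    pct_c = pct[["C"]], pct_g = pct[["G"]],
    pct_at = pct[["A"]] + pct[["T"]],
    pct_gc = pct[["G"]] + pct[["C"]],
    at_skew = skew(cnt[["A"]], cnt[["T"]]),
    gc_skew = skew(cnt[["G"]], cnt[["C"]])
  )
}

#' Round a composition report to conventional precision
#'
#' Percentages to 2 decimal places and skews to 4, matching the usual
#' presentation of mitogenome composition tables.  Raw values should be kept
#' for further arithmetic; rounding is a report-layer operation.
#'
#' @param report A tibble as returned by [base_composition()] or
#'   [partition_report()].
#' @return The tibble with rounded columns.
#' @export
round_composition <- function(report) {
  pct_cols <- intersect(
    c("pct_a", "pct_t", "pct_c", "pct_g", "pct_at", "pct_gc"), names(report))
  skew_cols <- intersect(c("at_skew", "gc_skew"), names(report))
  report[pct_cols] <- lapply(report[pct_cols], round, digits = 2)
  report[skew_cols] <- lapply(report[skew_cols], round, digits = 4)
  report
}

#' Default partition specifications for a standard mitogenome
#'
#' Builds the partition list conventionally reported for vertebrate
#' mitogenomes: the whole genome; the concatenated protein-coding genes
#' (PCGs) and their three codon positions; the concatenated tRNAs and rRNAs;
#' the individual rRNAs (any gene whose name contains `12S` or `16S`); the
#' control region; and, when `cr_domains` is supplied, its three domains.
#'
#' @param genome A `mito_genome`.
#' @param cr_domains Optional tibble with columns `domain`, `start`, `end`
#'   giving control-region-local 1-based inclusive domain intervals (as from
#'   [segment_domains()]).
#' @return A named list of partition specs understood by
#'   [partition_report()].  Each spec is a list with a `kind` field:
#'   `whole`, `types` (concatenate features of given types), `genes`
#'   (concatenate named genes), `codon_pos` (a codon position of the PCG
#'   concatenation), or `cr_slice` (a CR-local interval).
#' @export
default_partition_specs <- function(genome, cr_domains = NULL) {
  feats <- genome$features
  specs <- list(Mitogenome = list(kind = "whole"))
  if (any(feats$type == "PCG")) {
    specs$PCGs <- list(kind = "types", types = "PCG")
    specs[["PCG-1st"]] <- list(kind = "codon_pos", pos = 1)
    specs[["PCG-2nd"]] <- list(kind = "codon_pos", pos = 2)
    specs[["PCG-3rd"]] <- list(kind = "codon_pos", pos = 3)
  }
  if (any(feats$type == "tRNA")) specs$tRNA <- list(kind = "types", types = "tRNA")
  if (any(feats$type == "rRNA")) specs$rRNA <- list(kind = "types", types = "rRNA")
  for (tag in c("12S", "16S")) {
    hit <- feats$gene[grepl(tag, feats$gene, fixed = TRUE)]
    if (length(hit) == 1) {
      specs[[paste(tag, "rRNA")]] <- list(kind = "genes", genes = hit)
    }
  }
  if (any(feats$type == "control_region")) {
    specs$CR <- list(kind = "types", types = "control_region")
    if (!is.null(cr_domains)) {
      for (i in seq_len(nrow(cr_domains))) {
        specs[[paste0("CR-Domain ", cr_domains$domain[i])]] <-
          list(kind = "cr_slice",
               start = cr_domains$start[i], end = cr_domains$end[i])
      }
    }
  }
  specs
}

# materialize the sequence of one partition spec
partition_seq <- function(genome, spec, strand_policy) {
  feats <- genome$features
  coding <- identical(strand_policy, "coding")
  grab <- function(rows) {
    paste(vapply(seq_len(nrow(rows)), function(i) {
      extract_feature_sequence(genome, rows[i, ], as_deposited = !coding)
    }, character(1)), collapse = "")
  }
  switch(spec$kind,
    whole = genome$seq,
    types = {
      rows <- feats[feats$type %in% spec$types, ]
      if (nrow(rows) == 0) abort("partition matches no feature")
      grab(rows)
    },
    genes = {
      rows <- feats[feats$gene %in% spec$genes, ]
      if (nrow(rows) == 0) {
        abort(paste0("partition names missing gene(s): ",
                     paste(spec$genes, collapse = ", ")))
      }
      grab(rows)
    },
    codon_pos = {
      rows <- feats[feats$type == "PCG", ]
      if (nrow(rows) == 0) abort("no protein-coding genes for codon partition")
      pieces <- vapply(seq_len(nrow(rows)), function(i) {
        # codon-position slices always use the coding strand
        cds <- extract_feature_sequence(genome, rows[i, ])
        ncod <- nchar(cds) %/% 3    # incomplete trailing codon excluded
        if (ncod == 0) return("")
        v <- seq_chars(substr(cds, 1, 3 * ncod))
        paste(v[seq(spec$pos, 3 * ncod, by = 3)], collapse = "")
      }, character(1))
      paste(pieces, collapse = "")
    },
    cr_slice = {
      rows <- feats[feats$type == "control_region", ]
      if (nrow(rows) != 1) abort("CR slice needs exactly one control region")
      cr <- extract_feature_sequence(genome, rows[1, ])
      substr(cr, spec$start, spec$end)
    },
    abort(paste0("unknown partition kind: ", spec$kind))
  )
}

#' Per-partition composition report
#'
#' Computes [base_composition()] for each partition of a genome, reproducing
#' the layout of a standard mitogenome composition table (whole genome, PCG
#' concatenation, PCG codon positions, tRNA/rRNA concatenations, individual
#' rRNAs, control region and its domains).
#'
#' Per-gene and concatenated partitions default to the coding (mRNA-sense)
#' strand, i.e. L-strand genes such as ND6 are reverse complemented before
#' counting; the whole-genome row always uses the deposited H strand.  Set
#' `strand_policy = "as_deposited"` to count every partition on the H strand
#' instead — published tables rarely state which convention they used, so
#' both are available.
#'
#' @param genome A `mito_genome` with a sequence.
#' @param specs Partition specs, as from [default_partition_specs()].
#' @param strand_policy `"coding"` (default) or `"as_deposited"`.
#' @param cr_domains Passed to [default_partition_specs()] when `specs` is
#'   not supplied.
#' @return A tibble with one [base_composition()] row per partition, in spec
#'   order.
#' @export
partition_report <- function(genome, specs = NULL,
                             strand_policy = c("coding", "as_deposited"),
                             cr_domains = NULL) {
  stopifnot(inherits(genome, "mito_genome"))
  strand_policy <- match.arg(strand_policy)
  if (is.null(specs)) specs <- default_partition_specs(genome, cr_domains)
  purrr::imap(specs, function(spec, name) {
    base_composition(partition_seq(genome, spec, strand_policy), name)
  }) |>
    bind_rows()
}
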