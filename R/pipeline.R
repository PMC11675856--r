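round_cols <- function(tab, cols, digits) {
  for (cl in intersect(cols, names(tab))) tab[[cl]] <- round(tab[[cl]], digits)
  tab
}

write_report <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE, na = "NA")
  path
}

#' Full single-genome characterization
#'
#' Runs the whole descriptive pipeline on one annotated genome and writes
#' one TSV per stage plus a JSON summary into `out_dir`: the annotation
#' table (computed sizes, signed intergenic spacers, start/stop codons),
#' the circular adjacency ledger with overlap motifs, the per-partition
#' composition report (percentages to 2 decimals, skews to 4), the codon
#' usage/RSCU table, and the control-region annotation.  Stages run
#' independently: a failing stage is recorded in `MANIFEST.tsv` with its
#' error message and the remaining stages still run, so partial output is
#' always usable.
#'
#' @param genome A `mito_genome`, or a feature-table path (see
#'   [read_feature_table()]).
#' @param out_dir Output directory (created if needed).
#' @param fasta Optional FASTA path providing the sequence when `genome` is
#'   a feature-table path.
#' @param cr_motifs Motif configuration for [segment_domains()].
#' @param strand_policy Passed to [partition_report()].
#' @param code A [mito_genetic_code()].
#' @return Invisibly, a list with the per-stage tibbles, `manifest`, and
#'   `success` (TRUE iff no stage failed).
#' @export
characterize_run <- function(genome, out_dir, fasta = NULL,
                             cr_motifs = default_cr_motifs(),
                             strand_policy = "coding",
                             code = mito_genetic_code()) {
  if (is.character(genome)) {
    seq <- if (!is.null(fasta)) read_fasta(fasta)$seq[1]
    genome <- read_feature_table(genome, seq = seq)
  }
  stopifnot(inherits(genome, "mito_genome"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  run_stage <- function(stage, file, fun, needs_seq = FALSE) {
    path <- file.path(out_dir, file)
    if (needs_seq && is.null(genome$seq)) {
      manifest[[stage]] <<- tibble(stage = stage, status = "skipped",
                                   file = NA_character_,
                                   message = "no sequence")
      return(invisible(NULL))
    }
    tryCatch({
      out <- fun()
      write_report(out, path)
      results[[stage]] <<- out
      manifest[[stage]] <<- tibble(stage = stage, status = "ok",
                                   file = file, message = NA_character_)
    }, error = function(e) {
      manifest[[stage]] <<- tibble(stage = stage, status = "failed",
                                   file = NA_character_,
                                   message = conditionMessage(e))
    })
    invisible(NULL)
  }

  run_stage("ledger", "ledger.tsv", function() adjacency_ledger(genome))

  run_stage("annotation", "annotation.tsv", function() {
    feats <- genome$features
    led <- adjacency_ledger(genome)
    tab <- feats |>
      select("gene", "type", "strand", "start", "end", size = "length") |>
      left_join(select(led, gene = "upstream", igs = "igs"), by = "gene",
                relationship = "one-to-one")
    if (!is.null(genome$seq)) {
      pcg <- feats[feats$type == "PCG", ]
      codons <- purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
        start_stop_classify(extract_feature_sequence(genome, pcg[i, ]),
                            gene = pcg$gene[i], code = code)
      })
      tab <- left_join(tab, codons, by = "gene", relationship = "one-to-one")
    }
    tab
  })

  cr_ann <- NULL
  run_stage("control_region", "cr_annotation.tsv", function() {
    cr_row <- genome$features[genome$features$type == "control_region", ]
    if (nrow(cr_row) != 1) abort("genome has no (single) control region")
    cr <- extract_feature_sequence(genome, cr_row[1, ])
    cr_ann <<- segment_domains(cr, motifs = cr_motifs)
    tidy(cr_ann) |> round_cols("identity", 1)
  }, needs_seq = TRUE)

  run_stage("composition", "composition.tsv", function() {
    partition_report(
      genome, strand_policy = strand_policy,
      cr_domains = if (!is.null(cr_ann)) cr_ann$domains
    ) |>
      round_composition()
  }, needs_seq = TRUE)

  run_stage("codon_usage", "codon_usage.tsv", function() {
    pcg <- genome$features[genome$features$type == "PCG", ]
    if (nrow(pcg) == 0) abort("no protein-coding genes")
    cds <- vapply(seq_len(nrow(pcg)), function(i) {
      extract_feature_sequence(genome, pcg[i, ])
    }, character(1))
    codon_tally(cds, code) |> rscu() |> round_cols("rscu", 4)
  }, needs_seq = TRUE)

  manifest <- bind_rows(manifest)
  summary <- list(
    id = genome$id,
    genome_length = genome$length,
    n_features = nrow(genome$features),
    features_by_type = as.list(table(genome$features$type)),
    total_codons = if (!is.null(results$codon_usage)) {
      sum(results$codon_usage$count)
    },
    at_skew = if (!is.null(results$composition)) {
      results$composition$at_skew[results$composition$partition == "Mitogenome"]
    },
    stages_ok = sum(manifest$status == "ok"),
    stages_failed = sum(manifest$status == "failed")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_report(manifest, file.path(out_dir, "MANIFEST.tsv"))
  invisible(c(results, list(manifest = manifest,
                            success = !any(manifest$status == "failed"))))
}

# mask stop codons (either sequence) and trailing incomplete tails so a
# whole-CDS pair can be fed to the NG86 estimator
clean_cds_pair <- function(a, b, code = mito_genetic_code()) {
  tabs <- ng86_tables(code)
  trim <- function(s) substr(s, 1, 3 * (nchar(s) %/% 3))
  a <- trim(toupper(a)); b <- trim(toupper(b))
  n <- min(nchar(a), nchar(b))
  a <- substr(a, 1, n); b <- substr(b, 1, n)
  if (n < 3) return(NULL)
  ca <- split_codons(a); cb <- split_codons(b)
  ok_a <- !grepl("[^ACGT]", ca); ok_b <- !grepl("[^ACGT]", cb)
  stop_a <- ok_a & tabs$is_stop[ifelse(ok_a, codon_to_index(ca), 1L)]
  stop_b <- ok_b & tabs$is_stop[ifelse(ok_b, codon_to_index(cb), 1L)]
  mask <- stop_a | stop_b
  ca[mask] <- "NNN"; cb[mask] <- "NNN"
  list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""))
}

#' Side-by-side comparison of two genomes
#'
#' Compares two annotated genomes the way comparative mitogenome tables do:
#' per-partition composition side by side, adjacency ledgers joined on the
#' upstream gene, per-codon RSCU differences, and per-gene NG86 Ka/Ks for
#' every shared protein-coding gene whose extracted CDSs have equal length
#' (treated as pre-aligned; stop codons and codons with ambiguity characters
#' are masked pairwise before estimation).  Reports are written to
#' `out_dir` as TSVs with a MANIFEST, like [characterize_run()].
#'
#' @param genome1,genome2 `mito_genome` objects with sequences.
#' @param out_dir Output directory.
#' @param strand_policy,code As in [characterize_run()].
#' @return Invisibly, a list with `composition`, `ledger`, `rscu_diff`,
#'   `kaks`, `manifest`, `success`.
#' @export
compare_run <- function(genome1, genome2, out_dir,
                        strand_policy = "coding",
                        code = mito_genetic_code()) {
  stopifnot(inherits(genome1, "mito_genome"),
            inherits(genome2, "mito_genome"))
  shared <- intersect(genome1$features$gene, genome2$features$gene)
  if (length(shared) == 0) abort("genomes share no gene names")
  only1 <- setdiff(genome1$features$gene, shared)
  only2 <- setdiff(genome2$features$gene, shared)
  if (length(only1) + length(only2) > 0) {
    warn(paste0("gene sets differ; unmatched: ",
                paste(c(only1, only2), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  run_stage <- function(stage, file, fun) {
    tryCatch({
      out <- fun()
      write_report(out, file.path(out_dir, file))
      results[[stage]] <<- out
      manifest[[stage]] <<- tibble(stage = stage, status = "ok",
                                   file = file, message = NA_character_)
    }, error = function(e) {
      manifest[[stage]] <<- tibble(stage = stage, status = "failed",
                                   file = NA_character_,
                                   message = conditionMessage(e))
    })
  }
  suffixes <- c(paste0("_", genome1$id), paste0("_", genome2$id))
  if (identical(genome1$id, genome2$id)) suffixes <- c("_1", "_2")

  run_stage("composition", "composition_compare.tsv", function() {
    a <- partition_report(genome1, strand_policy = strand_policy) |>
      round_composition()
    b <- partition_report(genome2, strand_policy = strand_policy) |>
      round_composition()
    dplyr::full_join(a, b, by = "partition", suffix = suffixes)
  })

  run_stage("ledger", "ledger_compare.tsv", function() {
    a <- adjacency_ledger(genome1)
    b <- adjacency_ledger(genome2)
    dplyr::full_join(a, b, by = c("upstream", "downstream"),
                     suffix = suffixes)
  })

  run_stage("rscu_diff", "rscu_compare.tsv", function() {
    usage_of <- function(g) {
      pcg <- g$features[g$features$type == "PCG", ]
      cds <- vapply(seq_len(nrow(pcg)), function(i) {
        extract_feature_sequence(g, pcg[i, ])
      }, character(1))
      rscu(codon_tally(cds, code))
    }
    a <- usage_of(genome1); b <- usage_of(genome2)
    left_join(
      select(a, "codon", "amino_acid", "family", count_1 = "count",
             rscu_1 = "rscu"),
      select(b, "codon", count_2 = "count", rscu_2 = "rscu"),
      by = "codon"
    ) |>
      mutate(rscu_diff = .data$rscu_1 - .data$rscu_2) |>
      round_cols(c("rscu_1", "rscu_2", "rscu_diff"), 4)
  })

  run_stage("kaks", "kaks.tsv", function() {
    pcg <- intersect(
      genome1$features$gene[genome1$features$type == "PCG"],
      genome2$features$gene[genome2$features$type == "PCG"]
    )
    if (length(pcg) == 0) abort("no shared protein-coding genes")
    purrr::map_dfr(pcg, function(g) {
      c1 <- extract_feature_sequence(genome1, g)
      c2 <- extract_feature_sequence(genome2, g)
      if (nchar(c1) != nchar(c2)) {
        return(tibble(gene = g, note = "unequal lengths, skipped"))
      }
      pair <- clean_cds_pair(c1, c2, code)
      if (is.null(pair)) return(tibble(gene = g, note = "too short"))
      bind_cols(tibble(gene = g),
                tidy(ng86_kaks(pair$a, pair$b, code)) |>
                  round_cols(c("N", "S", "Nd", "Sd"), 2) |>
                  round_cols(c("pN", "pS", "ka", "ks", "ratio"), 4))
    })
  })

  manifest <- bind_rows(manifest)
  write_report(manifest, file.path(out_dir, "MANIFEST.tsv"))
  invisible(c(results, list(manifest = manifest,
                            success = !any(manifest$status == "failed"))))
}
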