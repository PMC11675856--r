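test_that("base composition handles simple and degenerate sequences", {
  r <- base_composition("AATT")
  expect_equal(r$pct_a, 50)
  expect_equal(r$pct_t, 50)
  expect_equal(r$pct_c + r$pct_g, 0)
  expect_equal(r$at_skew, 0)

  r2 <- base_composition("GGGC")
  expect_equal(r2$pct_g, 75)
  expect_equal(r2$pct_c, 25)
  expect_equal(r2$gc_skew, 0.5)

  # N residues excluded from the denominator entirely
  expect_equal(base_composition("AANNTT")$n_sites, 4)
  expect_error(base_composition("NNN"), "residues")
})

test_that("skew is antisymmetric, scale-invariant, and NA at zero mass", {
  expect_equal(skew(5, 5), 0)
  expect_equal(skew(3, 1), -skew(1, 3))
  expect_true(is.na(skew(0, 0)))
  # ratio invariance: counts vs percentages agree to machine precision
  counts <- c(311, 257)
  pct <- 100 * counts / sum(counts)
  expect_equal(skew(counts[1], counts[2]), skew(pct[1], pct[2]),
               tolerance = 1e-12)
})

test_that("published percentages reproduce published skews to print precision", {
  tab <- readr::read_tsv(pheasant_composition_table(), show_col_types = FALSE)
  at <- round(skew(tab$pct_a, tab$pct_t), 4)
  gc <- round(skew(tab$pct_g, tab$pct_c), 4)
  # percentages were printed at 2 d.p., so recomputed skews can move one
  # unit in the 4th decimal relative to count-based originals
  expect_true(all(abs(at - tab$at_skew) <= 1.5e-4))
  expect_true(all(abs(gc - tab$gc_skew) <= 1.5e-4))
  expect_equal(at[tab$partition == "Mitogenome"], 0.0958)
  expect_equal(gc[tab$partition == "Mitogenome"], -0.3981)
  expect_equal(at[tab$partition == "CR"], -0.0843)
})

test_that("partition report conserves percentages and respects concatenation", {
  sim <- generate_genome(seed = 3)
  g <- sim$genome
  rep <- partition_report(g)
  expect_true(all(abs(rep$pct_a + rep$pct_t + rep$pct_c + rep$pct_g - 100)
                  < 0.01))

  # PCG partition equals the length-weighted average of per-gene rows
  pcg <- g$features[g$features$type == "PCG", ]
  per_gene <- purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
    base_composition(extract_feature_sequence(g, pcg[i, ]), pcg$gene[i])
  })
  w <- per_gene$n_sites / sum(per_gene$n_sites)
  pcg_row <- rep[rep$partition == "PCGs", ]
  for (col in c("pct_a", "pct_t", "pct_c", "pct_g")) {
    expect_equal(pcg_row[[col]], sum(w * per_gene[[col]]), tolerance = 1e-9)
  }

  # a single feature spanning the whole genome equals base_composition
  whole <- annotated_genome(
    g$seq, data.frame(gene = "all", type = "rRNA", strand = "H",
                      start = 1, end = g$length))
  one <- partition_report(
    whole, specs = list(rRNA = list(kind = "types", types = "rRNA")))
  expect_equal(one$pct_a, base_composition(g$seq)$pct_a)
  expect_equal(one$at_skew, base_composition(g$seq)$at_skew)
})

test_that("strand policy switches ND6-style genes between strands", {
  sim <- generate_genome(seed = 4)
  g <- sim$genome
  coding <- partition_report(
    g, specs = list(PCGs = list(kind = "types", types = "PCG")))
  deposited <- partition_report(
    g, specs = list(PCGs = list(kind = "types", types = "PCG")),
    strand_policy = "as_deposited")
  # ND6 is L-strand: the two policies must disagree on the PCG row
  expect_false(isTRUE(all.equal(coding$pct_g, deposited$pct_g)))
})

test_that("generated partitions land within 1.5 points of their targets", {
  sim <- generate_genome(seed = 5)
  g <- sim$genome
  rep <- partition_report(g)
  targets <- sim$truth$composition_targets
  check <- list(PCGs = targets$PCG, tRNA = targets$tRNA, rRNA = targets$rRNA)
  for (part in names(check)) {
    row <- rep[rep$partition == part, ]
    tgt <- 100 * check[[part]]
    expect_lt(abs(row$pct_a - tgt[["A"]]), 1.5)
    expect_lt(abs(row$pct_c - tgt[["C"]]), 1.5)
    expect_lt(abs(row$pct_g - tgt[["G"]]), 1.5)
    expect_lt(abs(row$pct_t - tgt[["T"]]), 1.5)
  }
})
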