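test_that("default genome realizes its genome_spec and is seed-deterministic", {
  sim <- generate_genome(seed = 1)
  g <- sim$genome
  expect_equal(nrow(g$features), 38)
  expect_true(g$circular)
  led <- adjacency_ledger(g)
  expect_equal(led$igs[led$upstream == "ATP8"], -10)
  expect_equal(led$overlap_motif[led$upstream == "ATP8"], "ATGAACCTAA")
  expect_equal(led$overlap_motif[led$upstream == "ND4L"], "ATGCTAA")
  expect_equal(sim$truth$overlaps$igs, c(-10L, -7L))

  # byte-identical under the same seed, different under another
  sim2 <- generate_genome(seed = 1)
  expect_identical(sim2$genome$seq, g$seq)
  expect_identical(sim2$genome$features, g$features)
  expect_false(identical(generate_genome(seed = 2)$genome$seq, g$seq))

  # generator leaves the caller's RNG stream untouched
  set.seed(99)
  before <- .Random.seed
  invisible(generate_genome(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("emitted artifacts validate against their own truth", {
  sim <- generate_genome(seed = 13)
  g <- sim$genome
  # planted start/stops recoverable by classification
  for (gene in names(sim$truth$start_stop)) {
    got <- start_stop_classify(extract_feature_sequence(g, gene))
    expect_equal(got$start_codon, sim$truth$start_stop[[gene]]$start,
                 info = gene)
    expect_equal(got$stop_codon, sim$truth$start_stop[[gene]]$stop,
                 info = gene)
  }
  # planted CR motif intervals are in range and sit verbatim
  cr <- extract_feature_sequence(g, "D-loop")
  for (m in names(sim$truth$cr$motifs)) {
    at <- sim$truth$cr$motifs[[m]]
    expect_true(at[["start"]] >= 1 && at[["end"]] <= nchar(cr), info = m)
    hit <- find_motif(cr, substr(cr, at[["start"]], at[["end"]]),
                      min_identity = 100)
    expect_true(at[["start"]] %in% hit$start, info = m)
  }
  gh <- sim$truth$cr$motifs$goose_hairpin
  expect_equal(substr(cr, gh[["start"]], gh[["end"]]),
               "TACCCCCCCTTTCCCCCCCAGGGGGGGTA")
  pc <- sim$truth$cr$poly_c
  expect_equal(substr(cr, pc[["start"]], pc[["end"]]),
               strrep("C", pc[["end"]] - pc[["start"]] + 1))
})

test_that("infeasible genome specs are rejected", {
  feats <- data.frame(
    gene = c("g1", "g2"), type = "PCG", strand = "H",
    start = c(1L, 8L), end = c(10L, 40L),
    start_codon = NA_character_, stop_codon = NA_character_
  )
  expect_error(
    generate_genome(genome_spec(
      features = feats, cr = NULL,
      overlaps = tibble::tibble(upstream = "g1", downstream = "g2",
                                motif = strrep("A", 20))
    )),
    "infeasible"
  )
  expect_error(
    generate_genome(genome_spec(
      features = feats, cr = NULL,
      overlaps = tibble::tibble(upstream = "g1", downstream = "gX",
                                motif = "AAA")
    )),
    "infeasible"
  )
})

test_that("codon-pair evolution honours t, omega, and the seed", {
  p0 <- evolve_codon_pair(evolve_params(t = 0, n_codons = 200), seed = 1)
  expect_identical(p0$cds1, p0$cds2)
  expect_identical(p0$cds1, p0$truth$ancestor)

  pw0 <- evolve_codon_pair(
    evolve_params(t = 0.5, omega = 0, n_codons = 400), seed = 2)
  expect_equal(pw0$truth$lineage1$nonsyn, 0)
  expect_equal(pw0$truth$lineage2$nonsyn, 0)
  # the estimate need not be exactly 0: two synonymous hits in one codon
  # can yield a pathway whose steps are not all synonymous
  r <- ng86_kaks(pw0$cds1, pw0$cds2)
  expect_lt(r$ka, 0.01)
  expect_lt(r$ka / r$ks, 0.05)

  pa <- evolve_codon_pair(evolve_params(t = 0.3, n_codons = 300), seed = 3)
  pb <- evolve_codon_pair(evolve_params(t = 0.3, n_codons = 300), seed = 3)
  expect_identical(pa, pb)
  # realized counts are consistent with the emitted sequences: no stops
  expect_error(ng86_site_counts(pa$cds1), NA)

  expect_error(evolve_params(t = -1), "invalid")
})

test_that("tree simulation is deterministic and degenerate-safe", {
  star <- ape::read.tree(text = "(A:0,B:0,C:0,D:0);")
  sim <- simulate_alignment_on_tree(star, 200, seed = 5)
  expect_equal(length(unique(sim$alignment$seq)), 1)
  expect_equal(unique(nchar(sim$alignment$seq)), 200)

  tr <- ape::rtree(4, br = 0.05)
  s1 <- simulate_alignment_on_tree(tr, 500, seed = 6)
  s2 <- simulate_alignment_on_tree(tr, 500, seed = 6)
  expect_identical(s1$alignment, s2$alignment)
  expect_false(identical(
    simulate_alignment_on_tree(tr, 500, seed = 7)$alignment, s1$alignment))

  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(simulate_alignment_on_tree(bad, 100, seed = 1),
               "non-negative")
  expect_error(simulate_alignment_on_tree(tr, 0, seed = 1), "positive")

  # a 4-taxon tree with clear internal edge: NJ on K2P recovers topology
  gen <- ape::read.tree(
    text = "((A:0.03,B:0.03):0.02,(C:0.03,D:0.03):0.02);")
  aln <- simulate_alignment_on_tree(gen, 5000, kappa = 2, seed = 9)
  nj <- tree_build(distance_matrix(aln$alignment, "k2p"), "nj")
  expect_true(is_monophyletic(nj, c("A", "B"), outgroup = "D"))
})
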