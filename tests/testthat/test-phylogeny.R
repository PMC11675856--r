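test_that("p and K2P distances match closed forms and an independent oracle", {
  s <- random_sense_cds(40, seed = 1)
  expect_equal(pairwise_distance(s, s, "p"), 0)
  expect_equal(pairwise_distance(s, s, "k2p"), 0)

  # 100 sites: 10 transitions (A->G), 5 transversions (A->C)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(pairwise_distance(a, b, "p"), 0.15)
  got <- pairwise_distance(a, b, "k2p")
  bin <- ape::as.DNAbin(strsplit(tolower(c(x = a, y = b)), ""))
  oracle <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(got, oracle, tolerance = 1e-12)

  # pairwise deletion of ambiguous sites
  expect_equal(pairwise_distance("ACGTN", "ACGAC", "p"), 0.25)
  expect_error(pairwise_distance("NNN", "ACG"), "comparable")
  # saturation: log argument non-positive
  expect_error(pairwise_distance(strrep("A", 10), strrep("G", 10), "k2p"),
               "saturated")
})

test_that("distance matrices are symmetric with zero diagonal", {
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        seq = rep(random_sense_cds(30, 2), 3))
  expect_true(all(distance_matrix(aln) == 0))

  sim <- simulate_alignment_on_tree(ape::rtree(5, br = 0.05), 300, seed = 3)
  d <- distance_matrix(sim$alignment, "k2p")
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_equal(rownames(d), sim$alignment$id)

  expect_error(
    distance_matrix(tibble::tibble(id = c("a", "b"),
                                   seq = c("ACGT", "ACG"))),
    "ragged")

  # concatenation: joined alignments give the pooled-site distance
  a1 <- tibble::tibble(id = c("x", "y"), seq = c("AAAA", "AAAC"))
  a2 <- tibble::tibble(id = c("x", "y"), seq = c("GGGG", "GGGG"))
  joined <- concat_alignments(a1, a2)
  expect_equal(joined$seq, c("AAAAGGGG", "AAACGGGG"))
  expect_equal(distance_matrix(joined)["x", "y"], 1 / 8)
})

test_that("NJ is exact on additive matrices and UPGMA is ultrametric", {
  taxa <- c("A", "B", "C", "D")
  d <- matrix(4, 4, 4, dimnames = list(taxa, taxa))
  d[cbind(taxa, taxa)] <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  tr <- tree_build(d, "nj")
  # generating topology ((A,B),(C,D)) and exact path lengths
  expect_true(is_monophyletic(tr, c("A", "B"), outgroup = "D"))
  expect_equal(ape::cophenetic.phylo(tr)[taxa, taxa], d, tolerance = 1e-12)

  # UPGMA on an ultrametric matrix: node heights are half the distances
  t3 <- c("A", "B", "C")
  du <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(t3, t3))
  up <- tree_build(du, "upgma")
  expect_true(ape::is.ultrametric(up, tol = 1e-9))
  cc <- ape::cophenetic.phylo(up)[t3, t3]
  expect_equal(cc, du, tolerance = 1e-12)

  # 2-taxon UPGMA: two branches of d/2
  up2 <- tree_build(du[1:2, 1:2], "upgma")
  expect_equal(sort(up2$edge.length), c(1, 1))

  dbad <- d
  dbad[1, 2] <- 99
  expect_error(tree_build(dbad, "nj"), "symmetric")
  expect_error(tree_build(du[1:2, 1:2], "nj"), "3 taxa")
})

test_that("monophyly checks work on rooted and outgroup-rooted trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")

  # simulated data on the pheasant-genus topology: NJ recovers both clades
  gen <- ape::read.tree(text = paste0(
    "(((Phasianus:0.02,Chrysolophus:0.02):0.015,",
    "(Crossoptilon:0.02,Lophura:0.02):0.015):0.05,Outgroup:0.085);"))
  sim <- simulate_alignment_on_tree(gen, 4000, kappa = 2, seed = 8)
  nj <- tree_build(distance_matrix(sim$alignment, "k2p"), "nj")
  expect_true(is_monophyletic(nj, c("Phasianus", "Chrysolophus"),
                              outgroup = "Outgroup"))
  expect_true(is_monophyletic(nj, c("Crossoptilon", "Lophura"),
                              outgroup = "Outgroup"))
})

test_that("strict-clock dating scales depths linearly and exactly", {
  # depth-4 caterpillar-free tree: calibration node at depth 2 -> root 20
  tr <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
  tt <- strict_clock_dates(tr, calibration("A", "B", 10))
  expect_equal(max(tt$ages), 20)
  expect_equal(tt$rate, 0.2)
  td <- tidy(tt)
  expect_true(all(td$age[td$is_tip] == 0))

  # two mutually consistent calibrations change nothing
  tt2 <- strict_clock_dates(
    tr, dplyr::bind_rows(calibration("A", "B", 10),
                         calibration("A", "C", 20)))
  expect_equal(tt2$ages, tt$ages)

  # scale equivariance: c times the branch lengths, same ages
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7
  tt3 <- strict_clock_dates(tr2, calibration("A", "B", 10))
  expect_equal(tt3$ages, tt$ages)
  expect_equal(tt3$rate, tt$rate * 7)

  # interval calibration collapses to its midpoint
  tt4 <- strict_clock_dates(tr, calibration("A", "B", 8, 12))
  expect_equal(tt4$ages, tt$ages)

  # inconsistent calibrations warn with residuals
  expect_warning(
    strict_clock_dates(tr, dplyr::bind_rows(calibration("A", "B", 10),
                                            calibration("A", "C", 100))),
    "inconsistent")

  expect_error(strict_clock_dates(ape::read.tree(text = "((A:1,B:2):1,C:3);"),
                                  calibration("A", "B", 1)),
               "ultrametric")
})

test_that("dating recovers planted node ages on random ultrametric trees", {
  for (s in c(41, 42)) {
    set.seed(s)
    tr <- ape::rcoal(8)
    true_age <- max(ape::node.depth.edgelength(tr)) -
      ape::node.depth.edgelength(tr)
    # calibrate one internal node at its true age
    node <- ape::getMRCA(tr, c(tr$tip.label[1], tr$tip.label[2]))
    tt <- strict_clock_dates(
      tr, calibration(tr$tip.label[1], tr$tip.label[2], true_age[node]))
    expect_equal(tt$ages, true_age, tolerance = 1e-9)
  }
})
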