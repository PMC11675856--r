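test_that("site counts match enumeration of single-base mutants", {
  # TTT (Phe): only the third position has a synonymous mutant (TTC)
  sc <- ng86_site_counts("TTT")
  expect_equal(sc[["S"]], 1 / 3)
  expect_equal(sc[["N"]], 8 / 3)

  # conservation N + S = 3 per codon, against the brute-force oracle
  for (codon in sense_codons) {
    sc <- ng86_site_counts(codon)
    expect_equal(sc[["N"]] + sc[["S"]], 3)
    expect_equal(sc[["S"]], oracle_s_sites(codon), tolerance = 1e-12)
  }

  cds <- random_sense_cds(100, seed = 3)
  sc <- ng86_site_counts(cds)
  expect_equal(sc[["N"]] + sc[["S"]], 300)

  expect_error(ng86_site_counts("ATGTAAATG"), "codon 2")
  expect_error(ng86_site_counts("ATGA"), "multiple of 3")
})

test_that("pathway-averaged differences equal brute-force enumeration", {
  tabs <- mitochar:::ng86_tables(mito_genetic_code())
  idx <- mitochar:::codon_to_index(sense_codons)
  blocked <- 0
  for (a in seq_along(sense_codons)) {
    for (b in seq_along(sense_codons)) {
      if (b <= a) next
      o <- oracle_nd_sd(sense_codons[a], sense_codons[b])
      if (is.null(o)) { blocked <- blocked + 1; next }
      expect_equal(tabs$nd[idx[a], idx[b]], unname(o["nd"]),
                   tolerance = 1e-12,
                   info = paste(sense_codons[a], sense_codons[b]))
      expect_equal(tabs$sd[idx[a], idx[b]], unname(o["sd"]),
                   tolerance = 1e-12,
                   info = paste(sense_codons[a], sense_codons[b]))
    }
  }
  expect_gt(blocked, 0)  # fully blocked pairs exist under this code
})

test_that("fully stop-blocked pairs fall back to direct-position synonymy", {
  # AAA (Lys) <-> TGA (Trp): both orderings pass through a stop
  # (TAA via position 1, AGA via position 2)
  expect_null(oracle_nd_sd("AAA", "TGA"))
  tabs <- mitochar:::ng86_tables(mito_genetic_code())
  i <- mitochar:::codon_to_index("AAA")
  j <- mitochar:::codon_to_index("TGA")
  # both direct changes hit stops, hence are non-synonymous by the rule
  expect_equal(tabs$nd[i, j], 2)
  expect_equal(tabs$sd[i, j], 0)
})

test_that("Ka/Ks estimates known hand cases and is symmetric", {
  a <- random_sense_cds(50, seed = 5)
  r0 <- ng86_kaks(a, a)
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(is.na(r0$ratio))
  expect_equal(r0$class, "undefined")

  # ten TTT codons with one synonymous change
  r <- ng86_kaks(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.3)
  expect_equal(r$ks, -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-12)
  expect_equal(round(r$ks, 4), 0.3831)
  expect_equal(r$ka, 0)
  expect_equal(r$N + r$S, 3 * r$n_codons, tolerance = 1e-9)

  b <- random_sense_cds(50, seed = 6)
  expect_equal(tidy(ng86_kaks(a, b)), tidy(ng86_kaks(b, a)))

  expect_error(ng86_kaks("ATGATG", "ATG"), "length")
  expect_error(ng86_kaks("ATGTAA", "ATGTAC"), "stop")
  # ambiguous codons are dropped pairwise
  r2 <- ng86_kaks("ATGNNNGTA", "ATGAAAGTA")
  expect_equal(r2$n_codons, 2)
})

test_that("recovered Ka/Ks increases with the generating omega", {
  means <- vapply(c(0.1, 0.5, 1, 2), function(w) {
    est <- vapply(1:3, function(s) {
      pr <- evolve_codon_pair(
        evolve_params(t = 0.3, kappa = 1, omega = w, n_codons = 1500),
        seed = 100 + s)
      ng86_kaks(pr$cds1, pr$cds2)$ratio
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
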