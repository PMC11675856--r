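goose <- "TACCCCCCCTTTCCCCCCCAGGGGGGGTA"

test_that("motif scan finds exact and degraded plants at known positions", {
  set.seed(1)
  pad <- function(n) paste(sample(c("A", "T", "G"), n, replace = TRUE),
                           collapse = "")
  cr <- paste0(pad(120), goose, pad(200))
  hits <- find_motif(cr, goose, min_identity = 90)
  expect_equal(hits$start[1], 121)
  expect_equal(hits$identity[1], 100)
  expect_equal(hits$end[1] - hits$start[1] + 1, nchar(goose))

  # one mismatch over 25 positions: identity 96
  motif25 <- "ATACTATGAATGGTTACAGGACATA"
  degraded <- sub("^A", "C", motif25)
  cr2 <- paste0(pad(60), degraded, pad(60))
  h2 <- find_motif(cr2, motif25, min_identity = 90)
  expect_equal(h2$identity[1], 96)
  expect_equal(h2$start[1], 61)

  expect_equal(nrow(find_motif(strrep("A", 100), "GGGGG",
                               min_identity = 100)), 0)
  expect_error(find_motif("ACGT", "ACGTA"), "longer")
})

test_that("identity is invariant under simultaneous complementation", {
  set.seed(2)
  cr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  motif <- substr(cr, 101, 125)
  h1 <- find_motif(cr, motif, min_identity = 60)
  h2 <- find_motif(complement_str(cr), complement_str(motif),
                   min_identity = 60)
  expect_equal(h1$start, h2$start)
  expect_equal(h1$identity, h2$identity)
})

test_that("domain segmentation recovers planted truth and tiles the CR", {
  sim <- generate_genome(seed = 31)
  cr <- extract_feature_sequence(sim$genome, "D-loop")
  ann <- segment_domains(cr)
  expect_equal(ann$domains, sim$truth$cr$domains)
  expect_equal(ann$poly_c, sim$truth$cr$poly_c)
  # tiling: contiguous, ordered, no gaps or overlaps
  expect_equal(ann$domains$start[1], 1L)
  expect_equal(ann$domains$end[3], nchar(cr))
  expect_equal(ann$domains$start[-1], ann$domains$end[-3] + 1L)
  # the planted goose hairpin is found verbatim
  gh <- ann$hits[ann$hits$motif == "goose_hairpin", ]
  expect_equal(gh$identity[1], 100)
  expect_equal(gh$start[1],
               unname(sim$truth$cr$motifs$goose_hairpin[["start"]]))
})

test_that("segmentation is translation-equivariant and fails loudly", {
  sim <- generate_genome(seed = 32)
  cr <- extract_feature_sequence(sim$genome, "D-loop")
  ann <- segment_domains(cr)
  shifted <- paste0(strrep("GT", 25), cr)   # +50 nt, anchor-free pad
  ann2 <- segment_domains(shifted)
  expect_equal(ann2$domains$end[1], ann$domains$end[1] + 50L)
  expect_equal(ann2$domains$start[3], ann$domains$start[3] + 50L)
  expect_equal(ann2$poly_c, ann$poly_c + 50L)

  expect_error(segment_domains(strrep("AT", 200)),
               class = "mitochar_segmentation_failed")
  # anchor present but no room for domains II/III
  expect_error(
    segment_domains(paste0("AT", "ATACTATGAATGGTTACAGGACATA", "AT")),
    class = "mitochar_segmentation_failed")
})

test_that("poly-C detection takes the longest run, leftmost on ties", {
  s <- paste0(strrep("A", 10), strrep("C", 6), strrep("A", 10),
              strrep("C", 9), strrep("A", 5))
  r <- mitochar:::longest_run(s, "C", 6)
  expect_equal(unname(r), c(27, 35))
  s2 <- paste0(strrep("A", 5), strrep("C", 7), strrep("T", 5),
               strrep("C", 7), "A")
  r2 <- mitochar:::longest_run(s2, "C", 6)
  expect_equal(unname(r2), c(6, 12))
  expect_null(mitochar:::longest_run("ACACAC", "C", 6))
})
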