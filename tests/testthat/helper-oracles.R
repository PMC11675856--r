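# Independent oracles and small builders shared across the suite.

mito_aa <- local({
  gc2 <- Biostrings::getGeneticCode("2")
  setNames(as.character(gc2), names(gc2))
})

# brute-force NG86 pathway enumeration for one codon pair, independent of
# the package's lookup tables: enumerate every ordering of the differing
# positions recursively, dropping orderings that visit a stop codon before
# the final step, and average step classes over the surviving orderings.
oracle_nd_sd <- function(c1, c2) {
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  dif <- which(a1 != a2)
  if (length(dif) == 0) return(c(nd = 0, sd = 0))
  acc <- list()
  recurse <- function(cur, remaining, sn, nn) {
    if (length(remaining) == 0) {
      acc[[length(acc) + 1]] <<- c(nd = nn, sd = sn)
      return(invisible(NULL))
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- a2[p]
      cod <- paste(nxt, collapse = "")
      if (mito_aa[[cod]] == "*" && length(remaining) > 1) next
      syn <- mito_aa[[cod]] == mito_aa[[paste(cur, collapse = "")]]
      recurse(nxt, setdiff(remaining, p), sn + syn, nn + !syn)
    }
  }
  recurse(a1, dif, 0, 0)
  if (length(acc) == 0) return(NULL)   # every ordering blocked by stops
  colMeans(do.call(rbind, acc))[c("nd", "sd")]
}

# brute-force synonymous site count of one codon: per position, fraction of
# non-stop single-base mutants that keep the amino acid
oracle_s_sites <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), v[pos]), function(b) {
      w <- v
      w[pos] <- b
      paste(w, collapse = "")
    }, character(1))
    keep <- muts[mito_aa[muts] != "*"]
    if (length(keep) > 0) {
      s <- s + sum(mito_aa[keep] == mito_aa[[codon]]) / length(keep)
    }
  }
  s
}

sense_codons <- names(mito_aa)[mito_aa != "*"]

random_sense_cds <- function(n_codons, seed) {
  withr::with_seed(seed,
    paste(sample(sense_codons, n_codons, replace = TRUE), collapse = ""))
}

complement_str <- function(x) chartr("ACGT", "TGCA", x)

# a minimal two-feature circular genome for layout tests
tiny_genome <- function(seq = "ATGAAATAACCGGTTACAT") {
  annotated_genome(
    seq,
    data.frame(
      gene = c("g1", "t1"),
      type = c("PCG", "tRNA"),
      strand = c("H", "L"),
      start = c(1L, 11L),
      end = c(9L, 18L)
    ),
    circular = TRUE, id = "tiny"
  )
}
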