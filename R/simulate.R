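# run code under a private, explicitly seeded RNG stream, leaving the
# caller's .Random.seed untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic largest-remainder integer counts summing to n
freq_counts <- function(n, freq) {
  freq <- freq / sum(freq)
  cnt <- floor(n * freq)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(n * freq - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  cnt
}

# shuffled base vector of length n matching target frequencies to rounding;
# `planted` is an optional character vector of residues already fixed in the
# same region, whose counts are debited from the target before filling
fill_bases <- function(n_free, freq, planted = character(0)) {
  total <- n_free + length(planted)
  want <- freq_counts(total, freq[bases4])
  names(want) <- bases4
  if (length(planted) > 0) {
    have <- table(factor(planted, levels = bases4))
    want <- pmax(want - as.integer(have), 0L)
  }
  pool <- rep(bases4, want)
  if (length(pool) >= n_free) {
    sample(pool)[seq_len(n_free)]
  } else {
    c(sample(pool),
      sample(bases4, n_free - length(pool), replace = TRUE,
             prob = freq[bases4]))
  }
}

#' Template features and composition targets of the generator
#'
#' `template_features()` returns the standard 38-feature avian mitogenome
#' layout used as the default gene-order template (the bundled pheasant
#' annotation, including its planted start/stop codons);
#' `template_composition()` returns the default per-feature-type base
#' composition targets (fractions of A, C, G, T on the coding strand),
#' taken from the bundled published per-partition composition.
#'
#' @return A tibble (`template_features`) or a named list of numeric vectors
#'   (`template_composition`).
#' @export
template_features <- function() {
  readr::read_tsv(pheasant_feature_table(), show_col_types = FALSE,
                  progress = FALSE, na = c("", "NA")) |>
    select("gene", "type", "strand", "start", "end",
           "start_codon", "stop_codon")
}

#' @rdname template_features
#' @export
template_composition <- function() {
  pct <- function(a, c, g, t) c(A = a, C = c, G = g, T = t) / 100
  list(
    PCG = pct(28.40, 31.53, 13.00, 27.07),
    tRNA = pct(30.75, 20.74, 20.48, 28.03),
    rRNA = pct(33.81, 27.24, 18.05, 20.90),
    control_region = pct(27.44, 25.87, 14.20, 32.49),
    intergenic = pct(30.61, 30.85, 13.28, 25.26),
    cr_domains = list(
      I = pct(30.28, 27.44, 12.30, 29.97),
      II = pct(16.67, 31.41, 20.30, 31.62),
      III = pct(38.84, 17.36, 7.99, 35.81)
    )
  )
}

#' Specification for a synthetic annotated mitogenome
#'
#' Collects everything [generate_genome()] needs: the gene-order template
#' (default: the standard avian 38-feature order), per-feature-type base
#' composition targets, the gene overlaps to plant verbatim (default: the
#' conserved 10-bp `ATGAACCTAA` overlap between ATP8 and ATP6 and the 7-bp
#' `ATGCTAA` overlap between ND4L and ND4), and the control-region plan
#' (domain boundaries, goose-hairpin and CSB1-like motifs, poly-C run).
#'
#' @param features Feature template tibble (`gene`, `type`, `strand`,
#'   `start`, `end`, optional `start_codon`, `stop_codon`).
#' @param composition Named list of composition targets per feature type
#'   (fractions over A/C/G/T summing to 1), plus `intergenic` and
#'   `cr_domains`; see [template_composition()].
#' @param overlaps Tibble `upstream`, `downstream`, `motif` of overlaps to
#'   plant; motif lengths must equal the coordinate-derived overlap lengths.
#' @param cr List: `d1_end`, `d3_start` (CR-local domain boundaries),
#'   `goose_hairpin`, `goose_hairpin_at`, `anchor` (domain I/II boundary
#'   motif planted so it ends at `d1_end`), `poly_c_len` (poly-C planted at
#'   `d3_start`).  `NULL` for genomes without a control region.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(features = template_features(),
                        composition = template_composition(),
                        overlaps = tibble(
                          upstream = c("ATP8", "ND4L"),
                          downstream = c("ATP6", "ND4"),
                          motif = c("ATGAACCTAA", "ATGCTAA")
                        ),
                        cr = list(
                          d1_end = 317L,
                          d3_start = 778L,
                          goose_hairpin = "TACCCCCCCTTTCCCCCCCAGGGGGGGTA",
                          goose_hairpin_at = 35L,
                          anchor = "ATACTATGAATGGTTACAGGACATA",
                          poly_c_len = 14L
                        )) {
  features <- as_tibble(features)
  for (col in c("start_codon", "stop_codon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  chk <- vapply(
    composition[intersect(names(composition), feature_types)],
    function(p) abs(sum(p) - 1) < 1e-6, logical(1))
  if (!all(chk)) abort("composition targets must sum to 1 per type")
  structure(
    list(features = features, composition = composition,
         overlaps = as_tibble(overlaps), cr = cr),
    class = "genome_spec"
  )
}

#' Generate a synthetic annotated mitogenome with known ground truth
#'
#' Emits a circular genome realizing a [genome_spec()]: every feature is
#' filled on its coding strand with an exact-count draw from its type's
#' target composition (so realized composition matches the target to
#' rounding), protein-coding genes receive their template start and stop
#' codons (incomplete `T--`/`TA-` stops are planted as a non-stop final
#' codon plus the printed tail), the configured overlap motifs are written
#' verbatim at the overlap coordinates, and the control region is built
#' domain by domain with its goose hairpin, boundary anchor, and poly-C run
#' planted at known positions.  All randomness comes from one private RNG
#' stream seeded with `seed`: equal seeds give byte-identical output.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @param id Genome label.
#' @return A list with `genome` (a [annotated_genome()]) and `truth`, a list
#'   recording the planted overlaps (with expected `igs`), CR domains and
#'   motif positions (CR-local), planted start/stop codons, per-type
#'   composition targets, and the seed.
#' @examples
#' sim <- generate_genome(seed = 1)
#' sim$genome
#' @export
generate_genome <- function(spec = genome_spec(), seed = 1, id = "synthetic") {
  stopifnot(inherits(spec, "genome_spec"))
  feats <- spec$features
  L <- max(feats$end)
  comp <- spec$composition
  # feasibility of planted overlaps against the coordinate template
  ov <- spec$overlaps
  if (nrow(ov) > 0) {
    for (k in seq_len(nrow(ov))) {
      up <- feats[feats$gene == ov$upstream[k], ]
      down <- feats[feats$gene == ov$downstream[k], ]
      if (nrow(up) != 1 || nrow(down) != 1) {
        abort(paste0("infeasible spec: overlap names unknown gene (",
                     ov$upstream[k], "/", ov$downstream[k], ")"))
      }
      ov_len <- up$end - down$start + 1
      if (ov_len <= 0) {
        abort("infeasible spec: planted overlap at non-overlapping pair")
      }
      lens <- c(up$end - up$start + 1, down$end - down$start + 1)
      if (nchar(ov$motif[k]) != ov_len || ov_len >= min(lens)) {
        abort(paste0("infeasible spec: overlap motif length ",
                     nchar(ov$motif[k]), " does not fit the ", ov_len,
                     "-nt ", ov$upstream[k], "/", ov$downstream[k],
                     " overlap"))
      }
    }
  }
  with_seed(seed, {
    res <- rep(NA_character_, L)
    truth_start_stop <- list()
    cr_truth <- NULL
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      n <- f$end - f$start + 1
      if (f$type == "control_region" && !is.null(spec$cr)) {
        built <- build_cr(n, spec$cr, comp)
        coding <- built$seq
        cr_truth <- built$truth
      } else {
        freq <- comp[[f$type]] %||% comp$intergenic
        coding <- fill_bases(n, freq)
      }
      piece <- paste(coding, collapse = "")
      if (f$strand == "L") piece <- revcomp(piece)
      res[f$start:f$end] <- seq_chars(piece)
    }
    gaps <- which(is.na(res))
    if (length(gaps) > 0) {
      res[gaps] <- fill_bases(length(gaps), comp$intergenic)
    }
    # write a string at coding-local positions from1..from1+len-1 of a
    # feature (L-strand features map to complemented genome positions)
    plant_coding <- function(f, from1, s) {
      chars <- seq_chars(s)
      locs <- from1:(from1 + length(chars) - 1)
      if (f$strand == "H") {
        res[f$start + locs - 1] <<- chars
      } else {
        res[f$end - locs + 1] <<- rev(seq_chars(revcomp(s)))
      }
    }
    # start/stop codons after all fills, so overlapping neighbours cannot
    # erase them; overlap motifs last of all, verbatim on the H strand
    for (i in which(feats$type == "PCG" & !is.na(feats$start_codon))) {
      f <- feats[i, ]
      n <- f$end - f$start + 1
      ncod <- n %/% 3
      plant_coding(f, 1, f$start_codon)
      stop_tok <- f$stop_codon
      if (is.na(stop_tok)) next
      if (stop_tok %in% c("T--", "TA-")) {
        # incomplete stop: non-stop final codon, then the printed tail
        plant_coding(f, 3 * ncod - 2, "ACA")
        tail_res <- sub("-+$", "", stop_tok)
        if (3 * ncod + nchar(tail_res) <= n) {
          plant_coding(f, 3 * ncod + 1, tail_res)
        }
      } else {
        plant_coding(f, 3 * ncod - 2, stop_tok)
      }
      truth_start_stop[[f$gene]] <-
        list(start = f$start_codon, stop = f$stop_codon)
    }
    for (k in seq_len(nrow(ov))) {
      up <- feats[feats$gene == ov$upstream[k], ]
      down <- feats[feats$gene == ov$downstream[k], ]
      res[down$start:up$end] <- seq_chars(ov$motif[k])
    }
    genome <- annotated_genome(
      paste(res, collapse = ""),
      select(feats, "gene", "type", "strand", "start", "end",
             "start_codon", "stop_codon"),
      circular = TRUE, id = id
    )
    truth <- list(
      seed = seed,
      genome_length = L,
      overlaps = if (nrow(ov) > 0) {
        mutate(ov, igs = -nchar(.data$motif))
      } else {
        ov
      },
      cr = cr_truth,
      start_stop = truth_start_stop,
      composition_targets = comp
    )
    list(genome = genome, truth = truth)
  })
}

# control region builder: three domains with their own composition targets,
# planted goose hairpin + I/II anchor + poly-C run
build_cr <- function(n, cr, comp) {
  d1_end <- cr$d1_end
  d3_start <- cr$d3_start
  if (!(d1_end < d3_start - 1 && d3_start <= n)) {
    abort("infeasible spec: CR domain boundaries do not fit the CR length")
  }
  targets <- comp$cr_domains %||%
    list(I = comp$control_region, II = comp$control_region,
         III = comp$control_region)
  v <- rep(NA_character_, n)
  plant <- function(at, motif) {
    stopifnot(at >= 1, at + nchar(motif) - 1 <= n)
    v[at:(at + nchar(motif) - 1)] <<- seq_chars(motif)
  }
  hits <- list()
  if (!is.null(cr$goose_hairpin)) {
    plant(cr$goose_hairpin_at, cr$goose_hairpin)
    hits$goose_hairpin <- c(start = cr$goose_hairpin_at,
                            end = cr$goose_hairpin_at +
                              nchar(cr$goose_hairpin) - 1L)
  }
  anchor_at <- d1_end - nchar(cr$anchor) + 1L
  plant(anchor_at, cr$anchor)
  hits$anchor <- c(start = anchor_at, end = d1_end)
  plant(d3_start, strrep("C", cr$poly_c_len))
  poly_c <- c(start = d3_start, end = d3_start + cr$poly_c_len - 1L)
  # non-C guards so the random fill cannot extend the planted run
  if (d3_start > 1) plant(d3_start - 1L, "A")
  if (d3_start + cr$poly_c_len <= n) plant(d3_start + cr$poly_c_len, "A")
  bounds <- list(I = c(1L, d1_end), II = c(d1_end + 1L, d3_start - 1L),
                 III = c(d3_start, n))
  for (dom in names(bounds)) {
    idx <- bounds[[dom]][1]:bounds[[dom]][2]
    free <- idx[is.na(v[idx])]
    v[free] <- fill_bases(length(free), targets[[dom]],
                          planted = v[idx][!is.na(v[idx])])
  }
  domains <- tibble(
    domain = c("I", "II", "III"),
    start = c(1L, d1_end + 1L, d3_start),
    end = c(d1_end, d3_start - 1L, as.integer(n))
  )
  list(seq = v,
       truth = list(domains = domains, motifs = hits, poly_c = poly_c))
}

#' Parameters for codon-pair evolution
#'
#' @param t Expected mutation proposals per codon along each lineage
#'   (>= 0); the realized substitution counts are logged in the truth.
#' @param kappa Transition/transversion rate ratio of the proposal process
#'   (> 0; 1 = unbiased).
#' @param omega Target dN/dS rate ratio (>= 0); see
#'   [evolve_codon_pair()] for how it maps to acceptance probabilities.
#' @param n_codons Number of codons.
#' @return A list of class `evolve_params`.
#' @export
evolve_params <- function(t = 0.3, kappa = 1, omega = 1, n_codons = 1000) {
  if (t < 0 || kappa <= 0 || omega < 0 || n_codons < 1) {
    abort("invalid evolve parameters (need t >= 0, kappa > 0, omega >= 0)")
  }
  structure(list(t = t, kappa = kappa, omega = omega,
                 n_codons = as.integer(n_codons)),
            class = "evolve_params")
}

#' Evolve a pair of coding sequences from a common ancestor
#'
#' Draws a stop-free ancestor (codons uniform over the 60 sense codons of
#' the code) and evolves two independent lineages by sequential single-site
#' mutation proposals: a random codon, position, and replacement base
#' (transitions weighted `kappa`); proposals creating a stop codon are
#' rejected, synonymous proposals accepted with probability `min(1, 1/omega)`
#' and non-synonymous proposals with probability `min(1, omega)` -- for
#' `omega <= 1` this is acceptance 1 for synonymous changes and `omega` for
#' non-synonymous ones, and for `omega > 1` the synonymous class is thinned
#' instead so the rate ratio equals `omega` throughout.  The realized
#' per-lineage counts of
#' accepted synonymous/non-synonymous changes are logged as ground truth, so
#' recovery tests do not rely on asymptotics.  One private RNG stream per
#' call; equal seeds give identical pairs.
#'
#' @param params An [evolve_params()].
#' @param seed Integer seed.
#' @param code A [mito_genetic_code()].
#' @return A list `cds1`, `cds2` (sequence strings), and `truth` (list with
#'   the ancestor and per-lineage `proposals`, `syn`, `nonsyn`,
#'   `rejected_stop`, `rejected_omega`).
#' @examples
#' pair <- evolve_codon_pair(evolve_params(t = 0.2, omega = 0), seed = 1)
#' pair$truth$lineage1$nonsyn  # 0 by construction
#' @export
evolve_codon_pair <- function(params = evolve_params(), seed = 1,
                              code = mito_genetic_code()) {
  stopifnot(inherits(params, "evolve_params"))
  tabs <- ng86_tables(code)
  sense <- which(!tabs$is_stop)
  aa_idx <- unname(code$aa[index_to_codon(1:64)])
  base_of <- rbind(
    (0:63) %/% 16 + 1,            # pos 1 base index (A,C,G,T = 1..4)
    ((0:63) %/% 4) %% 4 + 1,
    (0:63) %% 4 + 1
  )
  mult <- c(16L, 4L, 1L)
  transition_partner <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  # acceptance probabilities generalized so omega > 1 (positive selection)
  # is representable: non-synonymous min(1, omega), synonymous min(1, 1/omega)
  p_nonsyn <- min(1, params$omega)
  p_syn <- if (params$omega > 1) 1 / params$omega else 1
  with_seed(seed, {
    anc <- sample(sense, params$n_codons, replace = TRUE)
    evolve_lineage <- function(codons) {
      n_prop <- rpois(1, params$t * params$n_codons)
      syn <- 0L; nonsyn <- 0L; rej_stop <- 0L; rej_omega <- 0L
      for (dummy in seq_len(n_prop)) {
        j <- sample.int(params$n_codons, 1)
        pos <- sample.int(3, 1)
        idx <- codons[j]
        cur <- base_of[pos, idx]
        alts <- setdiff(1:4, cur)
        w <- ifelse(alts == transition_partner[cur], params$kappa, 1)
        newb <- alts[sample.int(3, 1, prob = w)]
        new_idx <- idx + (newb - cur) * mult[pos]
        if (tabs$is_stop[new_idx]) { rej_stop <- rej_stop + 1L; next }
        if (aa_idx[new_idx] == aa_idx[idx]) {
          if (runif(1) < p_syn) {
            codons[j] <- new_idx; syn <- syn + 1L
          } else {
            rej_omega <- rej_omega + 1L
          }
        } else if (runif(1) < p_nonsyn) {
          codons[j] <- new_idx; nonsyn <- nonsyn + 1L
        } else {
          rej_omega <- rej_omega + 1L
        }
      }
      list(codons = codons, proposals = n_prop, syn = syn, nonsyn = nonsyn,
           rejected_stop = rej_stop, rejected_omega = rej_omega)
    }
    l1 <- evolve_lineage(anc)
    l2 <- evolve_lineage(anc)
    as_seq <- function(idx) paste(index_to_codon(idx), collapse = "")
    list(
      cds1 = as_seq(l1$codons),
      cds2 = as_seq(l2$codons),
      truth = list(
        seed = seed, params = params, ancestor = as_seq(anc),
        lineage1 = l1[-1], lineage2 = l2[-1]
      )
    )
  })
}

#' Simulate an alignment down a tree under the K80 model
#'
#' Evolves i.i.d. sites from a uniform-base root sequence along every branch
#' of a tree under the Kimura two-parameter substitution process, with
#' branch lengths in expected substitutions per site and transition rate
#' `kappa` times the transversion rate.  Zero-length branches copy their
#' parent sequence unchanged.
#'
#' @param tree An [ape::phylo] tree with non-negative branch lengths.
#' @param sites Number of sites (> 0).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed (one private RNG stream per call).
#' @return A list with `alignment` (tibble `id`, `seq`, one row per tip)
#'   and `truth` (list with the root sequence, `tree`, `kappa`, `seed`).
#' @export
simulate_alignment_on_tree <- function(tree, sites, kappa = 2, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (sites < 1) abort("site count must be positive")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("tree must have non-negative branch lengths")
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  transition_partner <- c(3L, 4L, 1L, 2L)
  with_seed(seed, {
    seqs <- vector("list", n_node)
    seqs[[root]] <- sample.int(4, sites, replace = TRUE)
    # parents precede children in cladewise edge order from the root
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      b <- ord$edge.length[e]
      x <- seqs[[parent]]
      if (b > 0) {
        # K80 transition probabilities at branch length b (subs/site)
        bt <- b / (kappa + 2)          # beta * t
        at <- kappa * bt               # alpha * t
        p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
        p_tv <- 0.25 - 0.25 * exp(-4 * bt)   # each of the two transversions
        u <- runif(sites)
        do_ts <- u < p_ts
        do_tv <- !do_ts & (u < p_ts + 2 * p_tv)
        x[do_ts] <- transition_partner[x[do_ts]]
        if (any(do_tv)) {
          cur <- x[do_tv]
          pick <- sample.int(2, sum(do_tv), replace = TRUE)
          # the two transversion targets of each base, in base-index space
          tv_targets <- matrix(c(2L, 4L, 1L, 3L, 2L, 4L, 1L, 3L), nrow = 4,
                               byrow = TRUE)   # A->C/T, C->A/G, G->C/T, T->A/G
          x[do_tv] <- tv_targets[cbind(cur, pick)]
        }
      }
      seqs[[child]] <- x
    }
    to_str <- function(v) paste(bases4[v], collapse = "")
    list(
      alignment = tibble(
        id = tree$tip.label,
        seq = vapply(seqs[seq_len(n_tip)], to_str, character(1))
      ),
      truth = list(root_seq = to_str(seqs[[root]]), tree = tree,
                   kappa = kappa, seed = seed, sites = sites)
    )
  })
}
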