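#' Default control-region motif set
#'
#' Ships the two avian control-region motifs printed for the ring-necked
#' pheasant: the goose-hairpin block
#' (`TACCCCCCCTTTCCCCCCCAGGGGGGGTA`, domain I part A) and the CSB1-like
#' block (`ATACTATGAATGGTTACAGGACATA`, domain I part B).  The CSB1-like
#' block doubles as the default domain I/II boundary anchor; consensus
#' entries for ETAS1/ETAS2 and boxes C-F vary across lineages and are meant
#' to be appended by the user.
#'
#' @return A tibble `name`, `seq`, `min_identity`, `role` with roles in
#'   `anchor_I_II`, `anchor_II_III`, `landmark`.
#' @export
default_cr_motifs <- function() {
  tibble(
    name = c("goose_hairpin", "CSB1-like"),
    seq = c("TACCCCCCCTTTCCCCCCCAGGGGGGGTA", "ATACTATGAATGGTTACAGGACATA"),
    min_identity = c(90, 80),
    role = c("landmark", "anchor_I_II")
  )
}

#' Scan a sequence for a motif by ungapped sliding window
#'
#' Slides the motif over every offset of the sequence and reports windows
#' whose positional identity (`matches / motif length * 100`) reaches
#' `min_identity`.  Hits are sorted by identity (descending) then start
#' (ascending), so a verbatim occurrence always ranks first.
#'
#' @param cr Sequence string (typically a control region).
#' @param motif Motif string; must not be longer than `cr`.
#' @param min_identity Minimum percent identity to report (default 70).
#' @param name Motif label carried into the result.
#' @return A tibble `motif`, `query`, `start`, `end` (1-based inclusive,
#'   local to `cr`), `identity`.  Zero rows when nothing reaches the
#'   threshold.
#' @examples
#' find_motif("AAATTTGGG", "TTTGG", min_identity = 100)
#' @export
find_motif <- function(cr, motif, min_identity = 70, name = motif) {
  stopifnot(is.character(cr), length(cr) == 1,
            is.character(motif), length(motif) == 1)
  cr <- toupper(cr); motif <- toupper(motif)
  n <- nchar(cr); m <- nchar(motif)
  if (m > n) abort("motif longer than the scanned sequence")
  crv <- seq_chars(cr)
  mv <- seq_chars(motif)
  n_win <- n - m + 1
  matches <- integer(n_win)
  for (k in seq_len(m)) {
    matches <- matches + (crv[k:(k + n_win - 1)] == mv[k])
  }
  identity <- 100 * matches / m
  keep <- which(identity >= min_identity)
  tibble(
    motif = name,
    query = motif,
    start = keep,
    end = keep + m - 1L,
    identity = identity[keep]
  ) |>
    arrange(dplyr::desc(.data$identity), .data$start)
}

# longest homopolymer run of `base` with length >= min_len; leftmost on ties
longest_run <- function(seq, base = "C", min_len = 6) {
  r <- rle(seq_chars(toupper(seq)))
  idx <- which(r$values == base & r$lengths >= min_len)
  if (length(idx) == 0) return(NULL)
  best <- idx[which.max(r$lengths[idx])]   # which.max is leftmost on ties
  start <- sum(r$lengths[seq_len(best - 1)]) + 1L
  c(start = start, end = start + r$lengths[best] - 1L)
}

#' Segment a control region into its three domains
#'
#' Vertebrate mitochondrial control regions divide into a variable domain I
#' carrying the extended termination-associated sequences (ETAS), a
#' conserved central domain II, and domain III carrying the conserved
#' sequence blocks (CSB) near the origin of H-strand replication (OH).
#' Boundaries here are anchored on recognizable motifs: domain I runs from
#' the CR start to the end of the best hit of the I/II anchor motif, domain
#' III starts at the II/III anchor when one is configured and otherwise at
#' the start of the poly-C run (the OH-adjacent landmark), and domain II is
#' everything between.  The three domains always tile the CR exactly.
#'
#' @param cr Control-region sequence string (CR-local coordinates).
#' @param motifs Motif configuration tibble as from [default_cr_motifs()]:
#'   columns `name`, `seq`, `min_identity`, `role` (`anchor_I_II`,
#'   `anchor_II_III`, or `landmark`).
#' @param poly_c_min Minimum length for the poly-C run (default 6).
#' @return An object of class `cr_annotation`: list with `length`,
#'   `domains` (tibble `domain`, `start`, `end`), `hits` (best hit per
#'   configured motif plus any further hits), and `poly_c`
#'   (named vector `start`, `end`, or `NULL`).
#' @examples
#' cr <- paste0(
#'   strrep("AT", 30), "ATACTATGAATGGTTACAGGACATA",
#'   strrep("TA", 40), "CCCCCCCC", strrep("AT", 20)
#' )
#' segment_domains(cr)$domains
#' @export
segment_domains <- function(cr, motifs = default_cr_motifs(),
                            poly_c_min = 6) {
  stopifnot(is.character(cr), length(cr) == 1)
  cr <- toupper(cr)
  n <- nchar(cr)
  motifs <- as_tibble(motifs)
  hits <- purrr::pmap(motifs, function(name, seq, min_identity, role, ...) {
    h <- find_motif(cr, seq, min_identity, name = name)
    if (nrow(h) > 0) h$role <- role
    h
  }) |> bind_rows()
  if (!"role" %in% names(hits)) hits$role <- character(0)
  best_of <- function(role) {
    h <- hits[hits$role == role, , drop = FALSE]
    if (nrow(h) == 0) NULL else h[1, ]
  }
  a1 <- best_of("anchor_I_II")
  if (is.null(a1)) {
    abort(
      paste0("segmentation failed: no hit for domain I/II anchor (",
             paste(motifs$name[motifs$role == "anchor_I_II"], collapse = ", "),
             ")"),
      class = "mitochar_segmentation_failed"
    )
  }
  poly_c <- longest_run(cr, "C", poly_c_min)
  a2 <- best_of("anchor_II_III")
  d3_start <- if (!is.null(a2)) {
    a2$start
  } else if (!is.null(poly_c)) {
    poly_c[["start"]]
  } else {
    abort("segmentation failed: no domain II/III anchor and no poly-C run",
          class = "mitochar_segmentation_failed")
  }
  d1_end <- a1$end
  if (d1_end + 1 >= d3_start || d3_start > n) {
    abort("segmentation failed: degenerate domain II (anchors too close)",
          class = "mitochar_segmentation_failed")
  }
  domains <- tibble(
    domain = c("I", "II", "III"),
    start = c(1L, d1_end + 1L, as.integer(d3_start)),
    end = c(d1_end, as.integer(d3_start) - 1L, n)
  )
  structure(
    list(length = n, domains = domains, hits = hits, poly_c = poly_c),
    class = "cr_annotation"
  )
}

#' @export
print.cr_annotation <- function(x, ...) {
  cat("<cr_annotation> ", x$length, " bp control region\n", sep = "")
  print(x$domains)
  if (!is.null(x$poly_c)) {
    cat("poly-C run: ", x$poly_c[["start"]], "-", x$poly_c[["end"]], "\n",
        sep = "")
  }
  if (nrow(x$hits)) {
    cat("motif hits:\n")
    print(x$hits)
  }
  invisible(x)
}

#' @describeIn segment_domains Tidy the annotation into a single interval
#'   table (domains, motif hits, poly-C run) in CR-local coordinates.
#' @param x A `cr_annotation`.
#' @param ... Unused.
#' @method tidy cr_annotation
#' @export
tidy.cr_annotation <- function(x, ...) {
  out <- bind_rows(
    tibble(feature = paste0("Domain ", x$domains$domain), kind = "domain",
           start = x$domains$start, end = x$domains$end,
           identity = NA_real_),
    if (nrow(x$hits) > 0) {
      tibble(feature = x$hits$motif, kind = "motif",
             start = x$hits$start, end = x$hits$end,
             identity = x$hits$identity)
    },
    if (!is.null(x$poly_c)) {
      tibble(feature = "poly-C", kind = "landmark",
             start = x$poly_c[["start"]], end = x$poly_c[["end"]],
             identity = NA_real_)
    }
  )
  out
}
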