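bases4 <- c("A", "C", "G", "T")

codon_to_index <- function(codons) {
  m <- match(
    c(substr(codons, 1, 1), substr(codons, 2, 2), substr(codons, 3, 3)),
    bases4
  )
  k <- length(codons)
  b1 <- m[seq_len(k)]; b2 <- m[k + seq_len(k)]; b3 <- m[2 * k + seq_len(k)]
  (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
}

index_to_codon <- function(idx) {
  idx <- idx - 1L
  paste0(bases4[idx %/% 16 + 1], bases4[(idx %/% 4) %% 4 + 1],
         bases4[idx %% 4 + 1])
}

# Lookup tables for NG86 counting under a genetic code:
#   s_sites[i]  fractional synonymous sites of codon i (NA for stops)
#   sd[i, j], nd[i, j]  pathway-averaged synonymous / non-synonymous
#     differences between codons i and j (equal-weight average over all
#     orderings of the differing positions; orderings that pass through a
#     stop codon are discarded; when every ordering is discarded the pair
#     falls back to direct per-position synonymy on the first codon's
#     background)
ng86_tables <- function(code = mito_genetic_code()) {
  key <- paste0("ng86_", code$id)
  if (!is.null(.mitochar_cache[[key]])) return(.mitochar_cache[[key]])
  codons <- index_to_codon(1:64)
  aa <- unname(code$aa[codons])
  is_stop <- aa == "*"
  neighbours <- function(i, pos) {
    cod <- seq_chars(codons[i])
    vapply(setdiff(bases4, cod[pos]), function(b) {
      cod2 <- cod; cod2[pos] <- b
      codon_to_index(paste(cod2, collapse = ""))
    }, integer(1))
  }
  s_sites <- rep(NA_real_, 64)
  for (i in which(!is_stop)) {
    s <- 0
    for (pos in 1:3) {
      nb <- neighbours(i, pos)
      valid <- nb[!is_stop[nb]]
      if (length(valid) > 0) s <- s + sum(aa[valid] == aa[i]) / length(valid)
    }
    s_sites[i] <- s
  }
  sd <- matrix(0, 64, 64)
  nd <- matrix(0, 64, 64)
  perms_of <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in which(!is_stop)) {
    ci <- seq_chars(codons[i])
    for (j in which(!is_stop)) {
      if (j <= i) next
      cj <- seq_chars(codons[j])
      diffpos <- which(ci != cj)
      d <- length(diffpos)
      if (d == 0) next
      tot_s <- 0; tot_n <- 0; n_valid <- 0
      for (ord in perms_of[[as.character(d)]]) {
        cur <- ci
        cur_idx <- i
        path_s <- 0; path_n <- 0
        ok <- TRUE
        for (p in diffpos[ord]) {
          nxt <- cur; nxt[p] <- cj[p]
          nxt_idx <- codon_to_index(paste(nxt, collapse = ""))
          if (is_stop[nxt_idx] && nxt_idx != j) { ok <- FALSE; break }
          if (aa[nxt_idx] == aa[cur_idx]) path_s <- path_s + 1
          else path_n <- path_n + 1
          cur <- nxt; cur_idx <- nxt_idx
        }
        if (ok) {
          tot_s <- tot_s + path_s; tot_n <- tot_n + path_n
          n_valid <- n_valid + 1
        }
      }
      if (n_valid > 0) {
        sd[i, j] <- tot_s / n_valid
        nd[i, j] <- tot_n / n_valid
      } else {
        # all orderings blocked by stops: split raw differences by
        # direct-position synonymy on codon i's background
        for (p in diffpos) {
          mut <- ci; mut[p] <- cj[p]
          mut_idx <- codon_to_index(paste(mut, collapse = ""))
          if (!is_stop[mut_idx] && aa[mut_idx] == aa[i]) {
            sd[i, j] <- sd[i, j] + 1
          } else {
            nd[i, j] <- nd[i, j] + 1
          }
        }
      }
      sd[j, i] <- sd[i, j]
      nd[j, i] <- nd[i, j]
    }
  }
  out <- list(s_sites = s_sites, sd = sd, nd = nd, is_stop = is_stop)
  .mitochar_cache[[key]] <- out
  out
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) abort("CDS length is not a multiple of 3")
  if (n == 0) abort("empty CDS")
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Nei-Gojobori synonymous and non-synonymous site counts
#'
#' For each codon, each of the three positions contributes the fraction of
#' its single-nucleotide mutants (mutants creating stop codons excluded from
#' the denominator) that are synonymous; the synonymous site count S is the
#' sum of these fractions and the non-synonymous count is N = 3 x codons - S.
#'
#' @param cds Coding-strand sequence, length a multiple of 3, with no
#'   internal stop codons.  Codons containing non-ACGT characters are
#'   skipped.
#' @param code A [mito_genetic_code()].
#' @return A named numeric vector `c(N = , S = )` with
#'   `N + S == 3 * (number of counted codons)`.
#' @examples
#' ng86_site_counts("TTT")  # Phe: S = 1/3, N = 8/3
#' @export
ng86_site_counts <- function(cds, code = mito_genetic_code()) {
  tabs <- ng86_tables(code)
  codons <- split_codons(toupper(cds))
  clean <- !grepl("[^ACGT]", codons)
  idx <- codon_to_index(codons[clean])
  if (any(tabs$is_stop[idx])) {
    at <- which(clean)[which(tabs$is_stop[idx])[1]]
    abort(paste0("internal stop codon at codon ", at))
  }
  S <- sum(tabs$s_sites[idx])
  c(N = 3 * length(idx) - S, S = S)
}

#' Nei-Gojobori (NG86) Ka/Ks for an aligned codon pair
#'
#' Estimates the non-synonymous (Ka) and synonymous (Ks) substitution rates
#' between two pre-aligned, stop-free coding sequences by the Nei-Gojobori
#' (1986) counting method: synonymous and non-synonymous sites are counted
#' per [ng86_site_counts()] and averaged between the two sequences;
#' differences at each differing codon pair are averaged with equal weight
#' over all orderings of the changed positions (orderings passing through a
#' stop codon are discarded); the proportions `pN = Nd/N`, `pS = Sd/S` are
#' corrected for multiple hits with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - 4p/3)`.  `Ka/Ks < 1` indicates purifying selection,
#' `= 1` neutral evolution, `> 1` positive selection.
#'
#' @param cds1,cds2 Aligned coding-strand sequences of equal length (a
#'   multiple of 3), stop-free.  Codon pairs in which either codon contains
#'   a non-ACGT character (alignment gap, ambiguity) are dropped pairwise.
#' @param code A [mito_genetic_code()].
#' @param neutral_tol Half-width of the reporting band around 1 within which
#'   the ratio is called `neutral` (default 0.05).
#' @return An object of class `kaks_result`: list with `n_codons`, `N`,
#'   `S`, `Nd`, `Sd`, `pN`, `pS`, `ka`, `ks`, `ratio` (NA when Ks is 0 or a
#'   proportion saturates the correction), and `class` (`purifying`,
#'   `neutral`, `positive`, `undefined`).  See [tidy.kaks_result()].
#' @examples
#' r <- ng86_kaks(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
#' r$ks  # about 0.3831
#' @export
ng86_kaks <- function(cds1, cds2, code = mito_genetic_code(),
                      neutral_tol = 0.05) {
  tabs <- ng86_tables(code)
  c1 <- split_codons(toupper(cds1))
  c2 <- split_codons(toupper(cds2))
  if (length(c1) != length(c2)) abort("aligned CDSs differ in length")
  clean <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  i1 <- codon_to_index(c1[clean])
  i2 <- codon_to_index(c2[clean])
  stop_hit <- tabs$is_stop[i1] | tabs$is_stop[i2]
  if (any(stop_hit)) {
    abort(paste0("internal stop codon at codon ",
                 which(clean)[which(stop_hit)[1]]))
  }
  n_cod <- length(i1)
  if (n_cod == 0) abort("no comparable codons after filtering")
  S <- (sum(tabs$s_sites[i1]) + sum(tabs$s_sites[i2])) / 2
  N <- 3 * n_cod - S
  Sd <- sum(tabs$sd[cbind(i1, i2)])
  Nd <- sum(tabs$nd[cbind(i1, i2)])
  pN <- Nd / N
  pS <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ka <- jc(pN)
  ks <- jc(pS)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  cls <- if (is.na(ratio)) {
    "undefined"
  } else if (abs(ratio - 1) < neutral_tol) {
    "neutral"
  } else if (ratio < 1) {
    "purifying"
  } else {
    "positive"
  }
  structure(
    list(n_codons = n_cod, N = N, S = S, Nd = Nd, Sd = Sd,
         pN = pN, pS = pS, ka = ka, ks = ks, ratio = ratio, class = cls),
    class = "kaks_result"
  )
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("<kaks_result> ", x$n_codons, " codons\n", sep = "")
  cat(sprintf("  N = %.2f, S = %.2f, Nd = %.2f, Sd = %.2f\n",
              x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s (%s)\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$ratio, digits = 4), x$class))
  invisible(x)
}

#' Tidy a Ka/Ks result
#'
#' @param x A `kaks_result` from [ng86_kaks()].
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with columns `n_codons`, `N`, `S`,
#'   `Nd`, `Sd`, `pN`, `pS`, `ka`, `ks`, `ratio`, `class` (fixed order, the
#'   package's per-gene-pair report row).  `glance()`: `ka`, `ks`, `ratio`,
#'   `class`, `n_codons`.
#' @method tidy kaks_result
#' @export
tidy.kaks_result <- function(x, ...) {
  tibble(
    n_codons = x$n_codons, N = x$N, S = x$S, Nd = x$Nd, Sd = x$Sd,
    pN = x$pN, pS = x$pS, ka = x$ka, ks = x$ks, ratio = x$ratio,
    class = x$class
  )
}

#' @rdname tidy.kaks_result
#' @method glance kaks_result
#' @export
glance.kaks_result <- function(x, ...) {
  tibble(ka = x$ka, ks = x$ks, ratio = x$ratio, class = x$class,
         n_codons = x$n_codons)
}
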