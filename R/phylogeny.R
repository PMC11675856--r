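#' Pairwise sequence distance
#'
#' Evolutionary distance between two aligned sequences.  Sites where either
#' sequence has a non-ACGT character (gap, ambiguity, N) are excluded
#' pairwise.  `method = "p"` is the raw proportion of differing sites;
#' `method = "k2p"` is the Kimura two-parameter distance
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with `P` the transition
#' (A/G, C/T) and `Q` the transversion proportion per comparable site.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @param method `"p"` or `"k2p"`.
#' @return A single non-negative number.
#' @examples
#' pairwise_distance("ACGT", "ACGA", "p")  # 0.25
#' @export
pairwise_distance <- function(a, b, method = c("p", "k2p")) {
  method <- match.arg(method)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) abort("aligned sequences differ in length")
  va <- seq_chars(toupper(a))
  vb <- seq_chars(toupper(b))
  ok <- va %in% bases4 & vb %in% bases4
  n <- sum(ok)
  if (n == 0) abort("no comparable sites")
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  if (method == "p") {
    return(sum(diff) / n)
  }
  purine <- c("A", "G")
  transition <- diff & ((va %in% purine) == (vb %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  argument <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (argument <= 0) {
    abort("K2P distance undefined: sequences saturated (log argument <= 0)")
  }
  -0.5 * log(argument)
}

#' Pairwise distance matrix of an alignment
#'
#' @param alignment A tibble with columns `id`, `seq` (as from
#'   [read_fasta()]) or a named character vector of equal-length aligned
#'   sequences.  Per-gene alignments of the same taxa can be concatenated
#'   with [concat_alignments()] beforehand.
#' @param method Passed to [pairwise_distance()].
#' @return A symmetric numeric matrix with zero diagonal and taxon labels
#'   as dimnames.
#' @export
distance_matrix <- function(alignment, method = c("p", "k2p")) {
  method <- match.arg(method)
  if (is.data.frame(alignment)) {
    alignment <- setNames(alignment$seq, alignment$id)
  }
  if (length(unique(nchar(alignment))) != 1) {
    abort("ragged alignment (unequal sequence lengths)")
  }
  k <- length(alignment)
  labels <- names(alignment) %||% paste0("t", seq_len(k))
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k >= 2) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        d[i, j] <- d[j, i] <-
          pairwise_distance(alignment[[i]], alignment[[j]], method)
      }
    }
  }
  d
}

#' Concatenate per-gene alignments over shared taxa
#'
#' @param ... Alignments (tibbles with `id`, `seq`, or named character
#'   vectors) over the same taxon set.
#' @return A tibble `id`, `seq` with sequences joined gene by gene.
#' @export
concat_alignments <- function(...) {
  parts <- lapply(list(...), function(a) {
    if (is.data.frame(a)) setNames(a$seq, a$id) else a
  })
  ids <- names(parts[[1]])
  for (p in parts[-1]) {
    if (!setequal(names(p), ids)) abort("alignments have different taxa")
  }
  tibble(
    id = ids,
    seq = unname(vapply(ids, function(i) {
      paste(vapply(parts, `[[`, character(1), i), collapse = "")
    }, character(1)))
  )
}

#' Build a distance tree
#'
#' Neighbor joining (Saitou & Nei's Q-criterion, exact on additive
#' matrices, unrooted) or UPGMA (average-linkage clustering, rooted and
#' ultrametric).  NJ occasionally yields negative branch lengths on noisy
#' matrices; by default these are clamped to zero with the deficit
#' transferred to the sibling branch so path lengths through the parent
#' node are preserved.
#'
#' @param d A symmetric distance matrix (see [distance_matrix()]).
#' @param method `"nj"` (needs >= 3 taxa) or `"upgma"` (>= 2).
#' @param clamp_negative Clamp negative NJ branch lengths (default `TRUE`).
#' @return An [ape::phylo] tree.
#' @export
tree_build <- function(d, method = c("nj", "upgma"), clamp_negative = TRUE) {
  method <- match.arg(method)
  if (!isSymmetric(unname(d))) abort("distance matrix is not symmetric")
  k <- nrow(d)
  if (method == "nj") {
    if (k < 3) abort("NJ needs at least 3 taxa")
    tree <- ape::nj(stats::as.dist(d))
    if (clamp_negative && any(tree$edge.length < 0)) {
      tree <- clamp_negative_edges(tree)
    }
    tree
  } else {
    if (k < 2) abort("UPGMA needs at least 2 taxa")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
  }
}

# zero out negative edges, moving the deficit onto the sibling edge so the
# sibling-to-sibling path length is unchanged
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
    if (tree$edge.length[sibs[1]] < 0 && length(neg) == 1) {
      # irreducibly negative: truncate rather than loop forever
      tree$edge.length[tree$edge.length < 0] <- 0
      break
    }
  }
  tree
}

#' Test a set of tips for monophyly
#'
#' @param tree An [ape::phylo] tree.
#' @param taxa Character vector of tip labels.
#' @param outgroup Optional tip label used to root an unrooted tree before
#'   testing.
#' @return `TRUE` iff `taxa` form a complete clade of the (rooted) tree.
#' @export
is_monophyletic <- function(tree, taxa, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown tip label(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    abort("tree is unrooted; supply an outgroup")
  }
  ape::is.monophyletic(tree, taxa)
}

#' Define a node-age calibration
#'
#' @param tip1,tip2 Two tip labels whose most recent common ancestor is the
#'   calibrated node.
#' @param age_min,age_max Age bounds in Mya; a point calibration repeats the
#'   same value.  Interval calibrations are used at their midpoint.
#' @return A one-row tibble `tip1`, `tip2`, `age_min`, `age_max`, `age`.
#' @examples
#' calibration("Gallus_gallus", "Gallus_sonneratii", 7.1, 9.6)
#' @export
calibration <- function(tip1, tip2, age_min, age_max = age_min) {
  if (age_min > age_max) abort("age_min > age_max")
  tibble(tip1 = tip1, tip2 = tip2, age_min = age_min, age_max = age_max,
         age = (age_min + age_max) / 2)
}

#' Strict-clock node dating of an ultrametric tree
#'
#' Under a strict molecular clock, node depth (substitutions per site from
#' the node to any descendant tip of an ultrametric tree) is proportional to
#' node age.  Given one or more fossil calibrations (tip pairs defining
#' calibrated ancestors, interval calibrations collapsed to midpoints), the
#' substitution rate is the least-squares fit of calibration-node depth
#' against calibration age through the origin; every node age is then its
#' depth divided by that rate.  With a single calibration this is exact
#' linear scaling.  Ages are therefore unchanged when all branch lengths are
#' rescaled by a constant.
#'
#' @param tree A rooted ultrametric [ape::phylo] tree (e.g. from UPGMA).
#' @param calibrations A tibble of [calibration()] rows.
#' @param tol Ultrametricity tolerance (relative, default 1e-6).
#' @param max_rel_residual Warn when any calibration's relative age residual
#'   exceeds this bound (default 0.1).
#' @return An object of class `time_tree`: list with `tree` (input tree),
#'   `tree_mya` (branch lengths rescaled to Mya), `rate` (substitutions per
#'   site per Mya), `ages` (numeric vector of node ages in Mya indexed by
#'   node number, tips 0), and `calibrations` (with fitted ages and
#'   residuals).  See [tidy.time_tree()].
#' @export
strict_clock_dates <- function(tree, calibrations, tol = 1e-6,
                               max_rel_residual = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (!ape::is.ultrametric(tree, tol = tol)) {
    abort("tree is not ultrametric within tolerance")
  }
  calibrations <- as_tibble(calibrations)
  if (nrow(calibrations) == 0) abort("need at least one calibration")
  n_tip <- length(tree$tip.label)
  heights <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  depth <- max(heights[seq_len(n_tip)]) - heights
  depth[seq_len(n_tip)] <- 0
  cal_node <- vapply(seq_len(nrow(calibrations)), function(i) {
    ape::getMRCA(tree, c(calibrations$tip1[i], calibrations$tip2[i]))
  }, integer(1))
  cal_depth <- depth[cal_node]
  if (any(cal_depth <= 0)) {
    abort("calibration node has zero depth (calibrated tips coincide)")
  }
  age <- calibrations$age
  rate <- sum(cal_depth * age) / sum(age^2)
  ages <- depth / rate
  fitted <- cal_depth / rate
  rel_res <- abs(fitted - age) / age
  if (any(rel_res > max_rel_residual)) {
    warn(paste0(
      "calibrations are mutually inconsistent; relative residuals: ",
      paste(sprintf("%.3f", rel_res), collapse = ", ")
    ))
  }
  tree_mya <- tree
  tree_mya$edge.length <- tree$edge.length / rate
  structure(
    list(
      tree = tree, tree_mya = tree_mya, rate = rate, ages = ages,
      calibrations = mutate(calibrations, node = cal_node,
                            fitted_age = fitted, rel_residual = rel_res)
    ),
    class = "time_tree"
  )
}

#' @export
print.time_tree <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  cat("<time_tree> ", n_tip, " tips, rate ",
      format(x$rate, digits = 4), " subst/site/Mya, root age ",
      format(max(x$ages), digits = 4), " Mya\n", sep = "")
  invisible(x)
}

#' Tidy a dated tree
#'
#' @param x A `time_tree` from [strict_clock_dates()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per node: `node`, `label` (tip
#'   label or `NA`), `is_tip`, `age` (Mya).  `glance()`: one row with
#'   `rate`, `root_age`, `n_tips`, `n_calibrations`.
#' @method tidy time_tree
#' @export
tidy.time_tree <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  n_node <- n_tip + x$tree$Nnode
  tibble(
    node = seq_len(n_node),
    label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
    is_tip = seq_len(n_node) <= n_tip,
    age = x$ages
  )
}

#' @rdname tidy.time_tree
#' @method glance time_tree
#' @export
glance.time_tree <- function(x, ...) {
  tibble(
    rate = x$rate,
    root_age = max(x$ages),
    n_tips = length(x$tree$tip.label),
    n_calibrations = nrow(x$calibrations)
  )
}
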