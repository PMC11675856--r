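#' RSCU bar chart by synonymous family
#'
#' The conventional stacked presentation of relative synonymous codon usage:
#' one bar per synonymous family (amino acid, with the two leucine and
#' serine families separate), stacked by codon, RSCU on the y axis.
#'
#' @param table A `codon_usage` tibble carrying an `rscu` column (see
#'   [rscu()]).
#' @return A ggplot object.
#' @export
plot_rscu <- function(table) {
  stopifnot("rscu" %in% names(table))
  dat <- filter(table, .data$family != "Stop", .data$count > 0 |
                  .data$family_used)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$family, y = .data$rscu,
                                    fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2,
                      show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$codon),
                       position = ggplot2::position_stack(vjust = 0.5),
                       size = 2.2) +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot codon_usage
#' @export
autoplot.codon_usage <- function(object, ...) {
  if (!"rscu" %in% names(object)) object <- rscu(object)
  plot_rscu(object)
}

#' Skew profile of a composition report
#'
#' AT and GC skews per partition, the strand-asymmetry summary of a
#' partitioned composition table.
#'
#' @param report A tibble from [partition_report()].
#' @return A ggplot object.
#' @export
plot_skew <- function(report) {
  dat <- report |>
    select("partition", "at_skew", "gc_skew") |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"), names_to = "skew",
                        values_to = "value") |>
    mutate(partition = factor(.data$partition,
                              levels = unique(report$partition)),
           skew = dplyr::recode(.data$skew, at_skew = "AT skew",
                                gc_skew = "GC skew"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$partition, y = .data$value,
                                    fill = .data$skew)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "skew", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method autoplot cr_annotation
#' @export
autoplot.cr_annotation <- function(object, ...) {
  dat <- tidy(object)
  dat$track <- factor(dat$kind, levels = c("domain", "motif", "landmark"))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$track,
                   yend = .data$track, colour = .data$feature),
      linewidth = 6
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$start + .data$end) / 2, y = .data$track,
                   label = .data$feature),
      vjust = -1.2, size = 2.8
    ) +
    ggplot2::labs(x = "control-region position (nt)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Tidy an annotated genome into its feature table
#'
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @return `tidy()`: the feature tibble with computed lengths.  `glance()`:
#'   a one-row summary (`id`, `length`, `circular`, feature counts by
#'   type).
#' @method tidy mito_genome
#' @export
tidy.mito_genome <- function(x, ...) {
  x$features
}

#' @rdname tidy.mito_genome
#' @method glance mito_genome
#' @export
glance.mito_genome <- function(x, ...) {
  counts <- table(factor(x$features$type, levels = feature_types))
  tibble(
    id = x$id, length = x$length, circular = x$circular,
    n_features = nrow(x$features),
    n_pcg = as.integer(counts[["PCG"]]),
    n_trna = as.integer(counts[["tRNA"]]),
    n_rrna = as.integer(counts[["rRNA"]]),
    n_control_region = as.integer(counts[["control_region"]])
  )
}
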