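# ggplot2 views of scan, duplication and expression results.

#' @importFrom ggplot2 ggplot aes geom_col geom_tile geom_errorbar geom_line
#'   geom_point facet_wrap labs scale_fill_gradient theme_minimal autoplot
NULL

#' Plot a sequence-logo profile
#'
#' Stacked per-position bars: each residue's bar height is its frequency
#' times the column's information content, the classic logo scaling.
#'
#' @param object A `ccch_logo` from [build_logo()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ccch_logo
#' @export
autoplot.ccch_logo <- function(object, ...) {
  df <- tidy(object) %>%
    filter(.data$freq > 0) %>%
    mutate(height = .data$freq * .data$ic)
  ggplot(df, aes(x = .data$position, y = .data$height,
                 fill = .data$residue)) +
    geom_col(width = 0.9, colour = NA) +
    labs(x = "alignment position", y = "information content (bits)",
         fill = "residue",
         title = paste(object$signatures, collapse = " + ")) +
    theme_minimal()
}

#' Plot motif class tallies
#'
#' @param tally Output of [tally_classes()].
#' @return A ggplot bar chart of counts per spacer signature.
#' @export
plot_class_tally <- function(tally) {
  ggplot(tally, aes(x = stats::reorder(.data$signature, -.data$count),
                    y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "motifs") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot duplication dates by pair
#'
#' @param dup_table Output of [duplicate_pair_table()].
#' @return A ggplot of dates (Mya) coloured by duplicate type.
#' @export
plot_duplication_dates <- function(dup_table) {
  ggplot(dup_table, aes(x = stats::reorder(.data$pair, .data$date_mya),
                        y = .data$date_mya, fill = .data$duplicate_type)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "duplication date (Mya)", fill = "type") +
    theme_minimal()
}

#' Plot relative expression with SE bars
#'
#' @param results Output of [delta_delta_ct()] or [tissue_profile()].
#' @return A ggplot of fold changes per condition, faceted by gene.
#' @export
plot_expression <- function(results) {
  ggplot(results, aes(x = .data$condition, y = .data$fold)) +
    geom_col(fill = "grey40") +
    geom_errorbar(aes(ymin = .data$fold - .data$se,
                      ymax = .data$fold + .data$se), width = 0.25) +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = NULL, y = expression(2^{-Delta * Delta * C[T]})) +
    theme_minimal()
}
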