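# broom-style tidiers for the package's result objects.

#' Tidy a sequence-logo profile
#'
#' @param x A `ccch_logo`.
#' @param ... Unused.
#' @return Tibble (`position`, `residue`, `freq`, `ic`, `n`).
#' @method tidy ccch_logo
#' @export
tidy.ccch_logo <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 20),
    residue = rep(rownames(x$freq), times = x$width),
    freq = as.numeric(x$freq),
    ic = rep(x$ic, each = 20),
    n = rep(x$n, each = 20)
  )
}

#' One-row summary of a logo profile
#'
#' @param x A `ccch_logo`.
#' @param ... Unused.
#' @return Tibble (`n_motifs`, `width`, `mean_ic`, `max_ic`, `signatures`).
#' @method glance ccch_logo
#' @export
glance.ccch_logo <- function(x, ...) {
  tibble(
    n_motifs = x$n_motifs,
    width = x$width,
    mean_ic = mean(x$ic),
    max_ic = max(x$ic),
    signatures = paste(x$signatures, collapse = "+")
  )
}

#' @export
generics::tidy

#' @export
generics::glance
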