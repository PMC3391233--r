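# CCCH zinc-finger motif scanning under the degenerate-spacer consensus
# C-Xa-C-Xb-C-X3-H, with class tallies and sequence-logo profiles.

#' Spacer bounds for the CCCH consensus
#'
#' The consensus matched by the scanner is `C-Xa-C-Xb-C-Xc-H`, where the
#' spacers `a` and `b` vary within bounds and `c` is fixed. The defaults
#' (`a` in 4..17, `b` in 4..6, `c = 3`) cover the canonical plant consensus
#' `C-X4-15-C-X4-6-C-X3-H` widened to admit the rare `C-X17-C-X6-C-X3-H`
#' variant observed in maize.
#'
#' @param a_min,a_max Bounds on the first spacer length.
#' @param b_min,b_max Bounds on the second spacer length.
#' @param c Fixed third spacer length.
#' @return A list of class `ccch_bounds`.
#' @export
#' @examples
#' ccch_bounds()
#' ccch_bounds(a_max = 15) # the stricter historical consensus
ccch_bounds <- function(a_min = 4, a_max = 17, b_min = 4, b_max = 6, c = 3) {
  stopifnot(a_min >= 1, a_min <= a_max, b_min >= 1, b_min <= b_max, c >= 1)
  structure(list(a_min = a_min, a_max = a_max,
                 b_min = b_min, b_max = b_max, c = c),
            class = "ccch_bounds")
}

#' @export
print.ccch_bounds <- function(x, ...) {
  cat(sprintf("CCCH consensus bounds: C-X%d-%d-C-X%d-%d-C-X%d-H\n",
              x$a_min, x$a_max, x$b_min, x$b_max, x$c))
  invisible(x)
}

#' Render a spacer signature
#'
#' Deterministic class label for a motif with spacers `(a, b, c)`, e.g.
#' `"C-X8-C-X5-C-X3-H"`.
#'
#' @param a,b,c Spacer lengths.
#' @return Character vector of signatures.
#' @export
#' @examples
#' motif_signature(8, 5) # the most common class in maize
motif_signature <- function(a, b, c = 3) {
  sprintf("C-X%d-C-X%d-C-X%d-H", a, b, c)
}

# All candidate (C, C, C, H) parses satisfying the bounds, unresolved.
# Positions are 1-based; end - start = a + b + c + 3.
ccch_candidates <- function(chars, bounds) {
  n <- length(chars)
  is_c <- chars == "C"
  is_h <- chars == "H"
  out <- list()
  c_pos <- which(is_c)
  for (i in c_pos) {
    for (a in bounds$a_min:bounds$a_max) {
      j <- i + a + 1
      if (j > n || !is_c[j]) next
      for (b in bounds$b_min:bounds$b_max) {
        k <- j + b + 1
        h <- k + bounds$c + 1
        if (h > n) next
        if (is_c[k] && is_h[h]) {
          out[[length(out) + 1]] <- c(start = i, end = h, a = a, b = b)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(),
                  a = integer(), b = integer()))
  }
  as_tibble(do.call(rbind, out))
}

# Greedy resolution: order candidates by (start, total span, a, b) and accept
# any candidate not overlapping an already accepted hit.
resolve_candidates <- function(cand) {
  cand <- arrange(cand, .data$start, .data$end - .data$start, .data$a, .data$b)
  taken_end <- integer(0)
  taken_start <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- cand$start[r]; e <- cand$end[r]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[r] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  arrange(cand[keep, ], .data$start)
}

#' Find CCCH motifs in one amino-acid sequence
#'
#' Enumerates every index quadruple (C, C, C, H) whose spacers satisfy
#' `bounds`, then resolves overlaps greedily by leftmost start, then smallest
#' total span, then smallest first and second spacer. `X` (unknown residue)
#' may occupy spacer positions but never an anchor C or H.
#'
#' @param sequence A single amino-acid string (20 standard residues plus X).
#' @param bounds A [ccch_bounds()] object.
#' @return A tibble with one row per accepted hit: `start`, `end` (1-based,
#'   inclusive; `start` indexes the first C, `end` the H), spacers `a`, `b`,
#'   `c`, the rendered `signature`, and the matched `subsequence`.
#' @export
#' @examples
#' find_motifs("CAAAACAAAACAAAH")
find_motifs <- function(sequence, bounds = ccch_bounds()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) {
    return(empty_hits())
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad)) {
    abort(sprintf("illegal residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  cand <- ccch_candidates(chars, bounds)
  if (!nrow(cand)) {
    return(empty_hits())
  }
  hits <- resolve_candidates(cand)
  mutate(hits,
         c = bounds$c,
         signature = motif_signature(.data$a, .data$b, bounds$c),
         subsequence = substring(sequence, .data$start, .data$end))
}

empty_hits <- function() {
  tibble(start = integer(), end = integer(), a = integer(), b = integer(),
         c = integer(), signature = character(), subsequence = character())
}

#' Scan a whole proteome for CCCH motifs
#'
#' @param proteins Protein sequences: a named character vector, an
#'   `AAStringSet`, or a path to a FASTA file.
#' @param bounds A [ccch_bounds()] object.
#' @return A tibble of hits with a leading `protein_id` column; proteins
#'   without hits contribute no rows.
#' @export
scan_proteome <- function(proteins, bounds = ccch_bounds()) {
  seqs <- as_seq_vector(proteins, "AA")
  res <- imap(seqs, function(s, id) {
    h <- find_motifs(s, bounds)
    if (nrow(h)) mutate(h, protein_id = id, .before = 1) else NULL
  })
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(mutate(empty_hits(), protein_id = character(), .before = 1))
  }
  out
}

#' Tally motif classes across a proteome
#'
#' @param hits A hits tibble from [scan_proteome()] or [find_motifs()].
#' @return A tibble (`signature`, `count`, `percentage`) sorted by
#'   decreasing count; percentages are to one decimal, half-up. The total is
#'   carried in attribute `total`.
#' @export
tally_classes <- function(hits) {
  if (!nrow(hits)) {
    out <- tibble(signature = character(), count = integer(),
                  percentage = numeric())
    attr(out, "total") <- 0L
    return(out)
  }
  out <- hits %>%
    count(.data$signature, name = "count") %>%
    arrange(dplyr::desc(.data$count), .data$signature) %>%
    mutate(percentage = round_half_up(100 * .data$count / sum(.data$count), 1))
  attr(out, "total") <- sum(out$count)
  out
}

#' Histogram of motif copies per protein
#'
#' @param hits A hits tibble with a `protein_id` column.
#' @param protein_ids Optional character vector of all scanned proteins, so
#'   proteins with zero hits can be reported (attribute `zero_hit_proteins`).
#' @return A tibble (`n_motifs`, `n_proteins`) covering 1..max observed,
#'   zero-filled.
#' @export
count_histogram <- function(hits, protein_ids = NULL) {
  if (!nrow(hits)) {
    out <- tibble(n_motifs = integer(), n_proteins = integer())
    attr(out, "zero_hit_proteins") <-
      if (is.null(protein_ids)) character() else protein_ids
    return(out)
  }
  per_prot <- count(hits, .data$protein_id, name = "n_motifs")
  out <- per_prot %>%
    count(.data$n_motifs, name = "n_proteins") %>%
    tidyr::complete(n_motifs = seq_len(max(per_prot$n_motifs)),
                    fill = list(n_proteins = 0L)) %>%
    arrange(.data$n_motifs)
  attr(out, "zero_hit_proteins") <-
    if (is.null(protein_ids)) character() else
      setdiff(protein_ids, per_prot$protein_id)
  out
}

#' Build a sequence-logo profile for one motif class
#'
#' All hits must share one spacer signature, or — for a combined logo of
#' classes differing only in the first spacer — be right-justified on the
#' second C so the variable-length first spacer absorbs the offset.
#'
#' @param hits A hits tibble; all rows must share `b` and `c` (single class:
#'   also `a`).
#' @return An object of class `ccch_logo`: per-position residue frequencies
#'   (rows = 20 residues, columns = alignment positions), per-position
#'   information content in bits (`ic`), per-position sequence counts (`n`),
#'   and anchor column indices.
#' @export
build_logo <- function(hits) {
  if (!nrow(hits)) abort("cannot build a logo from an empty motif class")
  if (length(unique(hits$b)) != 1 || length(unique(hits$c)) != 1) {
    abort("combined logos require classes differing only in the first spacer")
  }
  b <- hits$b[1]; cc <- hits$c[1]
  a_max <- max(hits$a)
  width <- a_max + b + cc + 4
  # right-justify on the second C: left-pad shorter first spacers with NA
  mat <- t(vapply(seq_len(nrow(hits)), function(r) {
    s <- strsplit(hits$subsequence[r], "", fixed = TRUE)[[1]]
    c(rep(NA_character_, width - length(s)), s)
  }, character(width)))
  freq <- vapply(seq_len(width), function(jc) {
    col <- mat[, jc]
    col <- col[!is.na(col) & col != "X"]
    tab <- table(factor(col, levels = AA20))
    if (sum(tab) == 0) rep(0, 20) else as.numeric(tab) / sum(tab)
  }, numeric(20))
  rownames(freq) <- AA20
  ic <- apply(freq, 2, function(f) {
    if (sum(f) == 0) return(0)
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    log2(20) - h
  })
  n <- apply(mat, 2, function(col) sum(!is.na(col)))
  structure(list(
    freq = freq,
    ic = as.numeric(ic),
    n = as.integer(n),
    width = width,
    # first_C is a fixed column only when a single class is profiled
    anchor_cols = c(first_C = if (length(unique(hits$a)) == 1) 1L else NA_integer_,
                    second_C = width - (b + cc + 2L),
                    third_C = width - (cc + 1L),
                    H = width),
    signatures = sort(unique(hits$signature)),
    n_motifs = nrow(hits)
  ), class = "ccch_logo")
}

#' @export
print.ccch_logo <- function(x, ...) {
  cat(sprintf("CCCH motif logo: %d motifs, %d columns (%s)\n",
              x$n_motifs, x$width, paste(x$signatures, collapse = " + ")))
  cat(sprintf("information content: %.2f-%.2f bits\n",
              min(x$ic), max(x$ic)))
  invisible(x)
}

#' Write scan outputs as TSV
#'
#' @param hits Hits tibble.
#' @param dir Output directory (created if needed).
#' @param params Named list recorded in the commented provenance header.
#' @return Invisibly, the paths written.
#' @export
write_scan_outputs <- function(hits, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    hits = file.path(dir, "motif_hits.tsv"),
    tally = file.path(dir, "motif_class_tally.tsv"),
    histogram = file.path(dir, "motif_count_histogram.tsv")
  )
  write_tsv_provenance(hits, paths["hits"], params)
  write_tsv_provenance(tally_classes(hits), paths["tally"], params)
  write_tsv_provenance(count_histogram(hits), paths["histogram"], params)
  invisible(paths)
}
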