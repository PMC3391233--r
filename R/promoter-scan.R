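# Promoter extraction and both-strand scanning for stress-responsive
# cis-element cores (ABRE, DRE) defined by an editable IUPAC lexicon.

#' Default cis-element lexicon (ABRE and DRE cores)
#'
#' Ships as an editable TSV (`element`, `pattern`, `note`) under
#' `inst/extdata/cis_elements.tsv`: the ABRE core `ACGTG` and the DRE/CRT
#' core `RCCGAC`. Patterns are IUPAC nucleotide codes.
#'
#' @return A tibble (`element`, `pattern`, `note`).
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "cis_elements.tsv",
                           package = "ccchsurvey", mustWork = TRUE))
}

#' Read and validate a cis-element lexicon
#'
#' @param path TSV with columns `element`, `pattern` (IUPAC) and optionally
#'   `note`.
#' @return A validated lexicon tibble.
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("element", "pattern") %in% names(lex))) {
    abort("a lexicon needs 'element' and 'pattern' columns")
  }
  lex$pattern <- toupper(lex$pattern)
  if (any(nchar(lex$pattern) == 0)) abort("empty pattern in lexicon")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  for (r in seq_len(nrow(lex))) {
    chars <- strsplit(lex$pattern[r], "")[[1]]
    bad <- setdiff(chars, iupac)
    if (length(bad)) {
      abort(sprintf("invalid IUPAC code '%s' in pattern for element '%s'",
                    bad[1], lex$element[r]))
    }
  }
  lex
}

#' Extract a fixed-length promoter upstream of a gene's start codon
#'
#' Returns the `length` bases immediately 5' of the translation start on the
#' coding strand: for a `+` strand gene the bases preceding `start`, for a
#' `-` strand gene the reverse complement of the bases following `end`.
#' Truncated with a warning at chromosome ends.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences (or a FASTA path).
#' @param locus One-row data frame (`gene_id`, `chromosome`, `start`, `end`,
#'   `strand`).
#' @param length Promoter length in bases.
#' @return A single promoter string (possibly shorter than `length`).
#' @export
extract_promoter <- function(genome, locus, length = 2000) {
  genome <- as_seq_vector(genome, "DNA")
  stopifnot(nrow(locus) == 1)
  chr <- unname(genome[as.character(locus$chromosome)])
  if (is.na(chr)) {
    abort(sprintf("chromosome '%s' not in genome", locus$chromosome))
  }
  L <- nchar(chr)
  if (locus$start < 1 || locus$end > L) {
    abort(sprintf("locus '%s' lies outside its chromosome", locus$gene_id))
  }
  if (locus$strand == "+") {
    to <- locus$start - 1
    from <- max(1, to - length + 1)
    if (to < 1) {
      warn(sprintf("gene '%s' starts at the chromosome edge; empty promoter",
                   locus$gene_id))
      return("")
    }
    if (to - from + 1 < length) {
      warn(sprintf("promoter of '%s' truncated to %d bases",
                   locus$gene_id, to - from + 1))
    }
    substring(chr, from, to)
  } else {
    from <- locus$end + 1
    to <- min(L, from + length - 1)
    if (from > L) {
      warn(sprintf("gene '%s' ends at the chromosome edge; empty promoter",
                   locus$gene_id))
      return("")
    }
    if (to - from + 1 < length) {
      warn(sprintf("promoter of '%s' truncated to %d bases",
                   locus$gene_id, to - from + 1))
    }
    revcomp(substring(chr, from, to))
  }
}

#' Scan one promoter for cis-element cores on both strands
#'
#' Reports every occurrence of every lexicon pattern on the sense and
#' reverse strand; overlapping occurrences are all reported. IUPAC
#' degeneracy in patterns is honored; `N` in the promoter never matches.
#'
#' @param promoter A single nucleotide string over A, C, G, T, N.
#' @param lexicon A lexicon tibble, see [default_lexicon()].
#' @return A tibble (`element`, `strand`, `position`, `match`) sorted by
#'   position; `position` is the 1-based sense-strand offset of the match
#'   window's first base for both strands.
#' @export
#' @examples
#' scan_elements("AAACGTGAA", default_lexicon())
scan_elements <- function(promoter, lexicon) {
  stopifnot(is.character(promoter), length(promoter) == 1)
  promoter <- toupper(promoter)
  empty <- tibble(element = character(), strand = character(),
                  position = integer(), match = character())
  if (!nrow(lexicon) || nchar(promoter) == 0) return(empty)
  chars <- strsplit(promoter, "")[[1]]
  bad <- which(!chars %in% c(DNA4, "N"))
  if (length(bad)) {
    abort(sprintf("invalid base '%s' at promoter position %d",
                  chars[bad[1]], bad[1]))
  }
  subject <- Biostrings::DNAString(promoter)
  one_strand <- function(pattern, element, strand) {
    pat <- Biostrings::DNAString(pattern)
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (!base::length(m)) return(NULL)
    hit <- tibble(element = element, strand = strand,
                  position = Biostrings::start(m),
                  match = as.character(m))
    # fixed = FALSE lets subject ambiguity codes match too; N must not
    filter(hit, !stringr::str_detect(.data$match, "N"))
  }
  out <- bind_rows(lapply(seq_len(nrow(lexicon)), function(r) {
    bind_rows(one_strand(lexicon$pattern[r], lexicon$element[r], "+"),
              one_strand(lexicon$pattern[r], lexicon$element[r], "-"))
  }))
  if (!nrow(out)) return(empty)
  arrange(out, .data$position, .data$element, .data$strand)
}

#' Scan many promoters
#'
#' @param promoters Named character vector, `DNAStringSet`, or FASTA path.
#' @param lexicon A lexicon tibble.
#' @return Hits tibble with a leading `promoter_id` column.
#' @export
scan_promoters <- function(promoters, lexicon = default_lexicon()) {
  seqs <- as_seq_vector(promoters, "DNA")
  out <- bind_rows(imap(seqs, function(s, id) {
    h <- scan_elements(s, lexicon)
    if (nrow(h)) mutate(h, promoter_id = id, .before = 1) else NULL
  }))
  if (!nrow(out)) {
    return(tibble(promoter_id = character(), element = character(),
                  strand = character(), position = integer(),
                  match = character()))
  }
  out
}

#' Per-promoter element-count summary
#'
#' @param hits Hits tibble from [scan_promoters()].
#' @return Tibble (`promoter_id`, one count column per element).
#' @export
element_counts <- function(hits) {
  if (!nrow(hits)) {
    return(tibble(promoter_id = character()))
  }
  hits %>%
    count(.data$promoter_id, .data$element) %>%
    tidyr::pivot_wider(names_from = "element", values_from = "n",
                       values_fill = 0L)
}
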