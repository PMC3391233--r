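# Shared alphabets, codon tables and small input helpers.

# The 20 standard residues; X is tolerated in scans but never matches an
# anchor C/H.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

#' All 61 non-stop codons of the standard genetic code
#' @noRd
non_stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Translate one codon under the standard genetic code
#' @noRd
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Coerce sequence input to a named character vector
#'
#' Accepts a named character vector, a `Biostrings::XStringSet`, or a path to
#' a FASTA file. Names are required (sequence records must be identifiable).
#' @noRd
as_seq_vector <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    x <- switch(type,
      AA  = Biostrings::readAAStringSet(x),
      DNA = Biostrings::readDNAStringSet(x)
    )
  }
  if (methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x)) {
    abort("sequences must be a named character vector, an XStringSet, or a FASTA path")
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    abort("every sequence record needs a name")
  }
  toupper(x)
}

#' Reverse complement of a DNA string
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Round half up to `digits` decimals (matching report-table conventions,
#' where 54.35 prints as 54.4)
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Write a tibble as TSV with a commented provenance header
#' @noRd
write_tsv_provenance <- function(x, path, params = list()) {
  hdr <- c(
    sprintf("# ccchsurvey %s", as.character(utils::packageVersion("ccchsurvey"))),
    if (length(params)) {
      sprintf("# %s", paste(names(params), unlist(lapply(params, format)),
                            sep = "=", collapse = " "))
    }
  )
  writeLines(hdr, path)
  suppressMessages(readr::write_tsv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Read a TSV written with [write_tsv_provenance()] (comment lines skipped)
#' @noRd
read_tsv_plain <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
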