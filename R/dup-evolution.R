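# Duplicate-pair evolution: tandem/segmental classification from gene order
# and duplicated-block maps, Nei-Gojobori (1986) Ka/Ks, selection calls, and
# Ks-based duplication dating.

#' Synonymous substitution rate for grasses
#'
#' Default clock rate lambda = 6.5e-9 synonymous substitutions per site per
#' year, as commonly adopted for grass genomes; duplication age is
#' T = Ks / (2 * lambda), reported in Mya.
#'
#' @param lambda Substitutions per synonymous site per year (> 0).
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(lambda = 6.5e-9) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda), class = "evolution_params")
}

#' Classify a gene pair as tandem from annotation order
#'
#' Tandem means both genes on one chromosome separated by at most `max_gap`
#' gene loci. Under the default `"intervening"` convention that is at most
#' `max_gap` loci between them (`|index difference| - 1 <= max_gap`); the
#' `"index"` convention instead requires `|index difference| <= max_gap`.
#'
#' @param gene_a,gene_b Gene identifiers.
#' @param loci Gene-locus tibble (`gene_id`, `chromosome`, `start`, `end`,
#'   `locus_index`).
#' @param max_gap Maximum separation in gene loci.
#' @param convention `"intervening"` (default) or `"index"`.
#' @return Logical.
#' @export
classify_tandem <- function(gene_a, gene_b, loci, max_gap = 5,
                            convention = c("intervening", "index")) {
  convention <- match.arg(convention)
  la <- locus_of(gene_a, loci)
  lb <- locus_of(gene_b, loci)
  if (la$chromosome != lb$chromosome) return(FALSE)
  gap <- abs(la$locus_index - lb$locus_index)
  if (convention == "intervening") gap <- gap - 1
  gap <= max_gap
}

#' Classify a gene pair as segmental from a duplicated-block map
#'
#' Segmental means the two genes fall (by coordinate containment) inside
#' the two mates of one duplicated-block pairing, in either orientation.
#'
#' @inheritParams classify_tandem
#' @param blocks Block map tibble (`chr_a`, `start_a`, `end_a`, `chr_b`,
#'   `start_b`, `end_b`).
#' @return Logical.
#' @export
classify_segmental <- function(gene_a, gene_b, loci, blocks) {
  la <- locus_of(gene_a, loci)
  lb <- locus_of(gene_b, loci)
  inside <- function(g, chr, lo, hi) {
    g$chromosome == chr & g$start >= lo & g$end <= hi
  }
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    if ((inside(la, b$chr_a, b$start_a, b$end_a) &&
         inside(lb, b$chr_b, b$start_b, b$end_b)) ||
        (inside(la, b$chr_b, b$start_b, b$end_b) &&
         inside(lb, b$chr_a, b$start_a, b$end_a))) {
      return(TRUE)
    }
  }
  FALSE
}

locus_of <- function(gene, loci) {
  i <- which(loci$gene_id == gene)
  if (length(i) != 1) abort(sprintf("unknown gene id '%s'", gene))
  loci[i, ]
}

#' Classify many duplicate pairs
#'
#' Tandem takes precedence (tandem clusters may also lie on duplicated
#' blocks); pairs that are neither are `"unclassified"`.
#'
#' @param pairs Tibble (`gene_a`, `gene_b`).
#' @inheritParams classify_tandem
#' @inheritParams classify_segmental
#' @return `pairs` with a `duplicate_type` column.
#' @export
classify_duplicates <- function(pairs, loci, blocks, max_gap = 5,
                                convention = c("intervening", "index")) {
  convention <- match.arg(convention)
  mutate(pairs, duplicate_type = vapply(seq_len(nrow(pairs)), function(r) {
    if (classify_tandem(pairs$gene_a[r], pairs$gene_b[r], loci,
                        max_gap, convention)) {
      "tandem"
    } else if (classify_segmental(pairs$gene_a[r], pairs$gene_b[r],
                                  loci, blocks)) {
      "segmental"
    } else {
      "unclassified"
    }
  }, character(1)))
}

# --- Nei-Gojobori (1986) ----------------------------------------------------

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# synonymous site count of one codon: for each position, the fraction of the
# three single-nucleotide changes that preserve the amino acid; changes to
# stop codons count as nonsynonymous (they stay in the denominator of 3)
ng86_sites <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  aa <- codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(DNA4, nts[p])) {
      v <- nts; v[p] <- nt
      vc <- paste(v, collapse = "")
      if (codon_aa(vc) == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# average synonymous/nonsynonymous difference counts between two codons over
# all minimal substitution pathways; pathways crossing a stop codon are
# excluded, falling back to all pathways (stop steps nonsynonymous) when
# every pathway is blocked
ng86_diffs <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  paths <- perms(pos)
  count_path <- function(order, allow_stop) {
    cur <- a
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- codon_aa(paste(cur, collapse = ""))
      aa2 <- codon_aa(paste(nxt, collapse = ""))
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counted <- keep(lapply(paths, count_path, allow_stop = FALSE),
                  Negate(is.null))
  if (!length(counted)) {
    counted <- lapply(paths, count_path, allow_stop = TRUE)
  }
  avg <- Reduce(`+`, counted) / length(counted)
  c(Sd = avg[1], Nd = avg[2])
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  unlist(lapply(seq_along(x), function(i) {
    lapply(perms(x[-i]), function(rest) c(x[i], rest))
  }), recursive = FALSE)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Ka and Ks by the Nei-Gojobori (1986) method
#'
#' Per-codon synonymous and nonsynonymous site fractions are averaged over
#' both sequences; differences are counted averaging over all minimal
#' substitution pathways (stop-crossing pathways excluded); proportions are
#' Jukes-Cantor corrected, `d = -3/4 log(1 - 4p/3)`.
#'
#' @param cds_a,cds_b Equal-length, in-frame, stop-free coding sequences
#'   (codon-aligned; codons containing `-` are dropped with a warning).
#' @return One-row tibble: `ka`, `ks`, `ka_ks`, `selection` (see
#'   [selection_call()]), and the underlying site/difference counts `S`,
#'   `N`, `Sd`, `Nd`. `ka`/`ks` are `NA` if the corresponding proportion
#'   reaches 3/4 (correction undefined, flagged with a warning).
#' @export
#' @examples
#' ng86_ka_ks("TTT", "TTC") # one synonymous difference
ng86_ka_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) abort("coding sequences differ in length")
  if (nchar(cds_a) %% 3 != 0) abort("alignment length not a multiple of 3")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  gapped <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  if (any(gapped)) {
    warn(sprintf("dropping %d gapped codon(s)", sum(gapped)))
    ca <- ca[!gapped]; cb <- cb[!gapped]
  }
  if (any(codon_aa(ca) == "*") || any(codon_aa(cb) == "*")) {
    abort("internal stop codon in coding sequence")
  }
  if (!length(ca)) abort("no ungapped codons to compare")
  sites_a <- vapply(ca, ng86_sites, numeric(2))
  sites_b <- vapply(cb, ng86_sites, numeric(2))
  S <- (sum(sites_a["S", ]) + sum(sites_b["S", ])) / 2
  N <- (sum(sites_a["N", ]) + sum(sites_b["N", ])) / 2
  diffs <- vapply(seq_along(ca), function(i) ng86_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- sum(diffs["Sd", ])
  Nd <- sum(diffs["Nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  if (is.na(ks) || is.na(ka)) {
    warn("difference proportion >= 3/4; Jukes-Cantor correction undefined")
  }
  sel <- selection_call(ka, ks)
  tibble(ka = ka, ks = ks, ka_ks = sel$ratio, selection = sel$call,
         S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Selection-mode call from Ka and Ks
#'
#' `purifying` if Ka/Ks < 1, `neutral` if = 1, `positive` if > 1,
#' `undefined` if Ks = 0 (or either input is `NA`).
#'
#' @param ka,ks Non-negative substitution rates.
#' @return List with `ratio` (Ka/Ks, `NA` when undefined) and `call`.
#' @export
#' @examples
#' selection_call(0.044, 0.143) # purifying, ratio 0.308
selection_call <- function(ka, ks) {
  if (is.na(ka) || is.na(ks) || ks == 0) {
    return(list(ratio = NA_real_, call = "undefined"))
  }
  ratio <- ka / ks
  call <- if (ratio < 1) "purifying" else if (ratio > 1) "positive"
          else "neutral"
  list(ratio = ratio, call = call)
}

#' Duplication date from synonymous divergence
#'
#' `T = Ks / (2 * lambda)`, in million years (Mya).
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param params An [evolution_params()] object.
#' @return Date in Mya (unrounded).
#' @export
#' @examples
#' duplication_date(0.143) # ~11 Mya with the grass clock
duplication_date <- function(ks, params = evolution_params()) {
  stopifnot(all(ks >= 0, na.rm = TRUE))
  ks / (2 * params$lambda) / 1e6
}

#' Build a duplicate-pair report table
#'
#' Takes per-pair Ka and Ks (estimated by [ng86_ka_ks()] or supplied, e.g.
#' from a published table) and derives the Ka/Ks ratio (three decimals),
#' the purifying-selection flag, the duplication date in Mya (two
#' decimals), and, when `loci`/`blocks` are given, the duplicate type.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`, `ka`, `ks` and optionally
#'   `duplicate_type`.
#' @param params An [evolution_params()] object.
#' @param loci,blocks Optional gene-locus table and block map for
#'   classification (overrides any supplied `duplicate_type`).
#' @param max_gap Tandem separation bound, see [classify_tandem()].
#' @return Tibble: `pair`, `ka`, `ks`, `ka_ks`, `purifying`, `date_mya`,
#'   `duplicate_type`.
#' @export
duplicate_pair_table <- function(pairs, params = evolution_params(),
                                 loci = NULL, blocks = NULL, max_gap = 5) {
  stopifnot(all(c("gene_a", "gene_b", "ka", "ks") %in% names(pairs)))
  if (!is.null(loci) && !is.null(blocks)) {
    pairs <- classify_duplicates(pairs, loci, blocks, max_gap)
  }
  if (!"duplicate_type" %in% names(pairs)) {
    pairs$duplicate_type <- NA_character_
  }
  sel <- map(seq_len(nrow(pairs)),
             ~selection_call(pairs$ka[.x], pairs$ks[.x]))
  tibble(
    pair = paste(pairs$gene_a, pairs$gene_b, sep = "-"),
    ka = pairs$ka,
    ks = pairs$ks,
    ka_ks = round_half_up(map_dbl(sel, "ratio"), 3),
    purifying = map_chr(sel, "call") == "purifying",
    date_mya = round_half_up(duplication_date(pairs$ks, params), 2),
    duplicate_type = pairs$duplicate_type
  )
}

#' The published maize CCCH duplicate-pair table
#'
#' The 17 duplicated ZmC3H paralog pairs with their printed Ka and Ks
#' values and duplicate types, shipped as plain TSV. These printed values
#' are inputs for recomputing ratios, selection calls and dates.
#'
#' @return Tibble (`gene_a`, `gene_b`, `ka`, `ks`, `duplicate_type`).
#' @export
zmc3h_pairs <- function() {
  read_tsv_plain(system.file("extdata", "zmc3h_duplicate_pairs.tsv",
                             package = "ccchsurvey", mustWork = TRUE))
}
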