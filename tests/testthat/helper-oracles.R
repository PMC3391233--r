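# Independent oracles used to cross-check the package implementations on
# small inputs: exhaustive motif-parse enumeration, naive per-codon
# Nei-Gojobori counting, and small sequence utilities.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# enumerate every (C, C, C, H) index quadruple satisfying the spacer
# bounds, then apply the stated resolution policy (leftmost start, smallest
# span, smallest a, smallest b, discard overlaps)
oracle_find_motifs <- function(sequence, a_min = 4, a_max = 17,
                               b_min = 4, b_max = 6, c = 3) {
  ch <- strsplit(sequence, "")[[1]]
  cs <- which(ch == "C")
  hs <- which(ch == "H")
  cand <- data.frame(start = integer(), end = integer(),
                     a = integer(), b = integer())
  for (i in cs) for (j in cs[cs > i]) for (k in cs[cs > j]) {
    for (h in hs[hs > k]) {
      a <- j - i - 1; b <- k - j - 1; c3 <- h - k - 1
      if (a >= a_min && a <= a_max && b >= b_min && b <= b_max && c3 == c) {
        cand <- rbind(cand, data.frame(start = i, end = h, a = a, b = b))
      }
    }
  }
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$start, cand$end - cand$start, cand$a, cand$b), ]
  acc <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    x <- cand[r, ]
    overlaps <- nrow(acc) > 0 &&
      any(x$start <= acc$end & x$end >= acc$start)
    if (!overlaps) acc <- rbind(acc, x)
  }
  acc[order(acc$start), ]
}

# naive Nei-Gojobori counting: per-codon site fractions (stop-producing
# changes nonsynonymous), per-codon pathway enumeration via explicit
# permutations, stop-crossing pathways excluded (all-pathways fallback)
oracle_ng86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- codons(s1); c2 <- codons(s2)
  syn_sites <- function(codon) {
    nt <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) for (x in setdiff(c("A", "C", "G", "T"), nt[p])) {
      v <- nt; v[p] <- x
      if (gc[[paste(v, collapse = "")]] == gc[[codon]]) s <- s + 1 / 3
    }
    s
  }
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  path_counts <- function(ca, cb) {
    na <- strsplit(ca, "")[[1]]; nb <- strsplit(cb, "")[[1]]
    pos <- which(na != nb)
    if (!length(pos)) return(c(0, 0))
    walk <- function(order, allow_stop) {
      cur <- na; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- nb[p]
        a1 <- gc[[paste(cur, collapse = "")]]
        a2 <- gc[[paste(nxt, collapse = "")]]
        if (a2 == "*" && !allow_stop) return(NULL)
        if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(permute(pos), walk,
                                          allow_stop = FALSE))
    if (!length(res)) res <- lapply(permute(pos), walk, allow_stop = TRUE)
    Reduce(`+`, res) / length(res)
  }
  S <- (sum(vapply(c1, syn_sites, 0)) + sum(vapply(c2, syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  dd <- Reduce(`+`, lapply(seq_along(c1),
                           function(i) path_counts(c1[i], c2[i])))
  ps <- dd[1] / S; pn <- dd[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = dd[1], Nd = dd[2], ks = jc(ps), ka = jc(pn))
}

random_protein <- function(n, p_anchor = 0.25) {
  paste(sample(c(AA_LETTERS, rep(c("C", "H"), round(p_anchor * 20))),
               n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# additive distance matrix from a random tree with strictly positive edges
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
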