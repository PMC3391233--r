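# Ground-truth synthetic data generators. Every generator plants known
# content (motifs, substitutions, duplicate placements, cis-elements, fold
# changes) and rejection-samples only the background, so the corresponding
# analysis stage can be tested against the plan as an exact oracle.

MAX_REJECTION_TRIES <- 10000L

#' Generate a synthetic proteome with planted CCCH motifs
#'
#' Each planted motif is written as its anchor residues (C, C, C, H) with
#' spacer and background positions drawn uniformly from `alphabet`.
#' Backgrounds are rejection-sampled until scanning the protein recovers
#' exactly the planted motif set — planted content is never altered, only
#' background.
#'
#' @param plan Tibble with one row per planted motif: `protein_id`,
#'   `position` (1-based index of the first C), `a`, `b` (spacer lengths;
#'   the third spacer is fixed by `bounds`).
#' @param background_length Minimum protein length; proteins are extended if
#'   a planted motif runs past it.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param protein_ids All proteins to emit (defaults to those in `plan`);
#'   extra ids yield motif-free proteins.
#' @param bounds Consensus bounds used for validation and the recovery scan.
#' @param alphabet Residue pool for background and spacer positions.
#' @return Named character vector of protein sequences.
#' @export
#' @examples
#' generate_proteome(
#'   tibble::tibble(protein_id = "p1", position = 1, a = 4, b = 4),
#'   background_length = 0, seed = 1, alphabet = "A"
#' )
generate_proteome <- function(plan, background_length, seed,
                              protein_ids = NULL,
                              bounds = ccch_bounds(),
                              alphabet = AA20) {
  stopifnot(is.data.frame(plan))
  if (nrow(plan)) {
    stopifnot(all(c("protein_id", "position", "a", "b") %in% names(plan)))
    ok_spacer <- plan$a >= bounds$a_min & plan$a <= bounds$a_max &
      plan$b >= bounds$b_min & plan$b <= bounds$b_max
    if (any(!ok_spacer)) {
      abort(sprintf("spacer out of bounds for protein '%s'",
                    plan$protein_id[which(!ok_spacer)[1]]))
    }
  }
  ids <- protein_ids %||% unique(plan$protein_id)
  if (!length(ids)) return(setNames(character(), character()))

  withr::with_seed(seed, {
    out <- vapply(ids, function(id) {
      pp <- plan[nrow(plan) > 0 & plan$protein_id == id, , drop = FALSE]
      pp <- arrange(pp, .data$position)
      ends <- pp$position + pp$a + pp$b + bounds$c + 3
      if (nrow(pp) > 1 && any(pp$position[-1] <= ends[-nrow(pp)])) {
        abort(sprintf("overlapping planted motifs in protein '%s'", id))
      }
      len <- max(background_length, if (nrow(pp)) max(ends) else 0L)
      anchor_idx <- unlist(pmap(pp, function(position, a, b, ...) {
        c(position, position + a + 1, position + a + b + 2,
          position + a + b + bounds$c + 3)
      }))
      anchor_res <- rep(c("C", "C", "C", "H"), nrow(pp))
      free_idx <- setdiff(seq_len(len), anchor_idx)
      target <- arrange(select(pp, start = "position", "a", "b"),
                        .data$start)
      for (try in seq_len(MAX_REJECTION_TRIES)) {
        chars <- character(len)
        chars[anchor_idx] <- anchor_res
        chars[free_idx] <- sample(alphabet, length(free_idx), replace = TRUE)
        seq <- paste(chars, collapse = "")
        got <- find_motifs(seq, bounds)
        if (same_table(select(got, "start", "a", "b"), target)) {
          return(seq)
        }
      }
      abort(sprintf("could not sample a clean background for protein '%s'", id))
    }, character(1))
    setNames(out, ids)
  })
}

#' Generate a diverged coding-sequence pair with known substitution counts
#'
#' Draws a stop-free ancestor of `n_codons` codons (codon-uniform over the
#' 61 non-stop codons), then applies exactly `syn_changes` single synonymous
#' substitutions and `nonsyn_changes` single nonsynonymous substitutions,
#' each in a distinct codon, to produce the derived copy. Codons that admit
#' no change of the requested kind (e.g. Met, Trp for synonymous) are
#' resampled at the affected position.
#'
#' @param n_codons Number of codons.
#' @param syn_changes,nonsyn_changes Planted substitution counts.
#' @param seed Integer seed.
#' @return List with `cds_a` (ancestor), `cds_b` (derived), and `changes`,
#'   a tibble of the planted edits (`codon`, `type`).
#' @export
generate_cds_pair <- function(n_codons, syn_changes, nonsyn_changes, seed) {
  stopifnot(n_codons >= 0, syn_changes >= 0, nonsyn_changes >= 0)
  if (syn_changes + nonsyn_changes > n_codons) {
    abort("syn_changes + nonsyn_changes must not exceed n_codons")
  }
  codons <- non_stop_codons()
  variants_of <- function(codon) {
    nts <- strsplit(codon, "")[[1]]
    out <- character(0)
    for (p in 1:3) for (nt in setdiff(DNA4, nts[p])) {
      v <- nts; v[p] <- nt
      out <- c(out, paste(v, collapse = ""))
    }
    out
  }
  kind_ok <- function(codon, type) {
    v <- variants_of(codon)
    aa <- codon_aa(codon)
    if (type == "synonymous") v[codon_aa(v) == aa]
    else v[codon_aa(v) != aa & codon_aa(v) != "*"]
  }
  withr::with_seed(seed, {
    anc <- sample(codons, n_codons, replace = TRUE)
    idx <- sample(n_codons, syn_changes + nonsyn_changes)
    types <- rep(c("synonymous", "nonsynonymous"),
                 c(syn_changes, nonsyn_changes))
    der <- anc
    for (k in seq_along(idx)) {
      i <- idx[k]
      choices <- kind_ok(anc[i], types[k])
      tries <- 0L
      while (!length(choices)) {
        tries <- tries + 1L
        if (tries > MAX_REJECTION_TRIES) {
          abort("no codon admits the requested change")
        }
        anc[i] <- sample(codons, 1)
        choices <- kind_ok(anc[i], types[k])
      }
      der[i] <- if (length(choices) == 1) choices else sample(choices, 1)
    }
    list(
      cds_a = paste(anc, collapse = ""),
      cds_b = paste(der, collapse = ""),
      changes = tibble(codon = idx, type = types)
    )
  })
}

#' Generate a gene-locus table with planted tandem and segmental duplicates
#'
#' Genes are laid out on `n_chromosomes` chromosomes in annotation order
#' (locus indices 1, 2, ...), with deterministic slot coordinates. Tandem
#' pairs are placed on one chromosome with the requested number of
#' intervening loci; segmental pairs are placed inside the two mates of a
#' duplicated-block pairing.
#'
#' @param n_genes Total genes (planted pairs included); background genes are
#'   named `bg###`.
#' @param tandem_pairs Tibble (`gene_a`, `gene_b`, `gap`) — `gap` intervening
#'   loci, at most `max_gap`; optional column `chromosome`.
#' @param segmental_pairs Tibble (`gene_a`, `gene_b`, `block`) — `block`
#'   indexes a row of `block_map`.
#' @param block_map Tibble (`chr_a`, `start_a`, `end_a`, `chr_b`, `start_b`,
#'   `end_b`) of duplicated chromosomal blocks.
#' @param seed Integer seed.
#' @param n_chromosomes Number of chromosomes.
#' @param max_gap Maximum intervening loci for a feasible tandem placement.
#' @return List with `loci` (tibble: `gene_id`, `chromosome`, `start`,
#'   `end`, `locus_index`) and `plan` (tibble: `gene_a`, `gene_b`, `type`).
#' @export
generate_gene_order <- function(n_genes,
                                tandem_pairs = tibble(gene_a = character(),
                                                      gene_b = character(),
                                                      gap = integer()),
                                segmental_pairs = tibble(gene_a = character(),
                                                         gene_b = character(),
                                                         block = integer()),
                                block_map = empty_block_map(),
                                seed = 1,
                                n_chromosomes = 10,
                                max_gap = 5) {
  both <- intersect(pair_keys(tandem_pairs), pair_keys(segmental_pairs))
  if (length(both)) {
    abort(sprintf("pair %s planted as both tandem and segmental", both[1]))
  }
  if (nrow(tandem_pairs) && any(tandem_pairs$gap > max_gap)) {
    abort("a tandem pair is planted with more than max_gap intervening loci")
  }
  if (nrow(segmental_pairs) &&
      any(segmental_pairs$block > nrow(block_map))) {
    abort("segmental pair references a block absent from block_map")
  }

  slot_width <- 5000
  slot_pitch <- 10000
  per_chr <- ceiling(n_genes / n_chromosomes)
  slots <- tidyr::expand_grid(
    chromosome = paste0("chr", seq_len(n_chromosomes)),
    locus_index = seq_len(per_chr)
  ) %>%
    mutate(start = (.data$locus_index - 1) * slot_pitch + 1,
           end = .data$start + slot_width - 1,
           gene_id = NA_character_)

  take_slot <- function(slots, i, gene) {
    if (!is.na(slots$gene_id[i])) {
      abort(sprintf("contradictory placement: slot already used (gene '%s')",
                    gene))
    }
    slots$gene_id[i] <- gene
    slots
  }

  withr::with_seed(seed, {
    # tandem pairs: consecutive-ish slots on one chromosome
    chr_cursor <- 0L
    for (r in seq_len(nrow(tandem_pairs))) {
      tp <- tandem_pairs[r, ]
      chr <- if ("chromosome" %in% names(tp) && !is.na(tp$chromosome)) {
        tp$chromosome
      } else {
        chr_cursor <- chr_cursor %% n_chromosomes + 1L
        paste0("chr", chr_cursor)
      }
      free <- which(slots$chromosome == chr & is.na(slots$gene_id))
      placed <- FALSE
      for (i in free) {
        j <- which(slots$chromosome == chr &
                     slots$locus_index == slots$locus_index[i] + tp$gap + 1)
        if (length(j) == 1 && is.na(slots$gene_id[j])) {
          slots <- take_slot(slots, i, tp$gene_a)
          slots <- take_slot(slots, j, tp$gene_b)
          placed <- TRUE
          break
        }
      }
      if (!placed) abort(sprintf("cannot place tandem pair %s-%s",
                                 tp$gene_a, tp$gene_b))
    }
    # segmental pairs: inside the mates of their block
    for (r in seq_len(nrow(segmental_pairs))) {
      sp <- segmental_pairs[r, ]
      blk <- block_map[sp$block, ]
      place_in <- function(slots, chr, lo, hi, gene) {
        i <- which(slots$chromosome == chr & is.na(slots$gene_id) &
                     slots$start >= lo & slots$end <= hi)
        if (!length(i)) {
          abort(sprintf("no free slot in block for gene '%s'", gene))
        }
        take_slot(slots, i[1], gene)
      }
      slots <- place_in(slots, blk$chr_a, blk$start_a, blk$end_a, sp$gene_a)
      slots <- place_in(slots, blk$chr_b, blk$start_b, blk$end_b, sp$gene_b)
    }
    # background genes fill remaining slots, truncated to n_genes total
    n_planted <- sum(!is.na(slots$gene_id))
    n_bg <- n_genes - n_planted
    if (n_bg < 0) abort("n_genes smaller than the number of planted genes")
    free <- which(is.na(slots$gene_id))
    fill <- free[sample.int(length(free), n_bg)]
    slots$gene_id[fill] <- sprintf("bg%03d", seq_len(n_bg))
    loci <- slots %>%
      filter(!is.na(.data$gene_id)) %>%
      group_by(.data$chromosome) %>%
      arrange(.data$locus_index, .by_group = TRUE) %>%
      mutate(locus_index = row_number()) %>%
      ungroup() %>%
      select("gene_id", "chromosome", "start", "end", "locus_index") %>%
      arrange(.data$chromosome, .data$locus_index)
    plan <- bind_rows(
      if (nrow(tandem_pairs)) mutate(select(tandem_pairs, "gene_a", "gene_b"),
                                     type = "tandem"),
      if (nrow(segmental_pairs)) mutate(select(segmental_pairs,
                                               "gene_a", "gene_b"),
                                        type = "segmental")
    )
    if (is.null(plan)) plan <- tibble(gene_a = character(),
                                      gene_b = character(),
                                      type = character())
    list(loci = loci, plan = plan)
  })
}

# NOTE: re-indexing locus_index after filling means planted tandem gaps are
# preserved only if every intervening slot is occupied; slots are filled
# densely from low indices, so keep n_genes close to slot capacity when gaps
# must be exact. generate_gene_order() therefore re-checks the planted gaps.

empty_block_map <- function() {
  tibble(chr_a = character(), start_a = numeric(), end_a = numeric(),
         chr_b = character(), start_b = numeric(), end_b = numeric())
}

pair_keys <- function(pairs) {
  if (!nrow(pairs)) return(character())
  vapply(seq_len(nrow(pairs)), function(r) {
    paste(sort(c(pairs$gene_a[r], pairs$gene_b[r])), collapse = "-")
  }, character(1))
}

#' Generate promoters with planted cis-elements
#'
#' Planted elements are written as concrete instantiations of their IUPAC
#' pattern (degenerate positions resolved uniformly), reverse-complemented
#' for minus-strand plantings. Backgrounds are rejection-sampled until the
#' scanner recovers exactly the planted hit set.
#'
#' @param n Number of promoters (`prom1` ... `promN`).
#' @param length Promoter length in bases.
#' @param planted Tibble (`promoter_id`, `element`, `strand`, `offset`) —
#'   `offset` is the 1-based sense-strand start of the planted occurrence.
#' @param lexicon An element lexicon, see [default_lexicon()].
#' @param seed Integer seed.
#' @return Named character vector of promoter sequences.
#' @export
generate_promoters <- function(n, length = 2000,
                               planted = tibble(promoter_id = character(),
                                                element = character(),
                                                strand = character(),
                                                offset = integer()),
                               lexicon = default_lexicon(),
                               seed = 1) {
  if (nrow(planted)) {
    unknown <- setdiff(planted$element, lexicon$element)
    if (length(unknown)) {
      abort(sprintf("planted element '%s' absent from the lexicon", unknown[1]))
    }
  }
  ids <- paste0("prom", seq_len(n))
  pat_of <- function(el) lexicon$pattern[match(el, lexicon$element)]
  withr::with_seed(seed, {
    out <- vapply(ids, function(id) {
      pl <- planted[planted$promoter_id == id, , drop = FALSE]
      if (nrow(pl)) {
        plen <- nchar(pat_of(pl$element))
        bad <- pl$offset < 1 | pl$offset > length - plen + 1
        if (any(bad)) {
          abort(sprintf("planted offset out of range in '%s'", id))
        }
      }
      target <- arrange(select(pl, "element", "strand", position = "offset"),
                        .data$position, .data$element, .data$strand)
      planted_pos <- integer(0)
      chars <- sample(DNA4, length, replace = TRUE)
      for (r in seq_len(nrow(pl))) {
        inst <- instantiate_iupac(pat_of(pl$element[r]))
        if (pl$strand[r] == "-") inst <- revcomp(inst)
        w <- strsplit(inst, "")[[1]]
        win <- pl$offset[r]:(pl$offset[r] + base::length(w) - 1)
        chars[win] <- w
        planted_pos <- union(planted_pos, win)
      }
      # accidental background matches are erased by resampling only the
      # offending windows; planted content is never touched
      for (try in seq_len(MAX_REJECTION_TRIES)) {
        seq <- paste(chars, collapse = "")
        got <- scan_elements(seq, lexicon) %>%
          select("element", "strand", "position") %>%
          arrange(.data$position, .data$element, .data$strand)
        if (same_table(got, target)) {
          return(seq)
        }
        extra <- dplyr::anti_join(got, target,
                                  by = c("element", "strand", "position"))
        fix <- integer(0)
        for (r in seq_len(nrow(extra))) {
          plen <- nchar(pat_of(extra$element[r]))
          fix <- union(fix, extra$position[r]:(extra$position[r] + plen - 1))
        }
        fix <- setdiff(fix, planted_pos)
        if (!base::length(fix)) {
          abort(sprintf(
            "planted elements in '%s' imply additional matches; plan infeasible",
            id))
        }
        chars[fix] <- sample(DNA4, base::length(fix), replace = TRUE)
      }
      abort(sprintf("could not sample a clean background for promoter '%s'", id))
    }, character(1))
    setNames(out, ids)
  })
}

# one concrete sequence drawn uniformly from an IUPAC pattern
instantiate_iupac <- function(pattern) {
  codes <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    opts <- strsplit(codes[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a qPCR Ct table with known true fold changes
#'
#' Target-gene Ct values are set so that the delta-delta-Ct pipeline with
#' the given reference gene and calibrator condition recovers
#' `true_fold_changes` exactly when `replicate_sd = 0`. Gaussian noise of SD
#' `replicate_sd` (Ct scale) is added independently to every measurement.
#'
#' @param true_fold_changes Tibble (`gene`, `condition`, `fold`), folds
#'   relative to the calibrator; calibrator rows default to fold 1.
#' @param calibrator Calibrator condition (e.g. `"CK"`).
#' @param reference_gene Reference (housekeeping) gene name.
#' @param replicate_sd Ct-scale standard deviation of replicate noise.
#' @param n_replicates Replicates per gene x condition.
#' @param seed Integer seed.
#' @param base_ct_target,base_ct_reference Baseline Ct levels.
#' @return Tibble (`gene`, `condition`, `replicate`, `replicate_type`, `ct`)
#'   including the reference gene's rows.
#' @export
generate_ct_table <- function(true_fold_changes, calibrator,
                              reference_gene = "Actin1",
                              replicate_sd = 0, n_replicates = 3, seed = 1,
                              base_ct_target = 25, base_ct_reference = 18) {
  stopifnot(all(c("gene", "condition", "fold") %in% names(true_fold_changes)))
  if (any(true_fold_changes$fold <= 0)) {
    abort("true fold changes must be positive")
  }
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  genes <- unique(true_fold_changes$gene)
  conditions <- union(calibrator, unique(true_fold_changes$condition))
  grid <- tidyr::expand_grid(gene = genes, condition = conditions) %>%
    left_join(true_fold_changes, by = c("gene", "condition")) %>%
    mutate(fold = ifelse(is.na(.data$fold) & .data$condition == calibrator,
                         1, .data$fold))
  if (anyNA(grid$fold)) {
    abort("true_fold_changes must cover every non-calibrator gene x condition")
  }
  withr::with_seed(seed, {
    target <- grid %>%
      tidyr::expand_grid(replicate = seq_len(n_replicates)) %>%
      mutate(ct = base_ct_target - log2(.data$fold) +
               rnorm(n(), 0, replicate_sd))
    ref <- tidyr::expand_grid(gene = reference_gene,
                              condition = conditions,
                              replicate = seq_len(n_replicates)) %>%
      mutate(ct = base_ct_reference + rnorm(n(), 0, replicate_sd))
    bind_rows(select(target, "gene", "condition", "replicate", "ct"), ref) %>%
      mutate(replicate_type = "technical", .before = "ct") %>%
      arrange(.data$gene, .data$condition, .data$replicate)
  })
}

#' Generate a planted-clade protein alignment
#'
#' Each clade receives an independent random ancestor; members are copies
#' with `n_mutations` random residue substitutions. Between-clade divergence
#' therefore dwarfs within-clade divergence, so neighbor joining (and its
#' bootstrap) should recover the clades.
#'
#' @param clades Named list: clade label -> character vector of taxon names.
#' @param length Alignment length (columns).
#' @param n_mutations Per-taxon substitutions away from the clade ancestor.
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector of equal-length
#'   rows) and `plan` (tibble: `taxon`, `clade`).
#' @export
generate_alignment <- function(clades, length = 200, n_mutations = 5,
                               seed = 1) {
  stopifnot(is.list(clades), length(clades) >= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (cl in names(clades)) {
      anc <- sample(AA20, length, replace = TRUE)
      for (tx in clades[[cl]]) {
        m <- sample(length, n_mutations)
        row <- anc
        row[m] <- vapply(row[m], function(res) sample(setdiff(AA20, res), 1),
                         character(1))
        rows[[tx]] <- paste(row, collapse = "")
      }
    }
    list(
      alignment = unlist(rows),
      plan = tibble(taxon = unlist(unname(clades)),
                    clade = rep(names(clades), lengths(clades)))
    )
  })
}

#' Write a synthetic bundle's sequences and tables to disk
#'
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- switch(type,
    AA  = Biostrings::AAStringSet(seqs),
    DNA = Biostrings::DNAStringSet(seqs)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# value-wise (type-insensitive) comparison of two plan tables
same_table <- function(got, want) {
  if (nrow(got) != nrow(want) || !identical(names(got), names(want))) {
    return(FALSE)
  }
  if (!nrow(got)) return(TRUE)
  all(mapply(function(g, w) all(g == w), got, want))
}
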