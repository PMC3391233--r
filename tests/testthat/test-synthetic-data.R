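# Ground-truth generators: plan validation, exact round-trips against the
# matching analysis stage, and seed determinism.

test_that("proteome generation honors plans and suppressed backgrounds", {
  plan <- tibble::tibble(protein_id = "p1", position = 1, a = 4, b = 4)
  seqs <- generate_proteome(plan, background_length = 0, seed = 1,
                            alphabet = "A")
  expect_equal(unname(seqs), "CAAAACAAAACAAAH")

  empty <- generate_proteome(plan[0, ], background_length = 10, seed = 1)
  expect_length(empty, 0)
})

test_that("infeasible motif plans are rejected with the offending protein", {
  overlapping <- tibble::tibble(protein_id = "bad", position = c(1, 5),
                                a = c(4, 4), b = c(4, 4))
  expect_error(generate_proteome(overlapping, 50, seed = 1), "bad")
  out_of_bounds <- tibble::tibble(protein_id = "oob", position = 1,
                                  a = 20, b = 4)
  expect_error(generate_proteome(out_of_bounds, 50, seed = 1), "oob")
})

test_that("scanner recovers exactly the planted motifs of a 50-protein proteome", {
  withr::with_seed(99, {
    n_motifs <- sample(0:7, 50, replace = TRUE)
    plan <- dplyr::bind_rows(lapply(seq_len(50), function(i) {
      if (n_motifs[i] == 0) return(NULL)
      tibble::tibble(
        protein_id = sprintf("p%02d", i),
        position = 10 + (seq_len(n_motifs[i]) - 1) * 40,
        a = sample(4:17, n_motifs[i], replace = TRUE),
        b = sample(4:6, n_motifs[i], replace = TRUE)
      )
    }))
  })
  ids <- sprintf("p%02d", 1:50)
  seqs <- generate_proteome(plan, background_length = 60, seed = 123,
                            protein_ids = ids)
  hits <- scan_proteome(seqs)
  per_planted <- table(factor(plan$protein_id, levels = ids))
  per_found <- table(factor(hits$protein_id, levels = ids))
  expect_equal(as.integer(per_found), as.integer(per_planted))
  # positions and spacers, not just counts
  got <- dplyr::arrange(hits[, c("protein_id", "start", "a", "b")],
                        protein_id, start)
  want <- dplyr::arrange(
    dplyr::rename(plan, start = position), protein_id, start)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical proteomes", {
  plan <- tibble::tibble(protein_id = "p1", position = 5, a = 8, b = 5)
  s1 <- generate_proteome(plan, 80, seed = 7)
  s2 <- generate_proteome(plan, 80, seed = 7)
  s3 <- generate_proteome(plan, 80, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("CDS pairs carry exactly the planted substitution counts", {
  same <- generate_cds_pair(50, 0, 0, seed = 1)
  expect_identical(same$cds_a, same$cds_b)

  syn_only <- generate_cds_pair(100, 5, 0, seed = 2)
  res <- ng86_ka_ks(syn_only$cds_a, syn_only$cds_b)
  expect_equal(res$ka, 0)
  expect_gt(res$ks, 0)

  mixed <- generate_cds_pair(300, 15, 6, seed = 7)
  aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])
  # per-codon check: 15 codons differ silently, 6 with amino-acid change
  c1 <- substring(mixed$cds_a, seq(1, 900, 3), seq(3, 900, 3))
  c2 <- substring(mixed$cds_b, seq(1, 900, 3), seq(3, 900, 3))
  diff <- which(c1 != c2)
  expect_length(diff, 21)
  aa_diff <- vapply(diff, function(i) aa(c1[i]) != aa(c2[i]), logical(1))
  expect_equal(sum(!aa_diff), 15)
  expect_equal(sum(aa_diff), 6)
  expect_false(any(aa(c1) == "*"))
  expect_false(any(aa(c2) == "*"))

  expect_error(generate_cds_pair(10, 8, 8, seed = 1), "exceed")
})

test_that("gene-order generation places and recovers planted duplicate types", {
  # one adjacent tandem pair
  simple <- generate_gene_order(
    n_genes = 10,
    tandem_pairs = tibble::tibble(gene_a = "ta", gene_b = "tb", gap = 0L),
    seed = 1, n_chromosomes = 2
  )
  expect_true(classify_tandem("ta", "tb", simple$loci))

  # mixed plan: classification of every planted pair matches the plan
  blocks <- tibble::tibble(
    chr_a = c("chr1", "chr2", "chr3"), start_a = 1, end_a = 50000,
    chr_b = c("chr4", "chr5", "chr6"), start_b = 1, end_b = 50000
  )
  mixed <- generate_gene_order(
    n_genes = 60,
    tandem_pairs = tibble::tibble(gene_a = c("t1a", "t2a"),
                                  gene_b = c("t1b", "t2b"),
                                  gap = c(0L, 3L)),
    segmental_pairs = tibble::tibble(gene_a = paste0("s", 1:3, "a"),
                                     gene_b = paste0("s", 1:3, "b"),
                                     block = 1:3),
    block_map = blocks, seed = 5, n_chromosomes = 10
  )
  got <- classify_duplicates(mixed$plan, mixed$loci, blocks)
  expect_equal(got$duplicate_type, mixed$plan$type)

  expect_error(generate_gene_order(
    10,
    tandem_pairs = tibble::tibble(gene_a = "x", gene_b = "y", gap = 0L),
    segmental_pairs = tibble::tibble(gene_a = "x", gene_b = "y", block = 1L),
    block_map = blocks, seed = 1
  ), "both tandem and segmental")
  expect_error(generate_gene_order(
    10, tandem_pairs = tibble::tibble(gene_a = "x", gene_b = "y", gap = 9L),
    seed = 1
  ), "max_gap")
})

test_that("planted promoter elements are recovered exactly, strands included", {
  one <- generate_promoters(
    1, length = 600,
    planted = tibble::tibble(promoter_id = "prom1", element = "ABRE",
                             strand = "+", offset = 500L),
    seed = 3
  )
  hits <- scan_elements(one[["prom1"]], default_lexicon())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$element, "ABRE")
  expect_equal(hits$strand, "+")
  expect_equal(hits$position, 500L)

  minus <- generate_promoters(
    1, length = 600,
    planted = tibble::tibble(promoter_id = "prom1", element = "DRE",
                             strand = "-", offset = 100L),
    seed = 4
  )
  mh <- scan_elements(minus[["prom1"]], default_lexicon())
  expect_equal(nrow(mh), 1)
  expect_equal(mh$strand, "-")
  expect_equal(mh$position, 100L)

  expect_error(generate_promoters(
    1, planted = tibble::tibble(promoter_id = "prom1", element = "NOPE",
                                strand = "+", offset = 1L), seed = 1
  ), "absent from the lexicon")
})

test_that("a 12-promoter mixed planting round-trips through the scanner", {
  withr::with_seed(21, {
    n_el <- sample(0:6, 12, replace = TRUE)
    plan <- dplyr::bind_rows(lapply(1:12, function(i) {
      if (n_el[i] == 0) return(NULL)
      tibble::tibble(
        promoter_id = paste0("prom", i),
        element = sample(c("ABRE", "DRE"), n_el[i], replace = TRUE),
        strand = sample(c("+", "-"), n_el[i], replace = TRUE),
        offset = sort(sample(seq(1, 560, by = 80), n_el[i])) +
          sample(0:40, n_el[i], replace = TRUE)
      )
    }))
  })
  proms <- generate_promoters(12, length = 620, planted = plan, seed = 8)
  hits <- scan_promoters(proms)
  got <- dplyr::arrange(hits[, c("promoter_id", "element", "strand",
                                 "position")],
                        promoter_id, position)
  want <- dplyr::arrange(
    dplyr::rename(plan, position = offset), promoter_id, position)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("Ct tables recover planted fold changes", {
  flat <- generate_ct_table(
    tibble::tibble(gene = "g1", condition = c("3h", "6h"), fold = 1),
    calibrator = "CK", replicate_sd = 0, seed = 1
  )
  res <- delta_delta_ct(flat)
  expect_equal(res$fold, rep(1, 3))

  up <- generate_ct_table(
    tibble::tibble(gene = "g1", condition = "3h", fold = 2),
    calibrator = "CK", replicate_sd = 0, seed = 1
  )
  res2 <- delta_delta_ct(up)
  expect_equal(res2$delta_delta_ct[res2$condition == "3h"], -1)
  expect_equal(res2$fold[res2$condition == "3h"], 2)

  expect_error(generate_ct_table(
    tibble::tibble(gene = "g1", condition = "3h", fold = -2),
    calibrator = "CK", seed = 1
  ), "positive")
})

test_that("noisy Ct estimates converge on the planted truth (Monte Carlo)", {
  plan <- tibble::tibble(gene = "g1", condition = "3h", fold = 2)
  est <- vapply(1:200, function(i) {
    ct <- generate_ct_table(plan, calibrator = "CK", replicate_sd = 0.2,
                            n_replicates = 3, seed = 1000 + i)
    res <- delta_delta_ct(ct)
    res$fold[res$condition == "3h"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  # small exponentiation bias is well inside three SE bands
  expect_lt(abs(mean(est) - 2), 3 * se + 0.02)
})
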