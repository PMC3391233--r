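# End-to-end family survey: scan -> tree -> groups -> duplicates ->
# promoters -> expression, from one configuration, plus a fully synthetic
# one-command demo bundle with known ground truth.

#' Run the full family survey
#'
#' Executes the enabled stages over the inputs named in `config` and writes
#' per-stage TSV/newick outputs plus a run manifest under
#' `config$out_dir`. Configuration may be a YAML path or a list with
#' entries:
#' \describe{
#'   \item{proteins}{FASTA of protein sequences (scan stage).}
#'   \item{alignment}{aligned FASTA (tree stage).}
#'   \item{pairs}{TSV with `gene_a`, `gene_b` and optionally `ka`, `ks`.}
#'   \item{cds}{FASTA of coding sequences named by gene (used when `pairs`
#'     lacks `ka`/`ks`).}
#'   \item{loci}{gene-locus TSV; \code{blocks}: duplicated-block TSV.}
#'   \item{promoters}{promoter FASTA; \code{lexicon}: lexicon TSV.}
#'   \item{ct_table}{Ct TSV (qpcr stage).}
#'   \item{parameters}{`a_min`, `a_max`, `b_min`, `b_max`, `bootstrap`,
#'     `seed`, `group_threshold`, `lambda`, `max_gap`, `reference_gene`,
#'     `calibrator`.}
#'   \item{stages}{character vector to enable a subset of
#'     `c("scan", "tree", "dups", "promoters", "qpcr")`; defaults to every
#'     stage whose inputs are present.}
#'   \item{out_dir}{output directory.}
#' }
#' Each stage input may also be given directly as an in-memory object
#' (named vector / tibble) instead of a path.
#'
#' @param config A list or a YAML file path.
#' @return A `ccch_survey_report`: per-stage results and a summary.
#' @export
run_survey <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # relative paths in a config file resolve against the file's directory
    for (k in c("proteins", "alignment", "pairs", "cds", "loci", "blocks",
                "promoters", "ct_table", "lexicon", "out_dir")) {
      v <- config[[k]]
      if (is.character(v) && length(v) == 1 && !grepl("^(/|~)", v)) {
        config[[k]] <- file.path(config_dir, v)
      }
    }
  }
  stopifnot(is.list(config))
  prm <- utils::modifyList(list(
    a_min = 4, a_max = 17, b_min = 4, b_max = 6,
    bootstrap = 200, seed = 1, group_threshold = 50,
    lambda = 6.5e-9, max_gap = 5, promoter_length = 2000,
    reference_gene = "Actin1", calibrator = "CK"
  ), config$parameters %||% list())
  all_stages <- c("scan", "tree", "dups", "promoters", "qpcr")
  stage_inputs <- list(
    scan = "proteins", tree = "alignment", dups = "pairs",
    promoters = "promoters", qpcr = "ct_table"
  )
  stages <- config$stages %||%
    all_stages[vapply(stage_inputs, function(k) !is.null(config[[k]]),
                      logical(1))]
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(sprintf("unknown stage '%s'", bad[1]))

  # validate every referenced path before any computation
  for (st in stages) {
    for (k in unique(c(stage_inputs[[st]],
                       if (st == "dups") c("loci", "blocks")))) {
      v <- config[[k]]
      if (is.character(v) && length(v) == 1 && is.null(names(v)) &&
          !file.exists(v)) {
        abort(sprintf("stage '%s': input file '%s' does not exist", st, v))
      }
    }
  }

  out_dir <- config$out_dir %||% tempfile("ccch_survey_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = prm, stages = stages, out_dir = out_dir)
  stage_log <- function(st, msg) message(sprintf("[%s] %s", st, msg))
  run_stage <- function(st, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", st, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
    })
  }

  bounds <- ccch_bounds(prm$a_min, prm$a_max, prm$b_min, prm$b_max)

  if ("scan" %in% stages) {
    run_stage("scan", function() {
      prot <- as_seq_vector(config$proteins, "AA")
      hits <- scan_proteome(prot, bounds)
      report$scan <<- list(
        hits = hits,
        tally = tally_classes(hits),
        histogram = count_histogram(hits, names(prot)),
        n_proteins = length(prot)
      )
      write_scan_outputs(hits, out_dir, prm["seed"])
      stage_log("scan", sprintf("%d proteins in, %d motifs out",
                                length(prot), nrow(hits)))
    })
  }
  if ("tree" %in% stages) {
    run_stage("tree", function() {
      aln <- as_alignment(config$alignment)
      tree <- bootstrap_nj(aln, n_reps = prm$bootstrap, seed = prm$seed)
      groups <- assign_groups(tree, threshold = prm$group_threshold)
      report$tree <<- list(tree = tree, groups = groups,
                           sisters = sister_pairs(tree))
      write_support_tree(tree, file.path(out_dir, "tree.nwk"))
      write_tsv_provenance(groups, file.path(out_dir, "groups.tsv"), prm)
      stage_log("tree", sprintf("%d taxa, %d groups", length(aln),
                                length(setdiff(unique(groups$group),
                                               "ungrouped"))))
    })
  }
  if ("dups" %in% stages) {
    run_stage("dups", function() {
      pairs <- if (is.character(config$pairs)) read_tsv_plain(config$pairs)
               else as_tibble(config$pairs)
      if (!all(c("ka", "ks") %in% names(pairs))) {
        cds <- as_seq_vector(config$cds, "DNA")
        est <- map(seq_len(nrow(pairs)), function(r) {
          ng86_ka_ks(cds[[pairs$gene_a[r]]], cds[[pairs$gene_b[r]]])
        })
        pairs$ka <- map_dbl(est, "ka")
        pairs$ks <- map_dbl(est, "ks")
      }
      loci <- if (is.null(config$loci)) NULL
              else if (is.character(config$loci)) read_tsv_plain(config$loci)
              else as_tibble(config$loci)
      blocks <- if (is.null(config$blocks)) NULL
                else if (is.character(config$blocks)) read_tsv_plain(config$blocks)
                else as_tibble(config$blocks)
      tab <- duplicate_pair_table(pairs, evolution_params(prm$lambda),
                                  loci = loci, blocks = blocks,
                                  max_gap = prm$max_gap)
      report$dups <<- tab
      write_tsv_provenance(tab, file.path(out_dir, "duplicate_pairs.tsv"), prm)
      stage_log("dups", sprintf("%d pairs (%d tandem, %d segmental)",
                                nrow(tab),
                                sum(tab$duplicate_type == "tandem", na.rm = TRUE),
                                sum(tab$duplicate_type == "segmental",
                                    na.rm = TRUE)))
    })
  }
  if ("promoters" %in% stages) {
    run_stage("promoters", function() {
      lex <- if (is.null(config$lexicon)) default_lexicon()
             else if (is.character(config$lexicon)) read_lexicon(config$lexicon)
             else as_tibble(config$lexicon)
      proms <- as_seq_vector(config$promoters, "DNA")
      hits <- scan_promoters(proms, lex)
      report$promoters <<- list(hits = hits, counts = element_counts(hits))
      write_tsv_provenance(hits, file.path(out_dir, "cis_element_hits.tsv"),
                           prm)
      write_tsv_provenance(element_counts(hits),
                           file.path(out_dir, "cis_element_counts.tsv"), prm)
      stage_log("promoters", sprintf("%d promoters in, %d hits out",
                                     length(proms), nrow(hits)))
    })
  }
  if ("qpcr" %in% stages) {
    run_stage("qpcr", function() {
      ct <- if (is.character(config$ct_table)) read_tsv_plain(config$ct_table)
            else as_tibble(config$ct_table)
      res <- delta_delta_ct(ct, reference_gene = prm$reference_gene,
                            calibrator = prm$calibrator)
      report$qpcr <<- res
      write_tsv_provenance(res, file.path(out_dir, "expression.tsv"), prm)
      stage_log("qpcr", sprintf("%d gene x condition results", nrow(res)))
    })
  }

  report$summary <- survey_summary(report)
  yaml::write_yaml(list(
    package = "ccchsurvey",
    version = as.character(utils::packageVersion("ccchsurvey")),
    parameters = prm, stages = stages
  ), file.path(out_dir, "run_manifest.yaml"))
  structure(report, class = "ccch_survey_report")
}

survey_summary <- function(report) {
  tibble(
    n_proteins = report$scan$n_proteins %||% NA_integer_,
    n_motifs = if (is.null(report$scan)) NA_integer_ else
      nrow(report$scan$hits),
    n_classes = if (is.null(report$scan)) NA_integer_ else
      nrow(report$scan$tally),
    n_groups = if (is.null(report$tree)) NA_integer_ else
      length(setdiff(unique(report$tree$groups$group), "ungrouped")),
    n_pairs = if (is.null(report$dups)) NA_integer_ else nrow(report$dups),
    n_tandem = if (is.null(report$dups)) NA_integer_ else
      sum(report$dups$duplicate_type == "tandem", na.rm = TRUE),
    n_segmental = if (is.null(report$dups)) NA_integer_ else
      sum(report$dups$duplicate_type == "segmental", na.rm = TRUE),
    n_element_hits = if (is.null(report$promoters)) NA_integer_ else
      nrow(report$promoters$hits),
    n_expression_results = if (is.null(report$qpcr)) NA_integer_ else
      nrow(report$qpcr)
  )
}

#' @export
print.ccch_survey_report <- function(x, ...) {
  cat("CCCH family survey report\n")
  cat(sprintf("stages run: %s\n", paste(x$stages, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @method glance ccch_survey_report
#' @export
glance.ccch_survey_report <- function(x, ...) x$summary

#' Generate the packaged synthetic demo bundle
#'
#' Writes a complete synthetic dataset emulating a maize-sized CCCH family
#' survey: 68 proteins carrying 180 planted motifs (98 C-X8-C-X5-C-X3-H,
#' 45 C-X7-C-X5-C-X3-H, one C-X17-C-X6-C-X3-H, 36 across four uncommon
#' classes; one protein with 7 motifs), a 20-taxon planted-clade alignment,
#' 17 duplicate pairs (15 segmental, 2 tandem) with coding sequences, gene
#' loci and a block map, 12 promoters with planted ABRE/DRE elements, and a
#' noisy Ct table — plus its plan manifest and a ready-to-run survey
#' configuration.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; fixed seed gives byte-identical bundles.
#' @return Invisibly, a list with the written `paths`, the ground-truth
#'   `plans`, and the survey `config`.
#' @export
make_demo <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    proteins = file.path(out_dir, "proteins.fasta"),
    alignment = file.path(out_dir, "alignment.fasta"),
    cds = file.path(out_dir, "cds.fasta"),
    pairs = file.path(out_dir, "pairs.tsv"),
    loci = file.path(out_dir, "loci.tsv"),
    blocks = file.path(out_dir, "blocks.tsv"),
    promoters = file.path(out_dir, "promoters.fasta"),
    ct_table = file.path(out_dir, "ct_table.tsv"),
    plan = file.path(out_dir, "plan_manifest.yaml"),
    config = file.path(out_dir, "survey_config.yaml")
  )

  # --- proteome plan: 68 proteins, 180 motifs ------------------------------
  per_protein <- rep(c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
                     c(20L, 19L, 12L, 3L, 11L, 2L, 1L))
  stopifnot(length(per_protein) == 68, sum(per_protein) == 180)
  sigs <- rbind(
    matrix(rep(c(8, 5), 98), ncol = 2, byrow = TRUE),
    matrix(rep(c(7, 5), 45), ncol = 2, byrow = TRUE),
    matrix(rep(c(7, 4), 9), ncol = 2, byrow = TRUE),
    matrix(rep(c(5, 4), 9), ncol = 2, byrow = TRUE),
    matrix(rep(c(7, 6), 9), ncol = 2, byrow = TRUE),
    matrix(rep(c(8, 4), 9), ncol = 2, byrow = TRUE),
    matrix(c(17, 6), ncol = 2)
  )
  sigs <- withr::with_seed(seed, sigs[sample.int(nrow(sigs)), , drop = FALSE])
  ids <- sprintf("prot%02d", seq_len(68))
  motif_plan <- tibble(
    protein_id = rep(ids, per_protein),
    slot = unlist(lapply(per_protein, seq_len)),
    a = sigs[, 1], b = sigs[, 2]
  ) %>%
    mutate(position = 30 + (.data$slot - 1) * 40) %>%
    select("protein_id", "position", "a", "b")
  proteins <- generate_proteome(motif_plan, background_length = 80,
                                seed = seed + 1, protein_ids = ids)
  write_fasta(proteins, paths$proteins, "AA")

  # --- planted-clade alignment for the tree stage --------------------------
  clades <- split(sprintf("tax%02d", 1:20),
                  rep(paste0("clade", 1:3), times = c(7, 7, 6)))
  aln <- generate_alignment(clades, length = 250, n_mutations = 6,
                            seed = seed + 2)
  write_fasta(aln$alignment, paths$alignment, "AA")

  # --- 17 duplicate pairs: 15 segmental + 2 tandem -------------------------
  seg_pairs <- tibble(
    gene_a = sprintf("segA%02d", 1:15),
    gene_b = sprintf("segB%02d", 1:15),
    block = 1:15
  )
  tan_pairs <- tibble(
    gene_a = c("tanA1", "tanA2"),
    gene_b = c("tanB1", "tanB2"),
    gap = c(0L, 1L)
  )
  per_chr_span <- 70000
  block_map <- tibble(
    chr_a = paste0("chr", ((1:15 - 1) %% 10) + 1),
    start_a = 1, end_a = per_chr_span,
    chr_b = paste0("chr", (1:15 %% 10) + 1),
    start_b = 1, end_b = per_chr_span
  )
  order_out <- generate_gene_order(
    n_genes = 68, tandem_pairs = tan_pairs, segmental_pairs = seg_pairs,
    block_map = block_map, seed = seed + 3, n_chromosomes = 10
  )
  write_tsv_provenance(order_out$loci, paths$loci, list(seed = seed))
  write_tsv_provenance(block_map, paths$blocks, list(seed = seed))

  pair_plan <- bind_rows(
    mutate(select(tan_pairs, "gene_a", "gene_b"), type = "tandem"),
    mutate(select(seg_pairs, "gene_a", "gene_b"), type = "segmental")
  )
  cds_plan <- pair_plan %>%
    mutate(n_codons = 300,
           syn = c(55, 62, 10 + seq_len(15)),
           nonsyn = c(18, 20, 3 + (seq_len(15) %% 5)))
  cds <- character()
  for (r in seq_len(nrow(cds_plan))) {
    pr <- generate_cds_pair(cds_plan$n_codons[r], cds_plan$syn[r],
                            cds_plan$nonsyn[r], seed = seed + 10 + r)
    cds[[cds_plan$gene_a[r]]] <- pr$cds_a
    cds[[cds_plan$gene_b[r]]] <- pr$cds_b
  }
  write_fasta(cds, paths$cds, "DNA")
  readr::write_tsv(select(pair_plan, "gene_a", "gene_b"), paths$pairs,
                   progress = FALSE)

  # --- promoters with planted ABRE/DRE -------------------------------------
  prom_plan <- withr::with_seed(seed + 4, {
    n_el <- c(0, sample(1:6, 11, replace = TRUE))
    bind_rows(lapply(seq_len(12), function(i) {
      if (n_el[i] == 0) return(NULL)
      tibble(
        promoter_id = paste0("prom", i),
        element = sample(c("ABRE", "DRE"), n_el[i], replace = TRUE),
        strand = sample(c("+", "-"), n_el[i], replace = TRUE),
        offset = sort(sample(seq(1, 1900, by = 60), n_el[i])) +
          sample(0:30, n_el[i], replace = TRUE)
      )
    }))
  })
  promoters <- generate_promoters(12, length = 2000, planted = prom_plan,
                                  seed = seed + 5)
  write_fasta(promoters, paths$promoters, "DNA")

  # --- Ct table with known fold changes ------------------------------------
  fold_plan <- tidyr::expand_grid(
    gene = sprintf("gene%d", 1:7),
    condition = c("3h", "6h", "12h")
  ) %>%
    mutate(fold = withr::with_seed(seed + 6,
                                   round(2^runif(n(), -2, 2), 3)))
  ct <- generate_ct_table(fold_plan, calibrator = "CK",
                          replicate_sd = 0.15, n_replicates = 3,
                          seed = seed + 7)
  readr::write_tsv(ct, paths$ct_table, progress = FALSE)

  plans <- list(
    motif_plan = motif_plan,
    clade_plan = aln$plan,
    pair_plan = pair_plan,
    cds_plan = cds_plan,
    locus_plan = order_out$plan,
    promoter_plan = prom_plan,
    fold_plan = fold_plan
  )
  yaml::write_yaml(purrr::map(plans, ~as.list(as.data.frame(.x))),
                   paths$plan)
  config <- list(
    proteins = paths$proteins, alignment = paths$alignment,
    pairs = paths$pairs, cds = paths$cds, loci = paths$loci,
    blocks = paths$blocks, promoters = paths$promoters,
    ct_table = paths$ct_table,
    parameters = list(seed = seed, bootstrap = 200),
    out_dir = file.path(out_dir, "survey_out")
  )
  # the written config uses paths relative to the bundle directory, so the
  # bundle is relocatable and byte-identical across runs
  rel_config <- config
  for (k in setdiff(names(rel_config), "parameters")) {
    rel_config[[k]] <- basename(rel_config[[k]])
  }
  yaml::write_yaml(rel_config, paths$config)
  invisible(list(paths = paths, plans = plans, config = config))
}
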