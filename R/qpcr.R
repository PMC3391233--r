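# Relative expression from qPCR Ct tables by the 2^-delta-delta-Ct method
# with a reference (housekeeping) gene and a calibrator condition.

validate_ct_table <- function(table, reference_gene, calibrator) {
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  if (!reference_gene %in% table$gene) {
    abort(sprintf("reference gene '%s' absent from the table", reference_gene))
  }
  if (!calibrator %in% table$condition) {
    abort(sprintf("calibrator condition '%s' absent from the table", calibrator))
  }
  invisible(table)
}

#' Relative expression by 2^-delta-delta-Ct
#'
#' Per replicate, `dCt = Ct_target - Ct_reference` (paired by replicate
#' index within a condition); `ddCt = dCt - mean(dCt calibrator)`; the
#' per-replicate fold is `2^-ddCt`. The reported point estimate is
#' `2^-mean(ddCt)`, so the calibrator condition's fold is exactly 1, as in
#' "normalized to 1" conventions; `se` is the standard error over
#' per-replicate fold values (or over `log2` folds with
#' `log_scale_se = TRUE`).
#'
#' @param table Ct tibble (`gene`, `condition`, `replicate`, `ct`;
#'   optionally `replicate_type`).
#' @param reference_gene Housekeeping gene measured in every
#'   (condition, replicate).
#' @param calibrator Calibrator condition present for every gene.
#' @param replicate_type If the table carries a `replicate_type` column,
#'   restrict to this type (e.g. `"technical"`); `NULL` pools all.
#' @param log_scale_se Compute `se` on `log2` fold values instead.
#' @return Tibble (`gene`, `condition`, `delta_ct`, `delta_delta_ct`,
#'   `fold`, `se`, `n_replicates`), excluding the reference gene.
#' @export
delta_delta_ct <- function(table, reference_gene = "Actin1",
                           calibrator = "CK",
                           replicate_type = NULL,
                           log_scale_se = FALSE) {
  validate_ct_table(table, reference_gene, calibrator)
  if (!is.null(replicate_type) && "replicate_type" %in% names(table)) {
    table <- filter(table, .data$replicate_type == !!replicate_type)
  }
  ref <- table %>%
    filter(.data$gene == reference_gene) %>%
    select("condition", "replicate", ref_ct = "ct")
  targets <- filter(table, .data$gene != reference_gene)
  paired <- left_join(targets, ref, by = c("condition", "replicate"))
  if (anyNA(paired$ref_ct)) {
    bad <- paired[is.na(paired$ref_ct), ][1, ]
    abort(sprintf(
      "reference gene '%s' not measured for condition '%s' replicate %s",
      reference_gene, bad$condition, format(bad$replicate)))
  }
  dct <- mutate(paired, delta_ct = .data$ct - .data$ref_ct)
  cal <- dct %>%
    filter(.data$condition == calibrator) %>%
    group_by(.data$gene) %>%
    summarise(cal_dct = mean(.data$delta_ct))
  if (!all(unique(dct$gene) %in% cal$gene)) {
    missing <- setdiff(unique(dct$gene), cal$gene)
    abort(sprintf("calibrator '%s' missing for gene '%s'",
                  calibrator, missing[1]))
  }
  dct %>%
    left_join(cal, by = "gene") %>%
    mutate(ddct = .data$delta_ct - .data$cal_dct,
           rep_fold = 2^(-.data$ddct)) %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(
      delta_ct = mean(.data$delta_ct),
      # difference of means (not mean of per-replicate differences) so the
      # calibrator's ddCt is exactly zero and its fold exactly 1
      delta_delta_ct = mean(.data$delta_ct) - .data$cal_dct[1],
      fold = 2^(-(mean(.data$delta_ct) - .data$cal_dct[1])),
      se = if (log_scale_se) {
        sd(log2(.data$rep_fold)) / sqrt(n())
      } else {
        sd(.data$rep_fold) / sqrt(n())
      },
      n_replicates = n(),
      .groups = "drop"
    ) %>%
    mutate(se = ifelse(is.na(.data$se), 0, .data$se)) %>%
    arrange(.data$gene, .data$condition)
}

#' Tissue expression profile relative to a baseline tissue
#'
#' The delta-delta-Ct computation with a baseline tissue (e.g. leaf) as the
#' calibrator condition.
#'
#' @inheritParams delta_delta_ct
#' @param baseline_tissue Tissue used as calibrator.
#' @return See [delta_delta_ct()].
#' @export
tissue_profile <- function(table, reference_gene = "Actin1",
                           baseline_tissue = "leaf", ...) {
  delta_delta_ct(table, reference_gene = reference_gene,
                 calibrator = baseline_tissue, ...)
}
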