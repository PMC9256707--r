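#' Evaluate a synthetic study through the full scoring pipeline in memory
#'
#' Convenience driver used by replicate-based analyses: takes a
#' [make_study()] bundle and runs the same sequence as
#' [run_prs_pipeline()] without any file I/O — validation, ambiguity
#' filtering, harmonization at `alpha`, gene partition at `window_bp`,
#' inverse-variance weights, target QC, the three standardized scores and
#' their case/control associations, plus decile case rates for the
#' gene-based score.
#'
#' @param study a `synthetic_study`.
#' @param alpha concordance threshold.
#' @param window_bp gene-boundary window.
#' @param k_pcs genotype PCs added as covariates (0 for none).
#' @param use_random_effect passed to [fit_prs_association()].
#' @return list: `assoc` (named list of `prs_assoc` per score label, NULL
#'   where a partition is empty), `counts` (harmonized/concordant/
#'   intragenic/intergenic), `scores`, `deciles`, `decile_rates`, `partition`.
#' @export
evaluate_study <- function(study, alpha = 0.05, window_bp = 1000,
                           k_pcs = 10, use_random_effect = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  ss1 <- remove_ambiguous(validate_sumstats(study$sumstats_pop1, "pop1"))
  ss2 <- remove_ambiguous(validate_sumstats(study$sumstats_pop2, "pop2"))
  harm <- harmonize_sumstats(ss1, ss2, alpha = alpha)
  conc <- harm[concordant == TRUE]
  counts <- list(harmonized = nrow(harm), concordant = nrow(conc))

  part <- if (nrow(conc)) partition_by_genes(conc, study$genes, window_bp) else NULL
  counts$intragenic <- if (is.null(part)) 0L else sum(part$partition == "intragenic")
  counts$intergenic <- if (is.null(part)) 0L else sum(part$partition == "intergenic")

  weights_all <- ivw_meta(harm)
  ds <- subset_dosage_set(study$target, weights_all$key)
  ds <- qc_variants(ds)
  counts$qc_kept <- ncol(ds$dosages)

  pheno <- copy(study$pheno)
  if (k_pcs > 0) {
    pcs <- compute_pcs(ds, k = min(k_pcs, min(dim(ds$dosages)) - 1))
    pheno <- merge(pheno, data.table(sample_id = rownames(pcs),
                                     as.data.table(pcs)), by = "sample_id")
  }
  wsets <- list(
    PRS_gene = if (!is.null(part)) weights_all[key %in% part[partition == "intragenic", key]],
    PRS_intergenic = if (!is.null(part)) weights_all[key %in% part[partition == "intergenic", key]],
    PRS_all = weights_all
  )
  scores <- assoc <- list()
  for (lbl in names(wsets)) {
    w <- wsets[[lbl]]
    if (is.null(w) || nrow(w) == 0L || !any(w$key %in% ds$variants$key)) next
    prs <- standardize_prs(compute_prs(ds, w, label = lbl))
    scores[[lbl]] <- prs
    assoc[[lbl]] <- fit_prs_association(pheno, prs,
                                        use_random_effect = use_random_effect)
  }
  deciles <- rates <- NULL
  if (!is.null(scores$PRS_gene)) {
    deciles <- decile_strata(scores$PRS_gene)
    rates <- decile_case_rates(pheno, deciles)
  }
  list(assoc = assoc, counts = counts, scores = scores,
       deciles = deciles, decile_rates = rates, partition = part)
}
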