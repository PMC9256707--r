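#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by
#' [run_prs_pipeline()]. All paths must exist at run time; thresholds are
#' range-checked. A YAML file with the same keys can be loaded with
#' [read_pipeline_config()].
#'
#' @param sumstats_pop1,sumstats_pop2 discovery summary-statistics files.
#' @param genes gene-model file.
#' @param genotypes target dosage file (VCF with DS field, or matrix
#'   dialect).
#' @param phenotypes phenotype/covariate table (`sample_id`, `case`,
#'   optional `sex`, `PC*`, `cohort`, `family_id`).
#' @param external_weights optional externally estimated weight file; when
#'   given it replaces the inverse-variance meta-analysis weights.
#' @param alpha per-study concordance threshold.
#' @param window_bp gene-boundary window for the main partition.
#' @param sweep_windows optional vector of windows for a sweep summary.
#' @param maf_min,info_min,missing_max,hwe_p_min QC thresholds (see
#'   [qc_variants()]).
#' @param missing_policy missing-dosage policy for [compute_prs()].
#' @param reference_ids optional standardization reference group.
#' @param use_random_effect family random intercept in association models.
#' @param k_pcs number of genotype PCs to compute when the phenotype table
#'   carries none (0 disables).
#' @param out_dir output directory.
#' @return config list of class `prs_pipeline_config`.
#' @export
prs_pipeline_config <- function(sumstats_pop1, sumstats_pop2, genes,
                                genotypes, phenotypes,
                                external_weights = NULL,
                                alpha = 0.05, window_bp = 1000,
                                sweep_windows = NULL,
                                maf_min = 0.01, info_min = 0.30,
                                missing_max = 0.05, hwe_p_min = 1e-4,
                                missing_policy = "mean_impute",
                                reference_ids = NULL,
                                use_random_effect = FALSE, k_pcs = 10,
                                out_dir = "prs_pipeline_out") {
  cfg <- as.list(environment())
  for (f in c("sumstats_pop1", "sumstats_pop2", "genes", "genotypes", "phenotypes"))
    if (!file.exists(cfg[[f]])) stopf("config path '%s' does not exist: %s", f, cfg[[f]])
  if (!is.null(external_weights) && !file.exists(external_weights))
    stopf("external_weights file does not exist: %s", external_weights)
  stopifnot(alpha > 0, alpha <= 1, window_bp >= 0, k_pcs >= 0)
  structure(cfg, class = "prs_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [prs_pipeline_config()]
#'   arguments; relative paths are resolved against the file's directory.
#' @return validated config.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("sumstats_pop1", "sumstats_pop2", "genes", "genotypes",
              "phenotypes", "external_weights"))
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  do.call(prs_pipeline_config, raw)
}

#' Run the gene-based PRS pipeline end to end
#'
#' Executes the full sequence: read and validate both discovery GWAS,
#' drop strand-ambiguous variants, harmonize to a common effect allele and
#' flag concordant variants, partition the concordant set by gene
#' boundaries, derive scoring weights (inverse-variance meta-analysis, or
#' imported posteriors), load and QC target dosages, compute and
#' standardize `PRS_gene` (intragenic concordant variants),
#' `PRS_intergenic` (concordant variants outside gene boundaries) and
#' `PRS_all` (all harmonized variants), test each score's association with
#' case status, and stratify `PRS_gene` into deciles with odds ratios
#' against the bottom decile. All tables are written to
#' `config$out_dir` together with a JSON run report whose per-stage
#' counts reconcile exactly.
#'
#' @param config a [prs_pipeline_config()] or the path to a YAML file.
#' @return invisibly, a list with the report and all result objects.
#' @export
run_prs_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "prs_pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("geneprs")),
    r_version = as.character(getRversion()),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    parameters = config[!vapply(config, is.null, logical(1))],
    stages = list()
  )
  stage <- function(name, x) {
    report$stages[[name]] <<- filter_report(x)
    x
  }

  ss1 <- stage("read_pop1", read_sumstats(config$sumstats_pop1))
  ss2 <- stage("read_pop2", read_sumstats(config$sumstats_pop2))
  ss1 <- stage("ambiguous_pop1", remove_ambiguous(ss1))
  ss2 <- stage("ambiguous_pop2", remove_ambiguous(ss2))
  harm <- stage("harmonize", harmonize_sumstats(ss1, ss2, alpha = config$alpha))
  write_harmonized(harm, file.path(config$out_dir, "harmonized.tsv"))

  genes <- stage("genes", load_gene_models(config$genes))
  conc <- harm[concordant == TRUE]
  if (nrow(conc) == 0L) stopf("pipeline stage 'partition': no concordant variants")
  part <- stage("partition",
                partition_by_genes(conc, genes, window_bp = config$window_bp))
  fwrite(part, file.path(config$out_dir, "concordant_partition.tsv"), sep = "\t")
  sweep <- NULL
  if (!is.null(config$sweep_windows)) {
    sweep <- window_sweep(conc, genes, windows = config$sweep_windows)
    fwrite(sweep, file.path(config$out_dir, "window_sweep.tsv"), sep = "\t")
  }

  weights_all <- if (is.null(config$external_weights)) {
    stage("weights", ivw_meta(harm))
  } else {
    stage("weights", read_external_weights(config$external_weights, harm))
  }
  wsets <- list(
    PRS_gene = weights_all[key %in% part[partition == "intragenic", key]],
    PRS_intergenic = weights_all[key %in% part[partition == "intergenic", key]],
    PRS_all = weights_all
  )
  for (lbl in names(wsets))
    write_weights(wsets[[lbl]], file.path(config$out_dir, paste0("weights_", lbl, ".tsv")))

  ds <- stage("load_dosages",
              load_dosages(config$genotypes, variant_subset = weights_all))
  ds <- stage("qc", qc_variants(ds, maf_min = config$maf_min,
                                info_min = config$info_min,
                                missing_max = config$missing_max,
                                hwe_p_min = config$hwe_p_min))

  pheno <- fread(config$phenotypes)
  if (!all(c("sample_id", "case") %in% names(pheno)))
    stopf("phenotype table must contain sample_id and case columns")
  pheno[, sample_id := as.character(sample_id)]
  if (config$k_pcs > 0 && !any(grepl("^PC[0-9]+$", names(pheno)))) {
    pcs <- compute_pcs(ds, k = min(config$k_pcs, min(dim(ds$dosages)) - 1))
    pheno <- merge(pheno,
                   data.table(sample_id = rownames(pcs), as.data.table(pcs)),
                   by = "sample_id")
  }

  scores <- list()
  assoc <- list()
  for (lbl in names(wsets)) {
    w <- wsets[[lbl]]
    if (nrow(w) == 0L) {
      scores[[lbl]] <- NULL
      assoc[[lbl]] <- list(label = lbl, note = "no variants in this partition")
      next
    }
    prs <- compute_prs(ds, w, missing_policy = config$missing_policy, label = lbl)
    prs <- standardize_prs(prs, reference_ids = config$reference_ids)
    write_prs(prs, file.path(config$out_dir, paste0("scores_", lbl, ".tsv")))
    scores[[lbl]] <- prs
    a <- fit_prs_association(pheno, prs,
                             use_random_effect = config$use_random_effect)
    assoc[[lbl]] <- c(unclass(a),
                      list(n_variants = attr(prs, "n_variants") %||% nrow(w)))
  }
  assoc_dt <- rbindlist(lapply(assoc, function(a) {
    data.table(label = a$label, beta = a$beta %||% NA_real_,
               se = a$se %||% NA_real_, pvalue = a$p %||% NA_real_,
               n_variants = a$n_variants %||% 0L, n = a$n %||% NA_integer_,
               model = a$model %||% NA_character_)
  }))
  fwrite(assoc_dt, file.path(config$out_dir, "associations.tsv"), sep = "\t")

  deciles <- or_tab <- rates <- NULL
  if (!is.null(scores$PRS_gene) && nrow(scores$PRS_gene) >= 10) {
    deciles <- decile_strata(scores$PRS_gene)
    rates <- decile_case_rates(pheno, deciles)
    fwrite(rates, file.path(config$out_dir, "decile_case_rates.tsv"), sep = "\t")
    or_tab <- tryCatch(decile_or(pheno, deciles), error = function(e) {
      report$stages$decile_or <<- list(skipped = conditionMessage(e))
      NULL
    })
    if (!is.null(or_tab))
      fwrite(or_tab, file.path(config$out_dir, "decile_or.tsv"), sep = "\t")
  }

  report$stages$scores <- list(
    n_gene = nrow(wsets$PRS_gene), n_intergenic = nrow(wsets$PRS_intergenic),
    n_all = nrow(wsets$PRS_all),
    partition_conserved = nrow(wsets$PRS_gene[key %in% conc$key]) +
      nrow(wsets$PRS_intergenic[key %in% conc$key])
  )
  report$associations <- assoc_dt
  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(report = report, harmonized = harm, partition = part,
                 sweep = sweep, weights = wsets, dosages = ds, pheno = pheno,
                 scores = scores, associations = assoc, assoc_table = assoc_dt,
                 deciles = deciles, decile_or = or_tab,
                 decile_case_rates = rates))
}
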