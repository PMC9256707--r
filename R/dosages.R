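#' Construct a dosage set
#'
#' A `dosage_set` bundles a samples x variants matrix of expected
#' effect-allele counts (entries in \[0, 2\] or `NA` for missing) with
#' per-variant metadata. `eaf` and `missing_rate` are recomputed from the
#' matrix so they always describe the data as held.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   `colnames` are variant keys, `rownames` sample ids.
#' @param variants `data.table` with `key`, `variant_id`, `chrom`, `pos`,
#'   `effect_allele` (the counted allele), `other_allele`, optional `info`.
#' @return object of class `dosage_set`.
#' @export
dosage_set <- function(dosages, variants) {
  variants <- as.data.table(variants)
  if (ncol(dosages) != nrow(variants))
    stopf("dosage matrix has %d columns but %d variant records",
          ncol(dosages), nrow(variants))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$key
  if (!identical(colnames(dosages), variants$key))
    stopf("dosage column names do not match variant keys")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stopf("dosages must lie in [0, 2]")
  if (!"info" %in% names(variants)) variants[, info := NA_real_]
  variants[, eaf := colMeans(dosages, na.rm = TRUE) / 2]
  variants[, missing_rate := colMeans(is.na(dosages))]
  structure(list(dosages = dosages, variants = variants[],
                 samples = rownames(dosages)),
            class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat(sprintf("dosage_set: %d samples x %d variants (mean missing %.3f)\n",
              nrow(x$dosages), ncol(x$dosages),
              mean(x$variants$missing_rate)))
  invisible(x)
}

#' @export
dim.dosage_set <- function(x) dim(x$dosages)

subset_dosage_set <- function(ds, keys) {
  idx <- match(keys, ds$variants$key)
  idx <- idx[!is.na(idx)]
  dosage_set(ds$dosages[, idx, drop = FALSE], ds$variants[idx])
}

#' Load target-cohort dosages
#'
#' Reads imputed genotype dosages either from a VCF with a `DS` FORMAT
#' field (the counted allele is ALT, per convention) or from a plain
#' tab-separated matrix dialect with columns `variant_id`, `chrom`, `pos`,
#' `counted_allele`, `other_allele`, optional `info`, followed by one
#' column per sample. When `variant_subset` is given (a table with `key`
#' and `effect_allele`, e.g. a harmonized or weight table), only those
#' variants are loaded and every dosage is oriented to the subset's effect
#' allele: where the file counts the other allele of the pair, dosages are
#' flipped to `2 - d`.
#'
#' @param path input file; dialect chosen by extension (`.vcf` vs anything
#'   else) unless `dialect` is given.
#' @param variant_subset optional table with `key`, `effect_allele` (and
#'   `other_allele`) columns.
#' @param dialect `"auto"`, `"vcf"` or `"matrix"`.
#' @return a [dosage_set()].
#' @export
load_dosages <- function(path, variant_subset = NULL,
                         dialect = c("auto", "vcf", "matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("dosage file not found: %s", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"

  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.table(vcfR::getFIX(vcf))
    ds <- t(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    info <- suppressWarnings(as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1",
                                            vcfR::getINFO(vcf))))
    variants <- data.table(
      variant_id = fix$ID, chrom = as.character(fix$CHROM),
      pos = as.numeric(fix$POS),
      effect_allele = toupper(fix$ALT), other_allele = toupper(fix$REF),
      info = info
    )
  } else {
    dt <- fread(path, header = TRUE)
    meta_cols <- intersect(c("variant_id", "chrom", "pos", "counted_allele",
                             "other_allele", "info"), names(dt))
    need <- c("variant_id", "chrom", "pos", "counted_allele", "other_allele")
    miss <- setdiff(need, meta_cols)
    if (length(miss)) stopf("dosage matrix missing column(s): %s",
                            paste(miss, collapse = ", "))
    sample_cols <- setdiff(names(dt), meta_cols)
    if (length(sample_cols) == 0L) stopf("dosage matrix has no sample columns")
    variants <- dt[, .(variant_id = as.character(variant_id),
                       chrom = as.character(chrom), pos = as.numeric(pos),
                       effect_allele = toupper(counted_allele),
                       other_allele = toupper(other_allele))]
    variants[, info := if ("info" %in% meta_cols) as.numeric(dt$info) else NA_real_]
    ds <- t(as.matrix(dt[, sample_cols, with = FALSE]))
    colnames(ds) <- NULL
  }
  variants[, key := variant_key(chrom, pos, effect_allele, other_allele)]
  colnames(ds) <- variants$key
  n_file <- nrow(variants)
  flipped <- 0L
  if (!is.null(variant_subset)) {
    sub <- as.data.table(variant_subset)
    idx <- match(sub$key, variants$key)
    found <- !is.na(idx)
    if (!any(found)) stopf("none of the requested variants found in %s", path)
    idx <- idx[found]
    variants <- variants[idx]
    ds <- ds[, idx, drop = FALSE]
    want <- sub$effect_allele[found]
    flip <- want == variants$other_allele
    if (any(flip)) {
      ds[, flip] <- 2 - ds[, flip, drop = FALSE]
      variants[flip, `:=`(effect_allele = other_allele,
                          other_allele = effect_allele)]
      flipped <- sum(flip)
    }
    mism <- want != variants$effect_allele
    if (any(mism))
      stopf("allele mismatch for variant(s): %s",
            paste(utils::head(variants$key[mism], 5), collapse = ", "))
  }
  setcolorder(variants, c("key", "variant_id", "chrom", "pos",
                          "effect_allele", "other_allele", "info"))
  out <- dosage_set(ds, variants)
  set_report(out, list(in_file = n_file, loaded = ncol(ds),
                       flipped_to_effect_allele = flipped))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the 1-df chi-square goodness-of-fit of observed genotype
#' counts against the p^2 / 2pq / q^2 expectation — simple and adequate for
#' QC at the thresholds used here. `method = "exact"` gives the standard
#' mid-*p*-free exact test (sum of probabilities of heterozygote counts no
#' more probable than the observed one, conditional on the allele counts).
#' A monomorphic variant carries no HWE information and returns `p = 1`
#' with a `monomorphic` attribute set.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value in (0, 1]; attribute `monomorphic` flags degenerate input.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0) || (n_AA + n_Aa + n_aa) <= 0)
    stopf("genotype counts must be non-negative with positive total")
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(structure(1, monomorphic = TRUE))
  p <- nA / (2 * n)
  if (method == "chisq") {
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    # enumerate heterozygote counts compatible with the allele counts
    het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    logpr <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
      lfactorial(n - (nA + het) / 2) + het * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    pr <- exp(logpr - max(logpr))
    pr <- pr / sum(pr)
    pv <- sum(pr[pr <= pr[match(n_Aa, het)] * (1 + 1e-12)])
  }
  structure(min(max(pv, .Machine$double.xmin), 1), monomorphic = FALSE)
}

#' Variant quality control on a dosage set
#'
#' Applies the standard post-imputation inclusion filters: minor allele
#' frequency, imputation quality, per-variant missing rate, and a
#' Hardy-Weinberg test on best-guess genotypes (dosages rounded to 0/1/2).
#' Defaults follow common post-imputation practice: `maf_min = 0.01`,
#' `info_min = 0.30`, `missing_max = 0.05`, `hwe_p_min = 1e-4`. Variants
#' with unknown imputation quality (`info = NA`) are not filtered on it.
#'
#' @param ds a [dosage_set()].
#' @param maf_min minimum minor-allele frequency (computed from dosages).
#' @param info_min minimum imputation quality.
#' @param missing_max maximum per-variant missing rate.
#' @param hwe_p_min minimum HWE p-value.
#' @param hwe_method passed to [hwe_test()].
#' @return filtered `dosage_set`; the report counts removals per filter
#'   (a variant failing several filters is counted under each).
#' @export
qc_variants <- function(ds, maf_min = 0.01, info_min = 0.30,
                        missing_max = 0.05, hwe_p_min = 1e-4,
                        hwe_method = "chisq") {
  stopifnot(inherits(ds, "dosage_set"))
  for (thr in c(maf_min, info_min, missing_max))
    if (!is.finite(thr) || thr < 0 || thr > 1) stopf("QC thresholds must lie in [0, 1]")
  if (!is.finite(hwe_p_min) || hwe_p_min < 0 || hwe_p_min > 1)
    stopf("hwe_p_min must lie in [0, 1]")
  v <- ds$variants
  maf <- pmin(v$eaf, 1 - v$eaf)
  g <- round(ds$dosages)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    as.numeric(hwe_test(sum(g[, j] == 2, na.rm = TRUE),
                        sum(g[, j] == 1, na.rm = TRUE),
                        sum(g[, j] == 0, na.rm = TRUE),
                        method = hwe_method))
  }, numeric(1))
  fail_maf <- maf < maf_min
  fail_info <- !is.na(v$info) & v$info < info_min
  fail_miss <- v$missing_rate > missing_max
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_info | fail_miss | fail_hwe)
  if (!any(keep)) stopf("all variants removed by QC")
  vkeep <- copy(v[keep])
  vkeep[, c("eaf", "missing_rate") := NULL]
  out <- dosage_set(ds$dosages[, keep, drop = FALSE], vkeep)
  set_report(out, list(input = ncol(ds$dosages),
                       removed_maf = sum(fail_maf),
                       removed_info = sum(fail_info),
                       removed_missing = sum(fail_miss),
                       removed_hwe = sum(fail_hwe),
                       kept = sum(keep)))
}
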