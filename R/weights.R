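#' Fixed-effect inverse-variance meta-analysis weights
#'
#' Combines the two harmonized per-variant effect estimates into a single
#' scoring weight by fixed-effect inverse-variance weighting:
#' \deqn{\beta_{meta} = \frac{\beta_1/se_1^2 + \beta_2/se_2^2}
#'                           {1/se_1^2 + 1/se_2^2},\qquad
#'       se_{meta} = (1/se_1^2 + 1/se_2^2)^{-1/2}.}
#' A fixed-effect (rather than random-effects) model is used because the
#' framework targets variants assumed to share their effect across
#' populations; under that premise precision weighting is the efficient
#' combination. Variants with non-finite inputs are dropped and counted.
#'
#' @param harmonized output of [harmonize_sumstats()] (any subset of rows).
#' @return a weight table: `key`, `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `weight` (= meta beta), `se_meta`,
#'   `source = "ivw_meta"`.
#' @export
ivw_meta <- function(harmonized) {
  h <- as.data.table(harmonized)
  ok <- is.finite(h$beta_pop1) & is.finite(h$beta_pop2) &
    is.finite(h$se_pop1) & is.finite(h$se_pop2) & h$se_pop1 > 0 & h$se_pop2 > 0
  out <- h[ok]
  if (nrow(out) == 0L) stopf("no variants with finite effects to meta-analyze")
  w1 <- 1 / out$se_pop1^2
  w2 <- 1 / out$se_pop2^2
  out <- out[, .(key, variant_id, chrom, pos, effect_allele, other_allele)]
  out[, weight := (h$beta_pop1[ok] * w1 + h$beta_pop2[ok] * w2) / (w1 + w2)]
  out[, se_meta := 1 / sqrt(w1 + w2)]
  out[, source := "ivw_meta"]
  set_report(out[], list(input = nrow(h), dropped_nonfinite = sum(!ok), kept = nrow(out)))
}

#' Import externally estimated scoring weights
#'
#' Reads a tab-separated weight file (columns `variant_id`, `effect_allele`,
#' `weight`, optional `chrom`/`pos`/`other_allele`), typically posterior
#' effect sizes from a cross-population shrinkage method, and aligns each
#' weight to the harmonized effect allele: a weight stated for the other
#' allele of the pair has its sign flipped. Variants absent from the
#' harmonized set, or whose alleles match neither side of the harmonized
#' pair, are dropped and counted.
#'
#' @param path weight file.
#' @param harmonized output of [harmonize_sumstats()]; defines the variant
#'   universe and allele alignment.
#' @return weight table as in [ivw_meta()], with `source = "external"`.
#' @export
read_external_weights <- function(path, harmonized) {
  if (!file.exists(path)) stopf("weight file not found: %s", path)
  w <- fread(path, header = TRUE)
  need <- c("variant_id", "effect_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss)) stopf("weight file missing column(s): %s", paste(miss, collapse = ", "))
  w[, `:=`(variant_id = as.character(variant_id),
           effect_allele = toupper(as.character(effect_allele)),
           weight = as.numeric(weight))]

  h <- as.data.table(harmonized)[, .(key, variant_id, chrom, pos,
                                     effect_allele, other_allele)]
  m <- merge(h, w[, .(variant_id, ext_allele = effect_allele, ext_weight = weight)],
             by = "variant_id")
  n_unknown <- nrow(w) - length(unique(m$variant_id))
  same <- m$ext_allele == m$effect_allele
  flip <- m$ext_allele == m$other_allele
  mism <- !(same | flip) | !is.finite(m$ext_weight)
  out <- m[!mism]
  out[, weight := fifelse(ext_allele == effect_allele, ext_weight, -ext_weight)]
  out <- out[, .(key, variant_id, chrom, pos, effect_allele, other_allele, weight)]
  out[, se_meta := NA_real_]
  out[, source := "external"]
  if (nrow(out) == 0L) stopf("no usable external weights after allele alignment")
  set_report(out[], list(input = nrow(w), not_in_harmonized = n_unknown,
                         dropped_allele_mismatch = sum(mism), kept = nrow(out)))
}

#' Write a weight table in score-file layout
#'
#' Column order (variant id, effect allele, weight) follows the PLINK
#' `--score` input convention.
#'
#' @param weights weight table from [ivw_meta()] or [read_external_weights()].
#' @param path output file.
#' @export
write_weights <- function(weights, path) {
  fwrite(as.data.table(weights)[, .(variant_id, effect_allele, weight)],
         path, sep = "\t")
  invisible(path)
}
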