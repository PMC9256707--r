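#' Compute a raw polygenic risk score
#'
#' The raw PRS of sample *i* is the weighted dosage sum
#' \eqn{\sum_j w_j d_{ij}} over the scored variants — a weighted *sum*,
#' not an allele-count-normalized average, for bit-compatibility with
#' summed PLINK `--score` output (standardization later makes the choice
#' immaterial for association testing). Every scored variant must carry a
#' weight whose effect allele matches the dosage set's counted allele;
#' any mismatch is a hard error naming the variant. Missing dosages are
#' handled by `missing_policy`:
#' \describe{
#'   \item{`mean_impute`}{(default) replace a missing dosage with
#'     `2 * eaf` of that variant in the target data — the PLINK default.}
#'   \item{`skip`}{the variant contributes nothing for that sample.}
#' }
#'
#' @param ds a [dosage_set()].
#' @param weights weight table ([ivw_meta()] / [read_external_weights()]);
#'   only variants present in `ds` are scored.
#' @param missing_policy `"mean_impute"` or `"skip"`.
#' @param label score label, e.g. `"PRS_gene"`.
#' @return `data.table` with `sample_id`, `raw_score`, `label`; attributes
#'   `n_variants` (number scored) and the usual report.
#' @export
compute_prs <- function(ds, weights, missing_policy = c("mean_impute", "skip"),
                        label = "PRS") {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(ds, "dosage_set"))
  w <- as.data.table(weights)
  idx <- match(w$key, ds$variants$key)
  found <- !is.na(idx)
  if (!any(found)) stopf("no weighted variants present in the dosage set")
  w <- w[found]
  idx <- idx[found]
  mism <- w$effect_allele != ds$variants$effect_allele[idx]
  if (any(mism))
    stopf("weight/dosage effect-allele mismatch for variant(s): %s",
          paste(utils::head(w$key[mism], 5), collapse = ", "))

  d <- ds$dosages[, idx, drop = FALSE]
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      fill <- 2 * ds$variants$eaf[idx]
      na_idx <- which(is.na(d), arr.ind = TRUE)
      d[na_idx] <- fill[na_idx[, 2]]
    } else {
      d[is.na(d)] <- 0
    }
  }
  raw <- as.numeric(d %*% w$weight)
  out <- data.table(sample_id = ds$samples, raw_score = raw, label = label)
  attr(out, "n_variants") <- nrow(w)
  set_report(out[], list(weights_in = nrow(weights), scored = nrow(w),
                         not_in_dosages = sum(!found),
                         missing_policy = missing_policy))
}

#' Standardize PRS to z-units in a reference group
#'
#' Transforms raw scores as `z = (raw - mean_ref) / sd_ref`, where the mean
#' and (n-1)-denominator standard deviation are taken over the reference
#' group — by default all samples, matching the usual practice of
#' standardizing within the combined analysis cohort. The transform is
#' applied to *all* samples, so the reference group attains mean 0 / sd 1
#' and other samples are expressed on the same scale.
#'
#' @param prs output of [compute_prs()].
#' @param reference_ids sample ids defining the reference group; default
#'   all samples. Must contain at least 2 samples with non-zero score
#'   variance.
#' @return the input table with a `standardized_score` column added.
#' @export
standardize_prs <- function(prs, reference_ids = NULL) {
  prs <- as.data.table(prs)
  ref <- if (is.null(reference_ids)) prs$raw_score else {
    missing_ref <- setdiff(reference_ids, prs$sample_id)
    if (length(missing_ref))
      stopf("reference sample(s) absent from scores: %s",
            paste(utils::head(missing_ref, 5), collapse = ", "))
    prs$raw_score[prs$sample_id %in% reference_ids]
  }
  if (length(ref) < 2) stopf("reference group must contain at least 2 samples")
  m <- mean(ref)
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stopf("reference scores have zero variance")
  out <- copy(prs)
  out[, standardized_score := (raw_score - m) / s]
  out[]
}

#' Write per-sample PRS to disk
#'
#' @param prs standardized score table.
#' @param path output file (tab-separated).
#' @export
write_prs <- function(prs, path) {
  fwrite(as.data.table(prs), path, sep = "\t")
  invisible(path)
}
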