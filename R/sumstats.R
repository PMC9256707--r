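#' @importFrom data.table fread fwrite data.table as.data.table setnames
#'   setcolorder setkeyv copy rbindlist fifelse `:=` .N .SD
NULL

# default header names, the common GWAS summary-statistics convention
.default_sumstats_cols <- c(
  variant_id = "SNP", chrom = "CHR", pos = "BP",
  effect_allele = "A1", other_allele = "A2",
  beta = "BETA", se = "SE", pvalue = "P", n = "N",
  eaf = "FRQ", info = "INFO"
)

.mandatory_sumstats_cols <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "pvalue", "n"
)

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-separated summary-statistics file with a header, renames
#' columns according to `column_map`, coerces types, and drops rows that
#' violate the per-record invariants: alleles must be single bases A/C/G/T
#' with effect != other, `se > 0`, `pvalue` in (0, 1], `n > 0`, `eaf` and
#' `info` in \[0, 1\] when present, and one record per (chrom, pos,
#' unordered allele pair). For duplicated sites the first occurrence is
#' kept. Dropped rows are counted by reason in the attached report
#' (see [filter_report()]).
#'
#' @param path path to a tab- (or white-space-) separated file with header.
#' @param column_map named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pvalue`, `n`, `eaf`, `info`) to the file's header names.
#'   Defaults to the PLINK-style `SNP, CHR, BP, A1, A2, BETA, SE, P, N,
#'   FRQ, INFO`. `eaf` and `info` are optional.
#' @return a `data.table` of validated records with a `key` column
#'   (see [variant_key()]) and a drop report attribute.
#' @export
read_sumstats <- function(path, column_map = .default_sumstats_cols) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  column_map <- c(column_map,
                  .default_sumstats_cols[setdiff(names(.default_sumstats_cols),
                                                 names(column_map))])
  dt <- fread(path, header = TRUE, colClasses = list(character = unname(column_map[c("chrom")])))
  for (field in .mandatory_sumstats_cols) {
    src <- column_map[[field]]
    if (is.null(src) || !src %in% names(dt))
      stopf("mandatory column '%s' (mapped from '%s') missing in %s",
            field, column_map[[field]] %||% "<unmapped>", path)
  }
  present <- column_map[column_map %in% names(dt)]
  dt <- dt[, unname(present), with = FALSE]
  setnames(dt, unname(present), names(present))
  if (!"eaf" %in% names(dt)) dt[, eaf := NA_real_]
  if (!"info" %in% names(dt)) dt[, info := NA_real_]
  validate_sumstats(dt, source = path)
}

#' Validate summary-statistics records
#'
#' Applies the record invariants to an in-memory table (the workhorse behind
#' [read_sumstats()], exported so simulated tables can be pushed through the
#' same checks).
#'
#' @param dt a data.table/data.frame with the internal column names.
#' @param source label used in error messages.
#' @return validated `data.table` with drop report.
#' @export
validate_sumstats <- function(dt, source = "sumstats") {
  dt <- as.data.table(dt)
  dt[, chrom := as.character(chrom)]
  for (col in c("pos", "beta", "se", "pvalue", "n", "eaf", "info"))
    if (col %in% names(dt)) dt[, (col) := as.numeric(get(col))]
  dt[, effect_allele := toupper(as.character(effect_allele))]
  dt[, other_allele := toupper(as.character(other_allele))]

  n0 <- nrow(dt)
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(dt$effect_allele %in% bases) | !(dt$other_allele %in% bases) |
    dt$effect_allele == dt$other_allele
  bad_num <- !is.finite(dt$beta) | !is.finite(dt$se) | dt$se <= 0 |
    !is.finite(dt$pvalue) | dt$pvalue <= 0 | dt$pvalue > 1 |
    !is.finite(dt$n) | dt$n <= 0 | !is.finite(dt$pos) | dt$pos < 1
  bad_eaf <- !is.na(dt$eaf) & (dt$eaf < 0 | dt$eaf > 1)
  bad_info <- !is.na(dt$info) & (dt$info < 0 | dt$info > 1)
  bad <- bad_allele | bad_num | bad_eaf | bad_info
  kept <- dt[!bad]
  kept[, key := variant_key(chrom, pos, effect_allele, other_allele)]
  dup <- duplicated(kept$key)
  report <- list(
    input = n0,
    dropped_invalid_alleles = sum(bad_allele, na.rm = TRUE),
    dropped_invalid_numeric = sum(bad_num & !bad_allele, na.rm = TRUE),
    dropped_invalid_freq_info = sum((bad_eaf | bad_info) & !bad_allele & !bad_num, na.rm = TRUE),
    dropped_duplicate_site = sum(dup),
    kept = sum(!dup)
  )
  kept <- kept[!dup]
  if (nrow(kept) == 0L) stopf("no valid summary-statistics rows in %s", source)
  set_report(kept[], report)
}

#' Remove strand-ambiguous variants
#'
#' Drops variants whose allele pair is A/T or C/G. Such pairs read the same
#' on both DNA strands, so an effect reported by another study cannot be
#' oriented reliably; removing them (rather than attempting strand
#' resolution) is the standard conservative choice when combining GWAS.
#' All other records pass through unchanged, in their original order.
#'
#' @param records validated summary statistics from [read_sumstats()].
#' @return the non-ambiguous subset, with a report counting removals.
#' @export
remove_ambiguous <- function(records) {
  records <- as.data.table(records)
  amb <- is_ambiguous_pair(records$effect_allele, records$other_allele)
  out <- records[!amb]
  set_report(out[], list(input = nrow(records),
                         dropped_ambiguous = sum(amb),
                         kept = nrow(out)))
}

#' Harmonize two GWAS summary-statistics tables
#'
#' Inner-joins two validated, ambiguity-filtered tables on (chromosome,
#' position, unordered allele pair) — or on `variant_id` with
#' `join_on = "id"` — and expresses both studies' effects for population
#' 1's effect allele. When the effect alleles differ, population 2's beta
#' sign is flipped and its effect-allele frequency replaced by `1 - eaf`.
#' Sites whose allele pairs do not match are dropped and counted; no strand
#' flipping is attempted. Each variant is then flagged *concordant* when
#' `p < alpha` in both studies (strict inequality) and the aligned effects
#' have the same non-zero sign; a zero beta in either study has no defined
#' direction and is never concordant.
#'
#' @param table_pop1,table_pop2 validated tables (see [read_sumstats()]).
#' @param alpha per-study nominal significance threshold; default 0.05.
#' @param join_on `"site"` (default; chrom/pos/allele-pair key) or `"id"`
#'   (variant_id).
#' @return a `data.table` with columns `key`, `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta_pop1`, `se_pop1`, `p_pop1`,
#'   `n_pop1`, `eaf_pop1`, and the `_pop2` counterparts aligned to the same
#'   effect allele, plus `concordant`. Report counts non-overlapping and
#'   allele-mismatched variants.
#' @export
harmonize_sumstats <- function(table_pop1, table_pop2, alpha = 0.05,
                               join_on = c("site", "id")) {
  join_on <- match.arg(join_on)
  t1 <- as.data.table(table_pop1)
  t2 <- as.data.table(table_pop2)
  if (join_on == "site") {
    # join on position; allele-pair compatibility is checked afterwards so
    # that incompatible pairs at a shared site can be reported
    m <- merge(t1, t2, by = c("chrom", "pos"), suffixes = c("_pop1", "_pop2"),
               allow.cartesian = TRUE)
  } else {
    if (anyDuplicated(t1$variant_id) || anyDuplicated(t2$variant_id))
      stopf("join_on = 'id' requires unique variant_id in both tables")
    m <- merge(t1, t2, by = "variant_id", suffixes = c("_pop1", "_pop2"))
    m[, `:=`(chrom = chrom_pop1, pos = pos_pop1)]
  }
  n_overlap <- nrow(m)
  if (n_overlap == 0L) stopf("no overlapping variants between the two tables")

  same <- m$effect_allele_pop1 == m$effect_allele_pop2 &
    m$other_allele_pop1 == m$other_allele_pop2
  flipped <- m$effect_allele_pop1 == m$other_allele_pop2 &
    m$other_allele_pop1 == m$effect_allele_pop2
  mism <- !(same | flipped)
  out <- m[!mism]
  flp <- flipped[!mism]
  out[flp, `:=`(beta_pop2 = -beta_pop2, eaf_pop2 = 1 - eaf_pop2)]

  vid <- if (join_on == "site") out$variant_id_pop1 else out$variant_id
  out <- out[, .(
    key = variant_key(chrom, pos, effect_allele_pop1, other_allele_pop1),
    variant_id = vid,
    chrom, pos,
    effect_allele = effect_allele_pop1, other_allele = other_allele_pop1,
    beta_pop1, se_pop1, p_pop1 = pvalue_pop1, n_pop1, eaf_pop1,
    beta_pop2, se_pop2, p_pop2 = pvalue_pop2, n_pop2, eaf_pop2
  )]
  out[, concordant := p_pop1 < alpha & p_pop2 < alpha &
        sign(beta_pop1) == sign(beta_pop2) & beta_pop1 != 0 & beta_pop2 != 0]
  report <- list(
    n_pop1 = nrow(t1), n_pop2 = nrow(t2), overlapping = n_overlap,
    dropped_allele_mismatch = sum(mism),
    flipped_to_pop1_allele = sum(flp),
    harmonized = nrow(out), concordant = sum(out$concordant),
    alpha = alpha
  )
  set_report(out[], report)
}

#' Write a harmonized table to disk
#'
#' @param harmonized output of [harmonize_sumstats()].
#' @param path output file (tab-separated, with header).
#' @export
write_harmonized <- function(harmonized, path) {
  fwrite(harmonized, path, sep = "\t")
  invisible(path)
}
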