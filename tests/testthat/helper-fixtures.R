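library(data.table)

# in-memory summary-statistics table in the file's column layout
raw_sumstats <- function(id, chrom, pos, a1, a2, beta, se = 0.05,
                         p = 0.5, n = 1000, eaf = 0.3, info = 0.9) {
  data.table(SNP = id, CHR = chrom, BP = pos, A1 = a1, A2 = a2,
             BETA = beta, SE = se, P = p, N = n, FRQ = eaf, INFO = info)
}

write_tsv_tmp <- function(dt, name = "tbl") {
  path <- tempfile(name, fileext = ".tsv")
  fwrite(dt, path, sep = "\t")
  path
}

# validated in-memory sumstats (bypasses file round trip)
mem_sumstats <- function(...) {
  dt <- raw_sumstats(...)
  setnames(dt, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N",
                 "FRQ", "INFO"),
           c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "beta", "se", "pvalue", "n", "eaf", "info"))
  validate_sumstats(dt)
}

toy_genes <- function() {
  data.table(gene_id = c("GA", "GB", "GC"),
             chrom = c("1", "1", "2"),
             start = c(10000L, 50000L, 10000L),
             end = c(20000L, 60000L, 15000L),
             strand = c("+", "-", "+"))
}

toy_variants <- function(pos, chrom = "1") {
  dt <- data.table(variant_id = sprintf("v%03d", seq_along(pos)),
                   chrom = chrom, pos = pos,
                   effect_allele = "A", other_allele = "G")
  dt[, key := sprintf("%s:%d:A:G", chrom, pos)]
  setcolorder(dt, "key")
  dt[]
}

toy_dosage_set <- function(d, chrom = "1", pos = NULL, info = 0.9) {
  n <- nrow(d)
  m <- ncol(d)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  v <- data.table(variant_id = sprintf("v%03d", seq_len(m)),
                  chrom = chrom, pos = pos,
                  effect_allele = "A", other_allele = "G", info = info)
  v[, key := variant_key(chrom, pos, effect_allele, other_allele)]
  setcolorder(v, c("key", "variant_id", "chrom", "pos",
                   "effect_allele", "other_allele", "info"))
  colnames(d) <- v$key
  rownames(d) <- sprintf("S%03d", seq_len(n))
  dosage_set(d, v)
}

# independent logistic ML oracle: BFGS on the log-likelihood, SE from the
# numeric Hessian (deliberately avoids glm/IRLS)
logistic_oracle <- function(x, y) {
  X <- cbind(1, x)
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 500))
  se <- sqrt(diag(solve(fit$hessian)))
  list(beta = fit$par[2], se = se[2],
       p = 2 * pnorm(-abs(fit$par[2] / se[2])))
}
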