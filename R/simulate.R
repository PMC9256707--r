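#' Simulation configuration for a two-population synthetic study
#'
#' Bundles every knob of the synthetic generator with validated defaults.
#' The default regime mirrors the study design the pipeline targets: two
#' ancestral populations diverged at FST 0.1, causal variants concentrated
#' inside genes, liability-scale heritability 0.3 at 20% prevalence, two
#' discovery cohorts of 20,000 and a target cohort of 2,000.
#'
#' @param n_variants number of bi-allelic variants on the toy chromosome.
#' @param n_genes number of genes.
#' @param genome_bp chromosome length in base pairs.
#' @param gene_len_range min/max gene length (bp), drawn uniformly.
#' @param fst Balding-Nichols divergence between the two populations,
#'   in \[0, 1).
#' @param maf_range range of the uniform ancestral allele frequency.
#' @param prop_causal fraction of variants with non-zero effect.
#' @param prop_causal_intragenic fraction of causal variants placed inside
#'   gene bodies.
#' @param h2_liability liability-scale heritability in \[0, 1).
#' @param prevalence population case prevalence K in (0, 1).
#' @param n_discovery_pop1,n_discovery_pop2,n_target cohort sizes.
#' @param ld_block_size variants per LD block (1 = no LD).
#' @param ld_rho latent (copula) correlation within an LD block, in \[0, 1).
#' @param n_families number of sibships in the target cohort (0 = all
#'   unrelated); each sibship has `family_size` members sharing a
#'   `family_var` liability component.
#' @param family_size members per sibship.
#' @param family_var variance of the shared family liability component;
#'   must satisfy `h2_liability + family_var < 1`.
#' @param assoc_method discovery association engine passed to
#'   [generate_discovery_sumstats()]: `"score"` (default; vectorized score
#'   test, the practical choice at discovery-cohort sizes) or
#'   `"logistic"` (per-variant ML fits).
#' @param ambiguous_rate fraction of variants given a strand-ambiguous
#'   (A/T or C/G) allele pair, to exercise the ambiguity filter.
#' @param flip_coding_rate fraction of population-2 summary rows (and of
#'   VCF records) emitted with swapped allele coding, to exercise
#'   harmonization and dosage re-orientation.
#' @param seed integer seed fixing the whole generator stream.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 800, n_genes = 30, genome_bp = 4e6,
                       gene_len_range = c(1e4, 5e4),
                       fst = 0.1, maf_range = c(0.05, 0.95),
                       prop_causal = 0.075, prop_causal_intragenic = 1,
                       h2_liability = 0.3, prevalence = 0.2,
                       n_discovery_pop1 = 20000, n_discovery_pop2 = 20000,
                       n_target = 2000,
                       ld_block_size = 8, ld_rho = 0.7,
                       n_families = 0, family_size = 2, family_var = 0.1,
                       assoc_method = c("score", "logistic"),
                       ambiguous_rate = 0.10, flip_coding_rate = 0.30,
                       seed = 1) {
  assoc_method <- match.arg(assoc_method)
  cfg <- as.list(environment())
  stopifnot(
    n_variants >= 2, n_genes >= 1, genome_bp > max(gene_len_range),
    fst >= 0, fst < 1,
    maf_range[1] > 0, maf_range[2] < 1, maf_range[1] <= maf_range[2],
    prop_causal >= 0, prop_causal <= 1,
    prop_causal_intragenic >= 0, prop_causal_intragenic <= 1,
    h2_liability >= 0, h2_liability < 1,
    prevalence > 0, prevalence < 1,
    n_discovery_pop1 >= 2, n_discovery_pop2 >= 2, n_target >= 2,
    ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
    n_families >= 0, family_size >= 1, family_var >= 0,
    h2_liability + family_var < 1,
    ambiguous_rate >= 0, ambiguous_rate <= 1,
    flip_coding_rate >= 0, flip_coding_rate <= 1
  )
  structure(cfg, class = "sim_config")
}

#' Balding-Nichols allele frequencies for two diverged populations
#'
#' Ancestral frequencies are uniform on `maf_range`; each population's
#' frequency is drawn independently from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`. `fst = 0` short-circuits to an exact copy of the
#' ancestral frequencies.
#'
#' @param m number of variants.
#' @param fst divergence parameter in \[0, 1).
#' @param maf_range ancestral frequency range.
#' @return list with `anc`, `pop1`, `pop2` frequency vectors.
#' @export
simulate_freqs <- function(m, fst = 0.1, maf_range = c(0.05, 0.95)) {
  p <- stats::runif(m, maf_range[1], maf_range[2])
  if (fst == 0) return(list(anc = p, pop1 = p, pop2 = p))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  list(anc = p,
       pop1 = stats::rbeta(m, a, b),
       pop2 = stats::rbeta(m, a, b))
}

draw_haplotypes <- function(p, n, ld_block_size, ld_rho) {
  m <- length(p)
  thr <- stats::qnorm(p)
  if (ld_block_size <= 1 || ld_rho == 0) {
    z <- matrix(stats::rnorm(n * m), n, m)
  } else {
    block <- rep(seq_len(ceiling(m / ld_block_size)),
                 each = ld_block_size, length.out = m)
    s <- matrix(stats::rnorm(n * max(block)), n, max(block))
    z <- sqrt(ld_rho) * s[, block, drop = FALSE] +
      sqrt(1 - ld_rho) * matrix(stats::rnorm(n * m), n, m)
  }
  # threshold the latent Gaussian at each variant's frequency: the allele
  # indicator is Bernoulli(p_j) marginally, correlated within a block
  z < matrix(thr, n, m, byrow = TRUE)
}

#' Simulate diploid dosages with block LD
#'
#' Each sample's genotype is the sum of two haplotypes. Within an LD block
#' the haplotype alleles come from a Gaussian copula with latent
#' equicorrelation `ld_rho`, thresholded at each variant's frequency so
#' marginal allele frequencies are preserved; blocks are independent.
#'
#' @param p per-variant allele frequencies (frequency of the counted
#'   allele).
#' @param n number of samples.
#' @param ld_block_size,ld_rho block structure (see [sim_config()]).
#' @return `n` x `length(p)` integer dosage matrix with entries 0/1/2.
#' @export
simulate_genotypes <- function(p, n, ld_block_size = 1, ld_rho = 0) {
  h1 <- draw_haplotypes(p, n, ld_block_size, ld_rho)
  h2 <- draw_haplotypes(p, n, ld_block_size, ld_rho)
  g <- h1 + h2
  storage.mode(g) <- "double"
  g
}

#' Assign a gene-structured causal architecture
#'
#' Selects `round(prop_causal * m)` causal variants, placing
#' `prop_causal_intragenic` of them inside gene bodies and the remainder
#' outside, and draws their effects on *standardized* genotypes from
#' `Normal(0, h2_liability / m_causal)`, so the expected liability variance
#' explained sums to `h2_liability`. The same effect vector is used for
#' every population — the shared-causal-variant premise of the framework.
#'
#' @param variants table with `pos` (and `chrom`) columns.
#' @param genes gene-model table (`chrom`, `start`, `end`).
#' @param config a [sim_config()].
#' @return numeric effect vector (one per variant, zero for non-causal).
#' @export
assign_architecture <- function(variants, genes, config) {
  variants <- as.data.table(variants)
  genes <- as.data.table(genes)
  m <- nrow(variants)
  m_causal <- round(config$prop_causal * m)
  if (m_causal == 0) return(numeric(m))
  inside <- vapply(seq_len(m), function(i) {
    any(genes$chrom == variants$chrom[i] &
          genes$start <= variants$pos[i] & genes$end >= variants$pos[i])
  }, logical(1))
  n_intra <- round(m_causal * config$prop_causal_intragenic)
  n_inter <- m_causal - n_intra
  if (n_intra > sum(inside))
    stopf("cannot place %d intragenic causal variants: only %d intragenic positions",
          n_intra, sum(inside))
  if (n_inter > sum(!inside))
    stopf("cannot place %d intergenic causal variants: only %d intergenic positions",
          n_inter, sum(!inside))
  idx <- c(if (n_intra > 0) sample(which(inside), n_intra),
           if (n_inter > 0) sample(which(!inside), n_inter))
  effects <- numeric(m)
  effects[idx] <- stats::rnorm(m_causal, 0, sqrt(config$h2_liability / m_causal))
  effects
}

#' Liability-threshold case/control phenotypes
#'
#' Liability is `l_i = sum_j beta_j g~_ij + a_f(i) + e_i`, where `g~` is
#' the genotype standardized by the population allele frequency
#' (`(g - 2p)/sqrt(2p(1-p))`), `a_f` is an optional family-shared Normal
#' component, and `e_i ~ Normal(0, 1 - h2 - family_var)`. A sample is a
#' case when its liability exceeds the threshold `qnorm(1 - K)`.
#'
#' @param g dosage matrix (samples x variants).
#' @param p population allele frequencies used for standardization.
#' @param effects per-variant effects on standardized genotypes.
#' @param config a [sim_config()]; uses `h2_liability`, `prevalence`,
#'   `n_families`, `family_size`, `family_var`.
#' @param sample_prefix prefix for generated sample ids.
#' @param cohort cohort label stored in the table.
#' @param with_families apply the config's sibship structure (used for the
#'   target cohort; discovery cohorts are always unrelated).
#' @return `data.table`: `sample_id`, `case` (0/1), `sex` (0/1), `cohort`,
#'   `family_id`, `liability` (ground truth; drop before writing).
#' @export
simulate_phenotypes <- function(g, p, effects, config,
                                sample_prefix = "S", cohort = "target",
                                with_families = TRUE) {
  n <- nrow(g)
  sdg <- sqrt(2 * p * (1 - p))
  gen <- as.numeric(g %*% (effects / sdg)) - sum(2 * p * effects / sdg)
  n_fam <- if (with_families) config$n_families else 0L
  fam_n <- n_fam * config$family_size
  if (fam_n > n) stopf("family structure needs %d samples but cohort has %d", fam_n, n)
  family_id <- sprintf("%s_F%05d", sample_prefix,
                       c(if (fam_n > 0) rep(seq_len(n_fam),
                                            each = config$family_size),
                         seq_len(n - fam_n) + n_fam))
  fam_var <- if (n_fam > 0) config$family_var else 0
  a <- stats::rnorm(length(unique(family_id)), 0, sqrt(fam_var))
  names(a) <- unique(family_id)
  e_var <- 1 - config$h2_liability - fam_var
  liab <- gen + a[family_id] + stats::rnorm(n, 0, sqrt(e_var))
  thr <- stats::qnorm(1 - config$prevalence)
  data.table(
    sample_id = sprintf("%s%05d", sample_prefix, seq_len(n)),
    case = as.integer(liab > thr),
    sex = stats::rbinom(n, 1, 0.5),
    cohort = cohort,
    family_id = family_id,
    liability = as.numeric(liab)
  )
}

#' Per-variant discovery association summary statistics
#'
#' Runs a single-variant association of case status on dosage for every
#' variant and emits a standard summary-statistics table. Two engines:
#' `"logistic"` (default) fits per-variant logistic regressions and reports
#' Wald beta/se/p; `"score"` is a vectorized one-step score test
#' (beta = U/V, se = V^{-1/2}), asymptotically equivalent under weak
#' effects and fast enough for hundreds of thousands of variants.
#' Monomorphic variants are excluded and counted.
#'
#' @param g dosage matrix (samples x variants).
#' @param case 0/1 case-status vector.
#' @param variants table with `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (effect allele = the allele `g`
#'   counts).
#' @param method `"logistic"` or `"score"`.
#' @return summary-statistics `data.table` in the package's standard
#'   layout (beta, se, pvalue, n, eaf, info = 1), with a report counting
#'   monomorphic exclusions.
#' @export
generate_discovery_sumstats <- function(g, case, variants,
                                        method = c("logistic", "score")) {
  method <- match.arg(method)
  variants <- as.data.table(variants)
  if (length(unique(case)) < 2) stopf("need at least one case and one control")
  n <- nrow(g)
  eaf <- colMeans(g) / 2
  mono <- eaf == 0 | eaf == 1
  keep <- which(!mono)
  if (method == "score") {
    mu0 <- mean(case)
    r <- case - mu0
    u <- as.numeric(crossprod(g[, keep, drop = FALSE], r))
    v <- mu0 * (1 - mu0) *
      (colSums(g[, keep, drop = FALSE]^2) - n * (2 * eaf[keep])^2)
    beta <- u / v
    se <- 1 / sqrt(v)
  } else {
    fit <- logistic_newton(g[, keep, drop = FALSE], case)
    beta <- fit$beta
    se <- fit$se
  }
  z <- beta / se
  out <- data.table(
    variant_id = variants$variant_id[keep],
    chrom = as.character(variants$chrom[keep]),
    pos = variants$pos[keep],
    effect_allele = variants$effect_allele[keep],
    other_allele = variants$other_allele[keep],
    beta = beta, se = se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    n = n, eaf = eaf[keep], info = 1
  )
  set_report(out[], list(input = ncol(g), monomorphic = sum(mono),
                         kept = length(keep), method = method))
}

# Newton-Raphson IRLS for many single-covariate logistic regressions at
# once: one (intercept, slope) pair per column of g, all variants updated
# in vectorized matrix steps. Equivalent to looping glm() over variants
# but orders of magnitude faster at GWAS scale.
logistic_newton <- function(g, y, max_iter = 25, tol = 1e-10) {
  n <- nrow(g)
  m <- ncol(g)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- numeric(m)
  se <- rep(NA_real_, m)
  active <- seq_len(m)  # variants still iterating; (quasi-)separated
                        # variants run to the iteration cap, like glm
  for (it in seq_len(max_iter)) {
    ga <- g[, active, drop = FALSE]
    eta <- ga * rep(b[active], each = n) + rep(a[active], each = n)
    mu <- 1 / (1 + exp(-eta))
    r <- y - mu            # y recycles down columns
    w <- mu * (1 - mu)
    u0 <- colSums(r)
    u1 <- colSums(r * ga)
    s0 <- colSums(w)
    wg <- w * ga
    s1 <- colSums(wg)
    s2 <- colSums(wg * ga)
    det <- s0 * s2 - s1^2
    da <- (s2 * u0 - s1 * u1) / det
    db <- (s0 * u1 - s1 * u0) / det
    a[active] <- a[active] + da
    b[active] <- b[active] + db
    se[active] <- sqrt(s0 / det)
    done <- pmax(abs(da), abs(db)) < tol
    active <- active[!done]
    if (length(active) == 0L) break
  }
  list(beta = b, se = se, intercept = a, iterations = it,
       not_converged = active)
}

random_allele_pairs <- function(m, ambiguous_rate) {
  transitions <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  transversions <- list(c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  ambiguous <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  kind <- sample(c("ts", "tv", "amb"), m, replace = TRUE,
                 prob = c(0.9 - ambiguous_rate / 2, 0.1 - ambiguous_rate / 2,
                          ambiguous_rate))
  pairs <- t(vapply(kind, function(k) {
    switch(k, ts = transitions, tv = transversions, amb = ambiguous)[[sample.int(4, 1)]]
  }, character(2)))
  list(a1 = pairs[, 1], a2 = pairs[, 2])
}

#' Generate a complete synthetic two-population study
#'
#' Runs the whole generator under one seed: a toy single-chromosome gene
#' map, variant positions and allele pairs, Balding-Nichols population
#' frequencies, a gene-structured causal architecture shared by both
#' populations, two individual-level discovery cohorts summarized into
#' GWAS tables, and an individual-level target cohort (drawn from
#' population 2) with liability-threshold phenotypes and optional
#' sibships. A `flip_coding_rate` fraction of population-2 summary rows is
#' emitted with swapped allele coding (beta negated, eaf mirrored) so the
#' harmonization step has real work to do; the flips carry no information
#' and are exactly undone by [harmonize_sumstats()].
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: list with `config`, `genes`,
#'   `variants` (positions, alleles, per-population frequencies, true
#'   effects), `sumstats_pop1`, `sumstats_pop2`, `target` (a
#'   [dosage_set()] oriented to the study's effect allele), `pheno`
#'   (including ground-truth liability), and `vcf_flip` (which target
#'   records the VCF writer emits with REF/ALT swapped).
#' @export
make_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  genes <- data.table(
    gene_id = sprintf("G%04d", seq_len(config$n_genes)),
    chrom = "1",
    start = sort(sample.int(config$genome_bp - config$gene_len_range[2],
                            config$n_genes)),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  )
  genes[, end := start + round(stats::runif(.N, config$gene_len_range[1],
                                            config$gene_len_range[2]))]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand"))

  m <- config$n_variants
  pairs <- random_allele_pairs(m, config$ambiguous_rate)
  variants <- data.table(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = "1",
    pos = sort(sample.int(config$genome_bp, m)),
    effect_allele = pairs$a1,
    other_allele = pairs$a2
  )
  fr <- simulate_freqs(m, config$fst, config$maf_range)
  variants[, `:=`(p_anc = fr$anc, p_pop1 = fr$pop1, p_pop2 = fr$pop2)]
  variants[, effect := assign_architecture(.SD, genes, config)]
  variants[, key := variant_key(chrom, pos, effect_allele, other_allele)]

  disc <- function(p, n, prefix) {
    g <- simulate_genotypes(p, n, config$ld_block_size, config$ld_rho)
    ph <- simulate_phenotypes(g, p, variants$effect, config,
                              sample_prefix = prefix, cohort = prefix,
                              with_families = FALSE)
    ss <- generate_discovery_sumstats(g, ph$case, variants,
                                      method = config$assoc_method)
    rm(g)
    ss
  }
  ss1 <- disc(fr$pop1, config$n_discovery_pop1, "D1")
  ss2 <- disc(fr$pop2, config$n_discovery_pop2, "D2")

  # emit a fraction of pop-2 rows under the opposite allele coding
  flip2 <- stats::runif(nrow(ss2)) < config$flip_coding_rate
  ss2[flip2, `:=`(effect_allele = other_allele, other_allele = effect_allele,
                  beta = -beta, eaf = 1 - eaf)]

  gt <- simulate_genotypes(fr$pop2, config$n_target,
                           config$ld_block_size, config$ld_rho)
  pheno <- simulate_phenotypes(gt, fr$pop2, variants$effect, config,
                               sample_prefix = "T", cohort = "target")
  rownames(gt) <- pheno$sample_id
  target <- dosage_set(gt, variants[, .(key, variant_id, chrom, pos,
                                        effect_allele, other_allele,
                                        info = 1)])
  vcf_flip <- stats::runif(m) < config$flip_coding_rate

  structure(list(config = config, genes = genes, variants = variants,
                 sumstats_pop1 = ss1, sumstats_pop2 = ss2,
                 target = target, pheno = pheno, vcf_flip = vcf_flip),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d variants (%d causal), %d genes, ",
                     "discovery n = %d + %d, target n = %d (%.1f%% cases)\n"),
              nrow(x$variants), sum(x$variants$effect != 0), nrow(x$genes),
              x$config$n_discovery_pop1, x$config$n_discovery_pop2,
              nrow(x$pheno), 100 * mean(x$pheno$case)))
  invisible(x)
}

#' Write a synthetic study to pipeline-ready files
#'
#' Emits the exact file dialects the pipeline readers consume: two
#' tab-separated summary-statistics tables, a gene-model table, the target
#' genotypes (VCF 4.2 with a DS dosage field, or the plain matrix
#' dialect), and the phenotype table (without the ground-truth liability).
#' In VCF output a `vcf_flip` fraction of records is written with REF/ALT
#' swapped and dosage `2 - d`, which [load_dosages()] must undo.
#'
#' @param study a [make_study()] result.
#' @param dir output directory (created if needed).
#' @param genotype_format `"vcf"` or `"matrix"`.
#' @return named list of file paths.
#' @export
write_study <- function(study, dir, genotype_format = c("vcf", "matrix")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    sumstats_pop1 = file.path(dir, "sumstats_pop1.tsv"),
    sumstats_pop2 = file.path(dir, "sumstats_pop2.tsv"),
    genes = file.path(dir, "genes.tsv"),
    genotypes = file.path(dir, if (genotype_format == "vcf")
      "target_dosages.vcf" else "target_dosages.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv")
  )
  ss_cols <- c(SNP = "variant_id", CHR = "chrom", BP = "pos", A1 = "effect_allele",
               A2 = "other_allele", BETA = "beta", SE = "se", P = "pvalue",
               N = "n", FRQ = "eaf", INFO = "info")
  for (pop in 1:2) {
    ss <- copy(study[[paste0("sumstats_pop", pop)]])
    setnames(ss, unname(ss_cols), names(ss_cols))
    fwrite(ss, paths[[paste0("sumstats_pop", pop)]], sep = "\t")
  }
  fwrite(study$genes, paths$genes, sep = "\t")
  if (genotype_format == "vcf") {
    write_dosage_vcf(study$target, paths$genotypes, flip = study$vcf_flip)
  } else {
    write_dosage_matrix(study$target, paths$genotypes)
  }
  fwrite(study$pheno[, !"liability"], paths$phenotypes, sep = "\t")
  paths
}

#' Write a dosage set as VCF 4.2 with a DS field
#'
#' @param ds a [dosage_set()].
#' @param path output `.vcf` path (plain text).
#' @param flip logical per-variant vector; flipped records are written
#'   with REF = effect allele, ALT = other allele and dosage `2 - d`
#'   (the VCF DS convention counts ALT).
#' @export
write_dosage_vcf <- function(ds, path, flip = NULL) {
  v <- ds$variants
  m <- nrow(v)
  if (is.null(flip)) flip <- rep(FALSE, m)
  stopifnot(length(flip) == m)
  d <- t(ds$dosages)  # variants x samples
  d[flip, ] <- 2 - d[flip, , drop = FALSE]
  ref <- fifelse(flip, v$effect_allele, v$other_allele)
  alt <- fifelse(flip, v$other_allele, v$effect_allele)
  body <- data.table(
    CHROM = v$chrom, POS = as.integer(v$pos), ID = v$variant_id,
    REF = ref, ALT = alt, QUAL = ".", FILTER = "PASS",
    INFO = fifelse(is.na(v$info), ".", sprintf("R2=%.4g", v$info)),
    FORMAT = "DS"
  )
  dsch <- matrix(fifelse(is.na(d), ".", sprintf("%.4g", d)), nrow = m)
  body <- cbind(body, as.data.table(dsch))
  setnames(body, c(names(body)[1:9], ds$samples))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste0("#", paste(names(body), collapse = "\t"))
  )
  writeLines(header, path)
  fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Write a dosage set in the plain matrix dialect
#'
#' @param ds a [dosage_set()].
#' @param path output `.tsv` path.
#' @export
write_dosage_matrix <- function(ds, path) {
  v <- ds$variants
  out <- data.table(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                    counted_allele = v$effect_allele,
                    other_allele = v$other_allele, info = v$info)
  out <- cbind(out, as.data.table(t(ds$dosages)))
  setnames(out, c(names(out)[1:6], ds$samples))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Concordance rate of two null GWAS
#'
#' Simulates two independent discovery GWAS with *no* causal variants and
#' unlinked genotypes, runs the score-test engine, and measures the
#' fraction of variants that would be called concordant (p below `alpha`
#' in both studies with matching effect direction). Under the null this
#' fraction has the analytic value `alpha^2 / 2`: the two p-value events
#' are independent and, conditional on both, the sign agreement is a fair
#' coin. Work proceeds in variant chunks so memory stays flat at large m.
#'
#' @param m number of variants.
#' @param n samples per discovery cohort.
#' @param alpha per-study significance threshold.
#' @param prevalence case fraction of the simulated cohorts.
#' @param fst divergence between the two cohorts' allele frequencies.
#' @param chunk variants per chunk.
#' @return list: `m`, `n_concordant`, `fraction`, `expected` (=
#'   `alpha^2/2`).
#' @export
null_concordance <- function(m = 2e5, n = 1000, alpha = 0.05,
                             prevalence = 0.2, fst = 0.1, chunk = 2e4) {
  total <- 0L
  conc <- 0L
  done <- 0L
  while (done < m) {
    cm <- min(chunk, m - done)
    fr <- simulate_freqs(cm, fst)
    stat <- function(p) {
      g <- matrix(stats::rbinom(n * cm, 2, rep(p, each = n)), n, cm)
      y <- stats::rbinom(n, 1, prevalence)
      mu0 <- mean(y)
      u <- as.numeric(crossprod(g, y - mu0))
      v <- mu0 * (1 - mu0) * (colSums(g^2) - n * colMeans(g)^2)
      ok <- v > 0
      z <- u[ok] / sqrt(v[ok])
      list(p = 2 * stats::pnorm(-abs(z)), s = sign(u[ok]), ok = ok)
    }
    s1 <- stat(fr$pop1)
    s2 <- stat(fr$pop2)
    # align the two studies on jointly polymorphic variants
    both <- s1$ok & s2$ok
    i1 <- both[s1$ok]
    i2 <- both[s2$ok]
    p1 <- s1$p[i1]; sg1 <- s1$s[i1]
    p2 <- s2$p[i2]; sg2 <- s2$s[i2]
    total <- total + sum(both)
    conc <- conc + sum(p1 < alpha & p2 < alpha & sg1 == sg2 & sg1 != 0)
    done <- done + cm
  }
  list(m = total, n_concordant = conc, fraction = conc / total,
       expected = alpha^2 / 2)
}
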