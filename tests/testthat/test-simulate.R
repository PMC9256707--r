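test_that("Balding-Nichols frequencies have the stated moments", {
  set.seed(71)
  m <- 40000
  fr <- simulate_freqs(m, fst = 0.1, maf_range = c(0.2, 0.2001))
  # at an essentially fixed ancestral frequency p the Beta draw has mean p
  # and variance F p (1 - p)
  expect_equal(mean(fr$pop1), 0.2, tolerance = 0.01)
  expect_lt(abs(var(fr$pop1) - 0.1 * 0.2 * 0.8), 0.001)
  expect_lt(abs(var(fr$pop2) - 0.1 * 0.2 * 0.8), 0.001)
  # fst = 0 short-circuits to an exact copy
  fr0 <- simulate_freqs(100, fst = 0)
  expect_identical(fr0$pop1, fr0$anc)
  expect_identical(fr0$pop2, fr0$anc)
})

test_that("genotypes respect marginal frequencies, HWE and block LD", {
  set.seed(72)
  p <- rep(c(0.2, 0.5, 0.8), 4)
  g0 <- simulate_genotypes(p, 4000, ld_block_size = 1, ld_rho = 0)
  expect_true(all(g0 %in% 0:2))
  expect_equal(colMeans(g0) / 2, p, tolerance = 0.03)
  # HWE goodness of fit at each variant (chi-square oracle from stats)
  pvals <- sapply(seq_along(p), function(j) {
    obs <- tabulate(g0[, j] + 1, 3)
    exp_p <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    suppressWarnings(chisq.test(obs, p = exp_p)$p.value)
  })
  expect_gt(min(pvals), 1e-4)
  # independent variants: near-zero dosage correlation
  expect_lt(max(abs(cor(g0)[upper.tri(diag(12))])), 0.06)

  g1 <- simulate_genotypes(rep(0.4, 12), 4000, ld_block_size = 6, ld_rho = 0.8)
  cc <- cor(g1)
  within <- cc[1:6, 1:6][upper.tri(diag(6))]
  across <- cc[1:6, 7:12]
  expect_gt(min(within), 0.4)
  expect_lt(max(abs(across)), 0.08)
})

test_that("causal architecture obeys placement and variance bookkeeping", {
  set.seed(73)
  cfg <- sim_config(n_variants = 500, n_genes = 20, genome_bp = 2e6,
                    prop_causal = 0.2, prop_causal_intragenic = 1,
                    h2_liability = 0.4, seed = 73)
  genes <- data.table(gene_id = sprintf("g%02d", 1:20), chrom = "1",
                      start = seq(1e4, 1.9e6, length.out = 20))
  genes[, `:=`(start = round(start), end = round(start) + 40000L)]
  vars <- data.table(chrom = "1", pos = sort(sample.int(2e6, 500)))
  eff <- assign_architecture(vars, genes, cfg)
  causal <- which(eff != 0)
  expect_equal(length(causal), 100L)
  inside <- sapply(causal, function(i) any(genes$start <= vars$pos[i] &
                                             genes$end >= vars$pos[i]))
  expect_true(all(inside))  # prop_causal_intragenic = 1
  # expected squared-effect total is h2 (chi-square concentration at m = 100)
  expect_equal(sum(eff^2), 0.4, tolerance = 0.25)
  # null generator
  cfg0 <- sim_config(prop_causal = 0, seed = 1)
  expect_equal(assign_architecture(vars, genes, cfg0), rep(0, 500))
  # infeasible placement errors
  tiny <- data.table(gene_id = "g", chrom = "1", start = 1L, end = 2L)
  expect_error(assign_architecture(vars, tiny, cfg), "cannot place")
})

test_that("liability-threshold phenotypes hit the target prevalence", {
  set.seed(74)
  cfg <- sim_config(n_variants = 200, prevalence = 0.2, h2_liability = 0.3,
                    prop_causal = 0.1, seed = 74)
  p <- runif(200, 0.1, 0.9)
  g <- simulate_genotypes(p, 5000)
  eff <- numeric(200); eff[sample(200, 20)] <- rnorm(20, 0, sqrt(0.3 / 20))
  ph <- simulate_phenotypes(g, p, eff, cfg, with_families = FALSE)
  # binomial 99.9% interval around K = 0.2 at n = 5000
  expect_lt(abs(mean(ph$case) - 0.2), 3.3 * sqrt(0.2 * 0.8 / 5000))
  # higher genetic score -> higher case rate
  gs <- as.numeric(g %*% (eff / sqrt(2 * p * (1 - p))))
  top <- ph$case[gs > quantile(gs, 0.8)]
  bottom <- ph$case[gs < quantile(gs, 0.2)]
  expect_gt(mean(top), mean(bottom))
  # h2 = 0: phenotype independent of genotype
  cfg0 <- sim_config(prevalence = 0.2, h2_liability = 0, prop_causal = 0, seed = 74)
  ph0 <- simulate_phenotypes(g, p, numeric(200), cfg0, with_families = FALSE)
  expect_lt(abs(cor(ph0$case, g[, 1])), 0.05)
})

test_that("family structure shares liability within sibships", {
  set.seed(75)
  cfg <- sim_config(n_variants = 50, n_families = 200, family_size = 2,
                    family_var = 0.3, h2_liability = 0.2, prop_causal = 0,
                    seed = 75)
  p <- runif(50, 0.1, 0.9)
  g <- simulate_genotypes(p, 500)
  ph <- simulate_phenotypes(g, p, numeric(50), cfg)
  expect_equal(length(unique(ph$family_id)), 200 + 100)
  sib <- ph[1:400]
  l1 <- sib[seq(1, 400, 2), liability]
  l2 <- sib[seq(2, 400, 2), liability]
  expect_gt(cor(l1, l2), 0.1)  # shared component ~0.3 of unit variance
})

test_that("discovery sumstats match an independent logistic ML oracle", {
  set.seed(76)
  m <- 50; n <- 500
  p <- runif(m, 0.1, 0.9)
  g <- simulate_genotypes(p, n)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * scale(g[, 1])))
  vars <- toy_variants(seq_len(m) * 100L)
  ss <- generate_discovery_sumstats(g, y, vars, method = "logistic")
  expect_equal(nrow(ss), m)
  for (j in c(1, 7, 23, 50)) {
    o <- logistic_oracle(g[, j], y)
    expect_lt(abs(ss$beta[j] - o$beta), 1e-6)
    expect_lt(abs(ss$se[j] - o$se), 1e-6)
    expect_lt(abs(ss$pvalue[j] - o$p), 1e-5)
  }
  expect_equal(ss$eaf, colMeans(g) / 2)
  # monomorphic variants are excluded with a report
  g2 <- cbind(g, 0)
  vars2 <- toy_variants(c(seq_len(m), m + 1L) * 100L)
  ss2 <- generate_discovery_sumstats(g2, y, vars2)
  expect_equal(nrow(ss2), m)
  expect_equal(filter_report(ss2)$monomorphic, 1L)
})

test_that("score-test engine agrees with the logistic engine at weak effects", {
  set.seed(77)
  m <- 60; n <- 3000
  p <- runif(m, 0.2, 0.8)
  g <- simulate_genotypes(p, n)
  y <- rbinom(n, 1, 0.2)
  vars <- toy_variants(seq_len(m) * 100L)
  sl <- generate_discovery_sumstats(g, y, vars, method = "logistic")
  sc <- generate_discovery_sumstats(g, y, vars, method = "score")
  expect_equal(sc$beta / sl$beta, rep(1, m), tolerance = 0.15)
  expect_gt(cor(qnorm(sc$pvalue / 2), qnorm(sl$pvalue / 2)), 0.99)
})

test_that("null p-values are uniform", {
  set.seed(78)
  m <- 4000; n <- 800
  p <- runif(m, 0.1, 0.9)
  g <- simulate_genotypes(p, n)
  y <- rbinom(n, 1, 0.3)
  ss <- generate_discovery_sumstats(g, y, toy_variants(seq_len(m) * 10L),
                                    method = "score")
  ks <- suppressWarnings(ks.test(ss$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("make_study is seed-deterministic and internally consistent", {
  cfg <- sim_config(n_variants = 150, n_genes = 8, genome_bp = 8e5,
                    n_discovery_pop1 = 500, n_discovery_pop2 = 500,
                    n_target = 200, prop_causal = 0.1, seed = 99)
  s1 <- make_study(cfg)
  s2 <- make_study(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$sumstats_pop2, s2$sumstats_pop2)
  expect_identical(s1$target$dosages, s2$target$dosages)
  expect_identical(s1$pheno, s2$pheno)

  d1 <- write_study(s1, file.path(tempdir(), "det1"))
  d2 <- write_study(s2, file.path(tempdir(), "det2"))
  for (f in names(d1))
    expect_identical(readLines(d1[[f]]), readLines(d2[[f]]))

  s3 <- make_study(sim_config(n_variants = 150, n_genes = 8, genome_bp = 8e5,
                              n_discovery_pop1 = 500, n_discovery_pop2 = 500,
                              n_target = 200, prop_causal = 0.1, seed = 100))
  expect_false(identical(s1$target$dosages, s3$target$dosages))

  # causal placement respects the intragenic proportion
  causal <- s1$variants[effect != 0]
  inside <- sapply(seq_len(nrow(causal)), function(i)
    any(s1$genes$start <= causal$pos[i] & s1$genes$end >= causal$pos[i]))
  expect_true(all(inside))
  expect_error(sim_config(fst = 1.2), "fst")
})

test_that("written studies round-trip through every pipeline reader", {
  cfg <- sim_config(n_variants = 120, n_genes = 6, genome_bp = 6e5,
                    n_discovery_pop1 = 400, n_discovery_pop2 = 400,
                    n_target = 150, prop_causal = 0.1, seed = 101)
  st <- make_study(cfg)
  paths <- write_study(st, file.path(tempdir(), "rt_vcf"))
  ss1 <- read_sumstats(paths$sumstats_pop1)
  ss2 <- read_sumstats(paths$sumstats_pop2)
  expect_equal(nrow(ss1), nrow(st$sumstats_pop1))
  gm <- load_gene_models(paths$genes)
  expect_equal(gm$gene_id, st$genes$gene_id)
  ds <- load_dosages(paths$genotypes, variant_subset = st$target$variants)
  expect_equal(ds$dosages, st$target$dosages, tolerance = 1e-3)
  # matrix dialect carries the same content
  pm <- write_study(st, file.path(tempdir(), "rt_mat"), genotype_format = "matrix")
  dm <- load_dosages(pm$genotypes, variant_subset = st$target$variants)
  expect_equal(dm$dosages, st$target$dosages)
})
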