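test_that("dosage orientation follows the requested effect allele", {
  d <- matrix(c(1.5, 0.5, 2, 0), nrow = 2)
  ds <- toy_dosage_set(d)
  # request variant 2 counted on the OTHER allele: dosages flip to 2 - d
  sub <- copy(ds$variants[, .(key, effect_allele, other_allele)])
  sub[2, `:=`(effect_allele = "G", other_allele = "A")]
  path <- tempfile(fileext = ".vcf")
  write_dosage_vcf(ds, path)
  back <- load_dosages(path, variant_subset = sub)
  expect_equal(unname(back$dosages[, 1]), c(1.5, 0.5))
  expect_equal(unname(back$dosages[, 2]), c(0, 2))
  expect_equal(back$variants$effect_allele, c("A", "G"))
})

test_that("VCF and matrix dialects round-trip identically", {
  set.seed(51)
  d <- matrix(round(runif(60, 0, 2), 3), nrow = 6)
  d[2, 3] <- NA
  ds <- toy_dosage_set(d)
  pv <- tempfile(fileext = ".vcf")
  pm <- tempfile(fileext = ".tsv")
  write_dosage_vcf(ds, pv)
  write_dosage_matrix(ds, pm)
  from_vcf <- load_dosages(pv)
  from_mat <- load_dosages(pm)
  expect_equal(from_vcf$dosages, from_mat$dosages, tolerance = 1e-3)
  expect_equal(from_vcf$variants$key, from_mat$variants$key)
  expect_true(is.na(from_vcf$dosages[2, 3]) && is.na(from_mat$dosages[2, 3]))
  # a VCF record written with swapped REF/ALT reads back re-oriented
  pf <- tempfile(fileext = ".vcf")
  write_dosage_vcf(ds, pf, flip = c(TRUE, rep(FALSE, 9)))
  back <- load_dosages(pf, variant_subset = ds$variants)
  expect_equal(back$dosages[, 1], ds$dosages[, 1], tolerance = 1e-3)
  ghost <- data.table(effect_allele = "A")[, key := "9:9:A:G"]
  expect_error(load_dosages(pv, variant_subset = ghost),
               "none of the requested")
})

test_that("HWE chi-square matches closed forms and flags degenerate input", {
  expect_equal(as.numeric(hwe_test(25, 50, 25)), 1)  # perfect HWE, stat 0
  # counts (50,0,50): expected (25,50,25), statistic = 25+50+25 = n = 100
  p <- hwe_test(50, 0, 50)
  expect_equal(as.numeric(p), pchisq(100, 1, lower.tail = FALSE))
  expect_lt(as.numeric(p), 1e-20)
  mono <- hwe_test(0, 0, 60)
  expect_equal(as.numeric(mono), 1)
  expect_true(attr(mono, "monomorphic"))
  expect_error(hwe_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact test agrees with a resampling oracle of the conditional law", {
  # oracle: pair the fixed pool of alleles at random many times, estimate the
  # conditional heterozygote-count distribution, and sum the probabilities of
  # outcomes no more likely than the observed one
  set.seed(56)
  exact_oracle <- function(nAA, nAa, naa, reps = 4e4) {
    n <- nAA + nAa + naa
    alleles <- rep(c(1L, 0L), c(2 * nAA + nAa, 2 * naa + nAa))
    hets <- replicate(reps, {
      perm <- sample(alleles)
      sum(perm[seq(1, 2 * n, 2)] != perm[seq(2, 2 * n, 2)])
    })
    pr <- table(hets) / reps
    obs <- pr[as.character(nAa)]
    sum(pr[pr <= obs * (1 + 1e-9)])
  }
  for (cnt in list(c(5, 10, 5), c(8, 2, 10), c(12, 6, 2))) {
    expect_equal(as.numeric(hwe_test(cnt[1], cnt[2], cnt[3], method = "exact")),
                 exact_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 0.02)
  }
})

test_that("qc_variants applies each filter exactly as hand-enumerated", {
  set.seed(52)
  n <- 400
  freqs <- c(0.005, 0.3, 0.3, 0.3, 0.5, 0.25, 0.4, 0.35, 0.45, 0.2)
  d <- sapply(freqs, function(p) rbinom(n, 2, p))
  d[, 6] <- rep(c(0, 2), each = n / 2)        # extreme HWE violation
  d[sample(n, 0.2 * n), 4] <- NA              # 20% missing
  ds <- toy_dosage_set(d)
  ds$variants$info <- c(rep(0.9, 2), 0.1, rep(0.9, 7))  # variant 3 low info
  ds <- dosage_set(ds$dosages, ds$variants[, !c("eaf", "missing_rate")])
  out <- qc_variants(ds, maf_min = 0.01, info_min = 0.30,
                     missing_max = 0.05, hwe_p_min = 1e-4)
  r <- filter_report(out)
  expect_equal(r$removed_maf, 1L)       # variant 1, maf ~0.005
  expect_equal(r$removed_info, 1L)      # variant 3
  expect_equal(r$removed_missing, 1L)   # variant 4
  expect_gte(r$removed_hwe, 1L)         # variant 6 at least
  surviving <- ds$variants$key[-c(1, 3, 4, 6)]
  expect_true(all(out$variants$key %in% surviving))
  expect_error(qc_variants(out, maf_min = 0.6), "all variants removed")
})

test_that("compute_prs equals a brute-force weighted-sum oracle", {
  set.seed(53)
  d <- matrix(runif(12, 0, 2), nrow = 4)  # 4 samples x 3 variants
  ds <- toy_dosage_set(d)
  w <- copy(ds$variants)[, `:=`(weight = c(0.5, -0.2, 0.1), source = "ivw_meta")]
  prs <- compute_prs(ds, w)
  oracle <- sapply(1:4, function(i) sum(d[i, ] * w$weight))
  expect_equal(prs$raw_score, oracle)
  expect_equal(attr(prs, "n_variants"), 3L)

  # all-zero weights give all-zero scores; single-variant sanity value
  w0 <- copy(w)[, weight := 0]
  expect_equal(compute_prs(ds, w0)$raw_score, rep(0, 4))
  one <- toy_dosage_set(matrix(2, 1, 1))
  w1 <- copy(one$variants)[, weight := 0.5]
  expect_equal(compute_prs(one, w1)$raw_score, 1.0)
})

test_that("missing-dosage policies follow their formulas", {
  d <- matrix(c(0, 1, 2, NA, 1, 1, 0, 2), nrow = 4)  # NA: sample 4, variant 1
  ds <- toy_dosage_set(d)
  w <- copy(ds$variants)[, weight := c(1, 1)]
  eaf1 <- mean(c(0, 1, 2)) / 2  # observed frequency of variant 1
  mi <- compute_prs(ds, w, missing_policy = "mean_impute")
  expect_equal(mi$raw_score[4], 2 + 2 * eaf1)
  sk <- compute_prs(ds, w, missing_policy = "skip")
  expect_equal(sk$raw_score[4], 2)
  # effect-allele mismatch is a hard error naming the variant
  wbad <- copy(w)[1, effect_allele := "G"]
  expect_error(compute_prs(ds, wbad), ds$variants$key[1], fixed = TRUE)
})

test_that("standardization attains mean 0 / sd 1 in the reference group", {
  prs <- data.table(sample_id = sprintf("S%d", 1:6),
                    raw_score = c(5, 7, 9, 11, 13, 100), label = "PRS")
  z_all <- standardize_prs(prs)
  expect_lt(abs(mean(z_all$standardized_score)), 1e-12)
  expect_lt(abs(sd(z_all$standardized_score) - 1), 1e-12)

  # reference = first 5: hand computation with (n-1) sd
  ref <- sprintf("S%d", 1:5)
  z_ref <- standardize_prs(prs, reference_ids = ref)
  m <- mean(c(5, 7, 9, 11, 13)); s <- sd(c(5, 7, 9, 11, 13))
  expect_equal(z_ref$standardized_score, (prs$raw_score - m) / s)
  expect_lt(abs(mean(z_ref$standardized_score[1:5])), 1e-12)
  expect_false(abs(z_ref$standardized_score[6]) < 3)  # non-reference not 0/1

  expect_error(standardize_prs(data.table(sample_id = c("a", "b"),
                                          raw_score = c(1, 1))), "zero variance")
  # idempotence: standardizing a standardized score changes nothing
  z2 <- standardize_prs(z_all[, .(sample_id, raw_score = standardized_score)])
  expect_equal(z2$standardized_score, z_all$standardized_score)
})

test_that("allele recoding shifts raw scores by a constant, z-scores unchanged", {
  set.seed(54)
  d <- matrix(runif(40, 0, 2), nrow = 8)
  ds <- toy_dosage_set(d)
  w <- copy(ds$variants)[, weight := rnorm(5)]
  base <- standardize_prs(compute_prs(ds, w))

  # recode variant 3: swap alleles, dosage -> 2 - d, weight -> -weight
  d2 <- d
  d2[, 3] <- 2 - d2[, 3]
  v2 <- copy(ds$variants)
  v2[3, `:=`(effect_allele = other_allele, other_allele = effect_allele)]
  ds2 <- dosage_set(d2, v2[, !c("eaf", "missing_rate")])
  w2 <- copy(w)
  w2[3, `:=`(weight = -weight, effect_allele = v2$effect_allele[3],
             other_allele = v2$other_allele[3])]
  rec <- standardize_prs(compute_prs(ds2, w2))
  shift <- compute_prs(ds2, w2)$raw_score - compute_prs(ds, w)$raw_score
  expect_equal(diff(range(shift)), 0, tolerance = 1e-12)
  expect_equal(shift[1], 2 * w2$weight[3], tolerance = 1e-12)
  expect_equal(rec$standardized_score, base$standardized_score, tolerance = 1e-12)
})

test_that("gene + intergenic raw scores sum to the union score", {
  set.seed(55)
  d <- matrix(runif(48, 0, 2), nrow = 6)
  ds <- toy_dosage_set(d)
  w <- copy(ds$variants)[, weight := rnorm(8)]
  split1 <- w[1:3]; split2 <- w[4:8]
  total <- compute_prs(ds, w)$raw_score
  expect_equal(compute_prs(ds, split1)$raw_score +
                 compute_prs(ds, split2)$raw_score, total)
})
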