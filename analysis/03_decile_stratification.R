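#!/usr/bin/env Rscript
# Decile risk stratification of the gene-based score from 02_prs_pipeline.R:
# case rates per decile and odds ratios against the bottom decile, with and
# without covariate adjustment.

suppressMessages({library(geneprs); library(data.table)})

prs <- fread("results/pipeline/scores_PRS_gene.tsv")
pheno <- fread("results/study/phenotypes.tsv")
pheno[, sample_id := as.character(sample_id)]

deciles <- decile_strata(prs)
rates <- decile_case_rates(pheno, deciles)
or_unadj <- decile_or(pheno, deciles, adjust = FALSE)

fwrite(rates, "results/decile_case_rates.tsv", sep = "\t")
fwrite(or_unadj, "results/decile_or_unadjusted.tsv", sep = "\t")

cat("case rate per PRS_gene decile:\n")
print(rates)
cat(sprintf("\nSpearman(decile, case rate) = %.3f\n",
            cor(rates$decile, rates$case_rate, method = "spearman")))
cat(sprintf("top-decile OR vs bottom decile = %.2f (95%% CI %.2f-%.2f)\n",
            or_unadj[decile == 10, or], or_unadj[decile == 10, ci_lower],
            or_unadj[decile == 10, ci_upper]))
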