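#!/usr/bin/env Rscript
# Replicated contrast of the gene-based vs intergenic scores: with every
# causal variant intragenic, PRS_gene should dominate PRS_intergenic in
# association strength in (nearly) every seeded replicate, while the
# intergenic score carries only LD-leaked signal.

suppressMessages({library(geneprs); library(data.table)})

n_rep <- 20
rows <- vector("list", n_rep)
for (s in seq_len(n_rep)) {
  ev <- evaluate_study(make_study(sim_config(seed = s)))
  rows[[s]] <- data.table(
    seed = s,
    n_concordant = ev$counts$concordant,
    n_intragenic = ev$counts$intragenic,
    n_intergenic = ev$counts$intergenic,
    z_gene = if (!is.null(ev$assoc$PRS_gene)) ev$assoc$PRS_gene$z else NA_real_,
    p_gene = if (!is.null(ev$assoc$PRS_gene)) ev$assoc$PRS_gene$p else NA_real_,
    z_intergenic = if (!is.null(ev$assoc$PRS_intergenic))
      ev$assoc$PRS_intergenic$z else 0,
    z_all = if (!is.null(ev$assoc$PRS_all)) ev$assoc$PRS_all$z else NA_real_
  )
}
tab <- rbindlist(rows)
fwrite(tab, "results/signal_recovery.tsv", sep = "\t")
print(tab)
cat(sprintf("\nPRS_gene z exceeded PRS_intergenic z in %d / %d replicates\n",
            sum(tab$z_gene > tab$z_intergenic, na.rm = TRUE), n_rep))
cat(sprintf("PRS_gene reached p < 0.05 in %d / %d replicates\n",
            sum(tab$p_gene < 0.05, na.rm = TRUE), n_rep))
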