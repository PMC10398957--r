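#!/usr/bin/env Rscript
# Re-run the identical trajectory screen on a second cell type: a
# microglia-like population whose planted program is predominantly
# upregulated, as amyloid-responsive microglia are. The MA table should be
# up-dominated, the mirror image of the astrocyte screen.
library(astrotraj)

cfg <- simulation_config_microglia(n_nuclei = 1400L, seed = 1L)
ds <- simulate_dataset(cfg)
counts <- filter_genes_min_nuclei(ds$counts, 10)  # sparser population, lower cut
expr <- normalize_log(counts)

pt <- compute_pseudotime(knn_smooth(expr, k = 30, n_pcs = 30),
                         homeo_genes = c("NRXN1", "NRG3", "GPC5", "ERBB4", "NFIA"))
expr_s <- knn_smooth(expr, k = 30, n_pcs = 10)
rec <- gene_trajectory_regression(expr_s[match(pt$nucleus_id, rownames(expr_s)), ],
                                  rank_uniform(pt$t))
ma <- ma_table(rec)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(ma, "results/tables/ma_table_microglia.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("microglia-like screen: %d up vs %d down in the MA table (up-dominant: %s)\n",
            sum(ma$status == "up"), sum(ma$status == "down"),
            sum(ma$status == "up") > sum(ma$status == "down")))
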