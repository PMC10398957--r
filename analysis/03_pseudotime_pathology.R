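#!/usr/bin/env Rscript
# Diffusion pseudotime over the joint astrocyte populations with the
# homeostatic root rule, then the donor-level pathology mixed model
# (t ~ amyloid + tau + TREM2 + APOE + age + (1 | sample)) per population.
library(astrotraj)

counts <- read_count_matrix("results/data")
counts <- filter_genes_min_nuclei(counts, 30)
expr <- normalize_log(counts)
labels <- read.delim("results/tables/nucleus_labels.tsv")
meta <- read_nucleus_meta("results/data")

astro_ids <- labels$nucleus_id[labels$label %in% c("protoplasmic", "fibrous")]
proto_ids <- labels$nucleus_id[labels$label == "protoplasmic"]
expr_astro <- knn_smooth(expr[astro_ids, ], k = 30, n_pcs = 30)
pt <- compute_pseudotime(expr_astro,
                         homeo_genes = c("NRXN1", "NRG3", "GPC5", "ERBB4", "NFIA"),
                         candidates = proto_ids)
write.table(pt, "results/tables/pseudotime.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("root nucleus: %s; %d astrocyte nuclei ordered on [0,1]\n",
            attr(pt, "root"), nrow(pt)))

for (pop in c("protoplasmic", "fibrous")) {
  ids <- labels$nucleus_id[labels$label == pop]
  rows <- pt$nucleus_id %in% ids
  m <- meta[match(pt$nucleus_id[rows], meta$nucleus_id), ]
  fit <- fit_random_intercept_lmm(rank_uniform(pt$t)[rows], m)
  amy <- fit$coefficients[fit$coefficients$term == "amyloid", ]
  cat(sprintf("%s: amyloid coefficient %.4f (p = %.3f), %d nuclei, %d donors\n",
              pop, amy$estimate, amy$p.value, fit$n, fit$n_groups))
  write.table(cbind(population = pop, fit$coefficients),
              sprintf("results/tables/lmm_%s.tsv", pop), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
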