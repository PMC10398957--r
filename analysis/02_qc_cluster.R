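#!/usr/bin/env Rscript
# QC filters, normalization, Leiden resolution sweep, Wilcoxon markers,
# marker-panel annotation with doublet flagging, and the cluster-flow table.
library(astrotraj)

counts <- read_count_matrix("results/data")
counts <- filter_genes_min_nuclei(counts, 30)
counts <- filter_nuclei_gene_count(counts, 2500)
expr <- normalize_log(counts)
cat(sprintf("after QC: %d nuclei x %d genes\n", nrow(expr), ncol(expr)))

graph <- build_knn_graph(expr, n_pcs = 30, k = 15)
assignments <- cluster_sweep(graph, resolutions = c(0.1, 0.25, 0.5, 1), seed = 1)
n_cl <- vapply(assignments, function(x) length(unique(x)), integer(1))
cat("clusters per resolution:", paste(names(n_cl), n_cl, sep = "=",
                                      collapse = ", "), "\n")

res_use <- names(n_cl)[which(n_cl >= 4)[1]]
markers <- wilcoxon_markers(expr, assignments[[res_use]])
ann <- annotate_clusters(markers, marker_panels())
print(ann[, c("cluster", "label")])

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(cbind(nucleus_id = rownames(assignments), assignments),
            "results/tables/cluster_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(markers, "results/tables/marker_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann, "results/tables/cluster_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flow <- cluster_flow_table(assignments)
write.table(flow, "results/tables/cluster_flow.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
lab <- ann$label[match(assignments[[res_use]], ann$cluster)]
write.table(data.frame(nucleus_id = rownames(assignments), label = lab,
                       resolution = res_use),
            "results/tables/nucleus_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("labeled populations:", paste(names(table(lab)), table(lab), sep = "=",
                                  collapse = ", "), "\n")
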