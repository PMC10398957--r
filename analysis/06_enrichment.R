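#!/usr/bin/env Rscript
# Cross-signature statistics: (i) the published-count mouse-model overlap
# and transcription-factor enrichment, recomputed from the printed tables;
# (ii) the same operations run end-to-end on the synthetic signature with
# synthetic homology/TF/gene-set fixtures.
library(astrotraj)

## published counts: 224 mapped 5xFAD genes vs 196 human signature genes,
## 29 shared, in a 17,012-gene transcriptome
fis <- fisher_exact_2x2(c(29, 195, 167, 16621))
cat(sprintf("5xFAD overlap (printed counts): p = %.3g, OR = %.2f\n",
            fis$p.value, fis$odds.ratio))
## published counts: 1129 TFs among 17,012 genes; 17 TFs among 144 down
chi <- chi_squared_2x2(c(17, 127, 1112, 15756))
cat(sprintf("TF enrichment among downregulated (printed counts): chi2 = %.2f, p = %.4f\n",
            chi$statistic, chi$p.value))

## synthetic signature vs synthetic fixtures
sig_tab <- read.delim("results/tables/signature.tsv")
own <- list(up = sig_tab$gene[sig_tab$direction == "up"],
            down = sig_tab$gene[sig_tab$direction == "down"])
rec <- read.delim("results/tables/screen_records.tsv")
universe <- rec$gene

ext <- function(f) system.file("extdata", f, package = "astrotraj")
hom <- read_homology_map(ext("homology_synthetic.tsv"))
mouse <- read.delim(ext("mouse_signature_synthetic.tsv"))
mapped <- map_homologs(mouse$gene, hom, universe, directions = mouse$direction)
cat(sprintf("mouse signature: %d genes, %d mapped into the universe (%d unmapped)\n",
            nrow(mouse), length(mapped$mapped), mapped$n_unmapped))
ov <- overlap_fisher(mapped$mapped, unlist(own), universe)
cat(sprintf("synthetic model overlap: a=%d, p = %.3g, OR = %.2f\n",
            ov$table[["a"]], ov$p.value, ov$odds.ratio))

tfs <- readLines(ext("tf_list_synthetic.txt"))
tf <- tf_enrichment(own, tfs, universe)
print(tf)

sets <- read_gmt(ext("gene_sets_synthetic.gmt"))
ora <- ora_gene_sets(unlist(own), sets, universe)
print(ora)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(tf, "results/tables/tf_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ora, "results/tables/ora.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
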