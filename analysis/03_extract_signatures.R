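#!/usr/bin/env Rscript
# Component-based unsupervised feature extraction over the candidate
# genes: retain components to 60% cumulative variance, then select genes
# whose absolute correlation with a retained component exceeds that
# component's 95th percentile with p < 0.001.
library(sigsim)

out <- "results"
expr_df <- read.delim(file.path(out, "normalized_expression.tsv"),
                      check.names = FALSE)
expr <- as.matrix(expr_df[, -1])
rownames(expr) <- expr_df$gene_id
fc <- read.delim(file.path(out, "fold_changes.tsv"))
cand <- readLines(file.path(out, "candidate_genes.txt"))

pca <- run_pca(expr, cand)
m <- select_components(pca, 0.6)
cat(sprintf("retained %d of %d components (cumulative variance %.3f)\n",
            m, length(pca$variance_fraction),
            sum(pca$variance_fraction[1:m])))

corr <- correlate_genes(expr, pca, m)
sig <- extract_signatures(corr, fc)
cat(sprintf("signatures: %d (%d up, %d down)\n", nrow(sig),
            sum(sig$direction == "up"), sum(sig$direction == "down")))

write.table(as.data.frame(sig), file.path(out, "signatures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
scree <- data.frame(component = seq_along(pca$variance_fraction),
                    variance_fraction = pca$variance_fraction,
                    cumulative = cumsum(pca$variance_fraction))
write.table(scree, file.path(out, "scree.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
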