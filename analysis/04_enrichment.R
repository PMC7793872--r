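#!/usr/bin/env Rscript
# Right-tailed Fisher (hypergeometric) enrichment of the signature genes
# against the gene-set collection, scored as -log10(p) with the 1.3
# significance threshold (p <= 0.05). The background is the assayable
# transcriptome (genes surviving the annotation filter).
library(sigsim)

out <- "results"
sig <- read.delim(file.path(out, "signatures.tsv"))
expr_df <- read.delim(file.path(out, "normalized_expression.tsv"),
                      check.names = FALSE)
sets <- read_gmt("results/data/gene_sets.gmt")

res <- fisher_enrichment(sig$gene_id, sets, universe = expr_df$gene_id)
cat(sprintf("tested %d sets; %d significant at score >= 1.3\n",
            sum(res$tested), sum(res$significant)))
top <- res[res$tested, ][1:5, c("set", "k", "K", "score")]
top$overlap_pct <- round(overlap_fraction(top$k, top$K))
print(top, row.names = FALSE)

write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
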