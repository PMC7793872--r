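#!/usr/bin/env Rscript
# Simulate the three-cohort study data: tumors 150/100/120, normals 30/0/20
# (the middle cohort has no normals), 3,000 genes with 100 up- and 100
# downregulated genes planted at |log2FC| = 2, plus a synthetic gene-set
# collection and interaction edge list carrying the planted signal.
library(sigsim)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- generate_cohorts(synth_config(seed = seed))
print(sim)
write_cohorts(sim, out)

planted <- c(sim$truth$planted_up, sim$truth$planted_down)
sets <- simulate_gene_sets(rownames(sim$counts), planted,
                           n_signal = 8, n_background = 40, seed = seed)
write_gmt(sets, file.path(out, "gene_sets.gmt"))

graph <- simulate_interactions(rownames(sim$counts), planted,
                               n_hubs = 5, hub_degree = 25,
                               n_background = 800, seed = seed)
write_interactions(graph, file.path(out, "interactions.tsv"))

cat(sprintf("wrote %s: %d genes x %d samples, %d gene sets, %d edges\n",
            out, nrow(sim$counts), ncol(sim$counts), length(sets),
            nrow(graph)))
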