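#!/usr/bin/env Rscript
# Grow capped interaction networks (35 molecules) around the signature
# genes, rank them by the hypergeometric score of their focus-gene
# overlap, and call activity for the hub regulators by sign consistency.
library(sigsim)

out <- "results"
sig <- read.delim(file.path(out, "signatures.tsv"))
fc <- read.delim(file.path(out, "fold_changes.tsv"))
graph <- read_interactions("results/data/interactions.tsv")

nets <- build_networks(graph, sig$gene_id, max_size = 35)
cat(sprintf("built %d networks; top score %.2f (focus %d of %d molecules)\n",
            nrow(nets), nets$score[1], nets$focus_count[1],
            nets$n_molecules[1]))
write.table(nets, file.path(out, "networks.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

hubs <- grep("^HUB_", unique(graph$source), value = TRUE)
calls <- lapply(hubs, function(h) {
  act <- tryCatch(regulator_activity(graph, fc, h), error = function(e) NULL)
  if (is.null(act)) return(NULL)
  data.frame(regulator = h, z = act$z, call = act$call,
             n_targets = act$n_targets)
})
calls <- do.call(rbind, calls)
print(calls, row.names = FALSE)
write.table(calls, file.path(out, "regulator_activity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
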