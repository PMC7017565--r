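#!/usr/bin/env Rscript
# Ortholog assignment by reciprocal-best local protein search (>95 % query
# coverage, E-value < 1e-100) and a global identity/divergence table for the
# assigned pairs, written to results/orthologs.tsv.
suppressMessages(library(tsitescreen))

bundle <- read_bundle("results/bundle")
omap <- assign_orthologs(bundle$proteome, bundle$refs)
rows <- lapply(names(omap)[!is.na(omap)], function(q)
  global_identity(as.character(bundle$proteome)[q],
                  as.character(bundle$refs)[omap[q]]))
tab <- do.call(rbind, rows)
write.table(tab, "results/orthologs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("assigned:", sum(!is.na(omap)), "of", length(omap), "queries\n")
cat(sprintf("identity: median %.1f%%, range %.1f-%.1f%%\n",
            median(tab$percent_identity), min(tab$percent_identity),
            max(tab$percent_identity)))
cat("table written to results/orthologs.tsv\n")
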