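#!/usr/bin/env Rscript
# Call candidate A-to-I (A>G) RNA-editing sites by comparing each gene's
# genome-encoded spliced transcript with the transcript evidence, and check
# the calls against the generator's truth table.
suppressMessages(library(tsitescreen))

bundle <- read_bundle("results/bundle")
calls <- NULL
for (tid in grep("\\.t1$", names(bundle$models), value = TRUE)) {
  m <- bundle$models[[tid]]
  calls <- rbind(calls, call_editing(m, bundle$contigs,
                                     as.character(bundle$transcripts[[tid]])))
}
write.table(calls, "results/editing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- bundle$truth$edits   # list of row records (from truth.json)
truth_n <- length(truth)
cand <- calls[calls$status == "candidate_edit", ]
cat("candidate A>G edits called:", nrow(cand), "\n")
cat("planted in truth table:    ", truth_n, "\n")
if (truth_n > 0) {
  tk <- vapply(truth, function(r) paste(r$gene, r$genomic_pos), "")
  ck <- paste(cand$gene, cand$genomic_pos)
  cat(sprintf("sensitivity: %.1f%%  specificity: %.1f%%\n",
              100 * mean(tk %in% ck), 100 * mean(ck %in% tk)))
}
cat("non-A>G mismatches logged:", sum(calls$status != "candidate_edit"), "\n")
cat("report written to results/editing.tsv\n")
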