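#!/usr/bin/env Rscript
# Project the resistance-mutation catalog onto the synthetic proteome and
# call the state of every site; then show the shipped nine-mutation catalog
# (DSC1 D1924N; ryanodine-receptor E1338D/Q4594L/I4790M/G4946E; RDL A302S;
# tick phenolamine-receptor T8P/L22S/I61F) under self-projection, which must
# be uniformly susceptible.
suppressMessages(library(tsitescreen))

bundle <- read_bundle("results/bundle")
calls <- screen_catalog(bundle$catalog, bundle$refs, bundle$proteome,
                        as.list(setNames(bundle$catalog$target_gene,
                                         bundle$catalog$target_gene)))
write.table(calls, "results/resistance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("screen of", nrow(calls), "cataloged sites:\n")
print(table(calls$state))
planted <- vapply(bundle$truth$genes, function(g)
  isTRUE(g$resistance$planted), TRUE)
cat("planted resistant alleles:", sum(planted),
    "| called resistant:", sum(calls$state == "resistant"), "\n\n")

cat9 <- read_catalog()
set.seed(1)
aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
lens <- c(Dmel_DSC1 = 2100L, Pxyl_Ryr = 5100L, Dmel_RDL = 600L,
          Rmic_TAR1 = 450L, Rmic_OctB2R = 480L)
refs <- character()
for (id in unique(cat9$reference_seq_id)) {
  v <- sample(aa20, lens[[id]], replace = TRUE)
  rows <- cat9[cat9$reference_seq_id == id, ]
  v[rows$position] <- rows$wild_type_aa
  refs[id] <- paste(v, collapse = "")
}
self <- do.call(rbind, lapply(seq_len(nrow(cat9)), function(r)
  project_site(cat9[r, ], refs[cat9$reference_seq_id[r]],
               setNames(refs[cat9$reference_seq_id[r]], "self"))))
cat("published catalog under self-projection (synthetic reference stand-ins):\n")
print(self[, c("target_gene", "position", "wild_type_aa", "resistant_aa",
               "query_aa", "state")])
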