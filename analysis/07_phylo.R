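#!/usr/bin/env Rscript
# Progressive alignment (Gonnet-250, gap 10/0.2), p-distances with pairwise
# deletion, neighbor-joining and 1000 bootstrap replicates on the bundle's
# diverged protein family; the estimated tree is compared with the
# generating topology and written as Newick, the distance matrix as PHYLIP.
suppressMessages(library(tsitescreen))
suppressMessages(library(ape))

bundle <- read_bundle("results/bundle")
fam <- bundle$family
msa <- progressive_msa(fam)
dm <- msa_distances(msa)
write_phylip(dm, "results/family_distances.phy")
tree <- bootstrap_nj(msa, reps = 1000, seed = 7)
nwk <- write_newick(tree)
writeLines(nwk, "results/family_tree.nwk")
cat("alignment:", length(msa), "sequences x", nchar(msa[[1]]), "columns\n")
cat("tree:", nwk, "\n")

truth <- read.tree(text = bundle$truth$family_tree)
est <- as_phylo(tree)
rf <- phangorn::RF.dist(unroot(truth), unroot(est))
cat("Robinson-Foulds distance to the generating topology:", rf, "\n")
sup <- as.numeric(regmatches(nwk, gregexpr("(?<=\\))[0-9.]+(?=:)", nwk,
                                           perl = TRUE))[[1]])
cat("bootstrap supports (1000 reps):", paste(sup, collapse = ", "), "\n")
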