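test_that("progressive alignment handles identical and inserted sequences", {
  msa <- progressive_msa(c(a = "MKVLD", b = "MKVLD"))
  expect_identical(unname(msa), c("MKVLD", "MKVLD"))
  # one sequence with a 2-residue insertion: gapped in the other two
  set.seed(20)
  base <- random_aa_string(60)
  ins <- paste0(substring(base, 1, 30), "WW", substring(base, 31))
  msa2 <- progressive_msa(c(s1 = base, s2 = base, s3 = ins))
  expect_identical(nchar(msa2[["s3"]]), 62L)
  expect_identical(unname(nchar(msa2)), rep(62L, 3))
  expect_identical(substring(msa2[["s1"]], 31, 32), "--")
  expect_identical(gsub("-", "", msa2[["s1"]]), base)
  expect_error(progressive_msa(c(a = "MKV")), "at least 2")
})

test_that("alignment width is at least the longest sequence and input-order invariant", {
  set.seed(21)
  seqs <- setNames(vapply(1:5, function(i)
    random_aa_string(sample(40:60, 1)), ""), paste0("s", 1:5))
  msa <- progressive_msa(seqs)
  expect_gte(nchar(msa[[1]]), max(nchar(seqs)))
  msa_perm <- progressive_msa(seqs[c(3, 1, 5, 2, 4)])
  expect_identical(nchar(msa[[1]]), nchar(msa_perm[[1]]))
  expect_identical(msa[sort(names(msa))], msa_perm[sort(names(msa_perm))])
})

test_that("alignment distances follow p-distance and Poisson closed forms", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAACC")
  D <- msa_distances(msa)
  expect_equal(D["a", "b"], 0.2)
  expect_equal(unname(diag(D)), c(0, 0))
  # pairwise deletion ignores gap columns
  msa2 <- c(a = "AAAA-AAAAA", b = "AAAAC-AAAC")
  D2 <- msa_distances(msa2)
  expect_equal(D2["a", "b"], 1 / 8)
  P <- msa_distances(msa, "poisson")
  expect_equal(P["a", "b"], -log(1 - 0.2))
})

test_that("neighbor-joining recovers additive four-taxon matrices exactly", {
  set.seed(22)
  for (rep in 1:20) {
    # additive matrix from a random 4-taxon tree ((A,B),(C,D)) with random
    # positive edge lengths
    e <- runif(5, 0.05, 1)   # pendant a,b,c,d + internal
    labs <- c("A", "B", "C", "D")
    dm <- matrix(0, 4, 4, dimnames = list(labs, labs))
    dm["A", "B"] <- dm["B", "A"] <- e[1] + e[2]
    dm["C", "D"] <- dm["D", "C"] <- e[3] + e[4]
    dm["A", "C"] <- dm["C", "A"] <- e[1] + e[5] + e[3]
    dm["A", "D"] <- dm["D", "A"] <- e[1] + e[5] + e[4]
    dm["B", "C"] <- dm["C", "B"] <- e[2] + e[5] + e[3]
    dm["B", "D"] <- dm["D", "B"] <- e[2] + e[5] + e[4]
    tree <- neighbor_joining(dm)
    # topology matches the brute-force least-squares oracle
    expect_identical(sister_pair(tree), four_taxon_oracle(dm))
    # path lengths reproduce all pairwise distances
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(tree_path_length(tree, labs[i], labs[j]), dm[labs[i], labs[j]],
                   tolerance = 1e-9)
    }
  }
})

test_that("neighbor-joining agrees with the reference implementation in ape", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    labs <- paste0("t", seq_len(n))
    # random tree-generated (hence additive) distances plus mild noise
    ph <- ape::rtree(n, tip.label = labs)
    dm <- ape::cophenetic.phylo(ph)[labs, labs]
    dm <- dm + matrix(runif(n * n, 0, 0.01), n, n)
    dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    mine <- as_phylo(neighbor_joining(dm))
    ref <- ape::nj(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("degenerate and tiny inputs are handled", {
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  # star-like equidistant matrix: zero-length internal edges are clamped
  labs <- letters[1:4]
  dm <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(dm) <- 0
  tree <- neighbor_joining(dm)
  expect_identical(sort(tree_leaves(tree)), labs)
  ph <- as_phylo(tree)
  expect_true(all(ph$edge.length >= 0))
})

test_that("newick export is parseable and round-trip stable", {
  labs <- c("A", "B", "C")
  dm <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, dimnames = list(labs, labs))
  tree <- neighbor_joining(dm)
  nwk <- write_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, labs)
  # round trip preserves topology and branch lengths
  nwk2 <- ape::write.tree(ph)
  ph2 <- ape::read.tree(text = nwk2)
  expect_equal(phangorn::RF.dist(ph, ph2), 0)
})

test_that("bootstrap supports are reproducible, bounded, and high for clean signal", {
  set.seed(24)
  # two identical sequences are always sisters with support 100
  base <- random_aa_string(120)
  other1 <- diverge_family(base, "((x:1,y:1):1,(z:1,w:1):1);", 0.3)
  msa <- c(a = base, b = base, c = unname(other1["z"]), d = unname(other1["w"]))
  t1 <- bootstrap_nj(msa, reps = 60, seed = 5)
  t2 <- bootstrap_nj(msa, reps = 60, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  supports <- unlist(rapply(t1, function(x) x, how = "unlist"))
  nwk <- write_newick(t1)
  expect_match(nwk, "\\)100:")   # the a,b cherry is supported in every replicate
  t3 <- bootstrap_nj(msa, reps = 60, seed = 6)
  # different seed may change supports but all stay within [0, 100]
  sup <- as.numeric(regmatches(write_newick(t3),
                               gregexpr("(?<=\\))[0-9.]+(?=:)",
                                        write_newick(t3), perl = TRUE))[[1]])
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("supports appear after internal closing parentheses (parser oracle)", {
  set.seed(25)
  fam <- diverge_family(random_aa_string(150),
                        "((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);", 0.1)
  tree <- bootstrap_nj(progressive_msa(fam), reps = 40, seed = 2)
  ph <- ape::read.tree(text = write_newick(tree))
  expect_false(is.null(ph$node.label))
  sup <- suppressWarnings(as.numeric(ph$node.label))
  sup <- sup[!is.na(sup)]
  expect_gt(length(sup), 0L)
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("family divergence follows the per-edge substitution model", {
  root <- random_aa_string(300)
  tree <- "((A:1,B:1):1,(C:1,D:1):1);"
  # rate 0: all leaves identical to the root
  fam0 <- diverge_family(root, tree, 0)
  expect_true(all(fam0 == root))
  # mean leaf-root difference approximates the closed form
  # P(site differs) after k edges of rate r is at most k*r; with back
  # substitutions the expectation is 1-(1-r)^k up to 19/20 corrections
  set.seed(26)
  r <- 0.05
  k <- 2   # edges from root to each leaf
  diffs <- replicate(20, {
    fam <- diverge_family(root, tree, r)
    mean(strsplit(fam[["A"]], "")[[1]] != strsplit(root, "")[[1]])
  })
  expected <- 1 - (1 - r)^k
  expect_lt(abs(mean(diffs) - expected * (1 - r / 19)), 0.01)
})
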