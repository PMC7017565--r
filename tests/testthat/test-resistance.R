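# Synthetic stand-ins for the catalog's reference proteins: random sequences
# of realistic length carrying the wild-type residue at every cataloged
# position (the real accessions are not bundled).
synthetic_references <- function(catalog, seed = 77) {
  set.seed(seed)
  lens <- c(Dmel_DSC1 = 2100L, Pxyl_Ryr = 5100L, Dmel_RDL = 600L,
            Rmic_TAR1 = 450L, Rmic_OctB2R = 480L)
  refs <- character()
  for (id in unique(catalog$reference_seq_id)) {
    v <- strsplit(random_aa_string(lens[[id]]), "")[[1]]
    rows <- catalog[catalog$reference_seq_id == id, ]
    v[rows$position] <- rows$wild_type_aa
    refs[id] <- paste(v, collapse = "")
  }
  refs
}

test_that("the shipped catalog carries the nine published mutations", {
  cat <- read_catalog()
  expect_identical(nrow(cat), 9L)
  expect_setequal(paste0(cat$wild_type_aa, cat$position, cat$resistant_aa),
                  c("D1924N", "E1338D", "Q4594L", "I4790M", "G4946E",
                    "A302S", "T8P", "L22S", "I61F"))
  expect_true(all(cat$wild_type_aa != cat$resistant_aa))
})

test_that("self-projection is susceptible at every catalog site", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  omap <- as.list(setNames(paste0("Q_", unique(cat$target_gene)),
                           unique(cat$target_gene)))
  queries <- setNames(unname(refs[cat$reference_seq_id[
    !duplicated(cat$target_gene)]]),
    paste0("Q_", unique(cat$target_gene)))
  calls <- screen_catalog(cat, refs, queries, omap)
  expect_identical(nrow(calls), 9L)
  expect_true(all(calls$state == "susceptible"))
  expect_identical(calls$query_position, calls$position)
})

test_that("planted A302S-type substitutions are called resistant", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  rdl_entry <- cat[cat$target_gene == "RDL", ]
  q <- strsplit(refs[["Dmel_RDL"]], "")[[1]]
  q[302] <- "S"
  call <- project_site(rdl_entry, refs["Dmel_RDL"],
                       c(query_rdl = paste(q, collapse = "")))
  expect_identical(call$state, "resistant")
  expect_identical(call$query_aa, "S")
  expect_identical(call$query_position, 302L)
})

test_that("a divergent residue at the homologous column is called divergent", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  dsc1 <- cat[cat$target_gene == "DSC1", ]
  q <- strsplit(refs[["Dmel_DSC1"]], "")[[1]]
  q[1924] <- "T"   # sodium-channel-like paralogs carry T at this column
  call <- project_site(dsc1, refs["Dmel_DSC1"],
                       c(query_sc1 = paste(q, collapse = "")))
  expect_identical(call$state, "divergent")
  expect_identical(call$query_aa, "T")
})

test_that("sites in an unalignable N-terminus are called unalignable", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  tar1 <- cat[cat$target_gene == "TAR1" & cat$position == 8, ]
  # query lacking the first 60 residues entirely (divergent N-terminus)
  q <- substring(refs[["Rmic_TAR1"]], 61)
  call <- project_site(tar1, refs["Rmic_TAR1"], c(q_tar = q))
  expect_identical(call$state, "unalignable")
  expect_true(is.na(call$query_aa))
})

test_that("calls are invariant to unrelated terminal extensions", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  rdl <- cat[cat$target_gene == "RDL", ]
  set.seed(5)
  q0 <- refs[["Dmel_RDL"]]
  q1 <- paste0(random_aa_string(40), q0)
  q2 <- paste0(q0, random_aa_string(40))
  states <- vapply(list(q0, q1, q2), function(q)
    project_site(rdl, refs["Dmel_RDL"], c(q = q))$state, "")
  expect_true(all(states == "susceptible"))
})

test_that("reference drift triggers a warning but still projects", {
  cat <- read_catalog()
  refs <- synthetic_references(cat)
  drifted <- strsplit(refs[["Dmel_RDL"]], "")[[1]]
  drifted[302] <- "G"
  expect_warning(
    project_site(cat[cat$target_gene == "RDL", ],
                 setNames(paste(drifted, collapse = ""), "Dmel_RDL"),
                 c(q = refs[["Dmel_RDL"]])),
    "drift")
})

test_that("the screen recovers exactly the planted resistant alleles", {
  b <- simulate_screen_data(sim_config(seed = 31, n_genes = 10,
                                       resistance_plant_rate = 0.3))
  truth_state <- vapply(b$truth$genes, function(g)
    isTRUE(g$resistance$planted), TRUE)
  calls <- screen_catalog(b$catalog, b$refs, b$proteome,
                          as.list(setNames(b$catalog$target_gene,
                                           b$catalog$target_gene)))
  expect_identical(sort(calls$target_gene[calls$state == "resistant"]),
                   sort(names(truth_state)[truth_state]))
  expect_true(all(calls$state[!calls$target_gene %in%
                                names(truth_state)[truth_state]] ==
                    "susceptible"))
  # state partition is exhaustive and mutually exclusive
  expect_true(all(calls$state %in% c("susceptible", "resistant", "divergent",
                                     "unalignable", "no_ortholog")))
  # a gene with no ortholog is reported as such
  cat2 <- b$catalog[1, ]
  cat2$target_gene <- "missing_gene"
  calls2 <- screen_catalog(cat2, b$refs, b$proteome,
                           list(missing_gene = NA_character_))
  expect_identical(calls2$state, "no_ortholog")
})

test_that("a fully susceptible proteome yields zero resistant calls", {
  b <- simulate_screen_data(sim_config(seed = 32, n_genes = 8,
                                       resistance_plant_rate = 0))
  calls <- screen_catalog(b$catalog, b$refs, b$proteome,
                          as.list(setNames(b$catalog$target_gene,
                                           b$catalog$target_gene)))
  expect_identical(sum(calls$state == "resistant"), 0L)
  expect_true(all(calls$state == "susceptible"))
})
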