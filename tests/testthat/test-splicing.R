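test_that("a constructed two-exon gene maps back to exact boundaries", {
  set.seed(50)
  e1 <- random_dna_string(80)
  e2 <- random_dna_string(90)
  intron <- paste0("GT", random_dna_string(50), "AG")
  contig <- paste0(random_dna_string(30), e1, intron, e2,
                   random_dna_string(30))
  m <- map_transcript(paste0(e1, e2), contig)
  expect_identical(unname(m$exons),
                   cbind(c(30L, 30L + 80L + 54L),
                         c(30L + 80L, 30L + 80L + 54L + 90L)))
  expect_identical(m$strand, "+")
  expect_identical(spliced_transcript(m, Biostrings::DNAStringSet(
    c(contig = contig))), paste0(e1, e2))
})

test_that("non-consensus introns are rejected under the default consensus", {
  set.seed(51)
  e1 <- random_dna_string(80)
  e2 <- random_dna_string(90)
  contig_gc <- paste0(random_dna_string(30), e1, "GC",
                      random_dna_string(50), "AG", e2, random_dna_string(30))
  expect_error(map_transcript(paste0(e1, e2), contig_gc), "unmappable")
})

test_that("mapping recovers generator truth on multi-exon genes of both strands", {
  b <- simulate_screen_data(sim_config(seed = 97, n_genes = 25))
  strands <- vapply(b$models, `[[`, "", "strand")
  expect_true(all(c("+", "-") %in% strands))
  for (tid in names(b$models)) {
    m <- b$models[[tid]]
    mapped <- map_transcript(as.character(b$transcripts[[tid]]),
                             as.character(b$contigs[[m$contig_id]]))
    expect_identical(unname(mapped$exons), unname(m$exons), label = tid)
    expect_identical(mapped$strand, m$strand, label = tid)
    # every intron satisfies GT..AG on the sense strand
    L <- Biostrings::width(b$contigs[m$contig_id])
    sx <- tsitescreen:::sense_exons(mapped, L)
    if (nrow(sx) > 1L) {
      S <- if (m$strand == "+") as.character(b$contigs[[m$contig_id]])
           else revcomp(as.character(b$contigs[[m$contig_id]]))
      for (i in seq_len(nrow(sx) - 1L)) {
        expect_identical(substring(S, sx[i, 2] + 1L, sx[i, 2] + 2L), "GT")
        expect_identical(substring(S, sx[i + 1L, 1] - 1L, sx[i + 1L, 1]), "AG")
      }
    }
  }
})

test_that("isoform enumeration is exactly 2^n in binary-counting order", {
  expect_identical(nrow(enumerate_isoforms(letters[1:4])), 16L)
  expect_identical(nrow(enumerate_isoforms(character())), 1L)
  expect_identical(nrow(enumerate_isoforms(letters[1:3])), 8L)
  e <- enumerate_isoforms(c("f1", "f2"))
  expect_identical(unname(as.matrix(e)),
                   matrix(c(FALSE, FALSE, TRUE, TRUE,
                            FALSE, TRUE, FALSE, TRUE), ncol = 2))
})

test_that("identical models yield no events and duplicates are counted", {
  set.seed(52)
  e1 <- random_dna_string(60); e2 <- random_dna_string(60)
  contig <- paste0("AAAA", e1, "GT", random_dna_string(40), "AG", e2, "TTTT")
  m <- map_transcript(paste0(e1, e2), contig)
  ev <- diff_isoforms(list(a = m, b = m), contig)
  expect_identical(nrow(ev), 0L)
  tab <- config_table(list(a = m, b = m), contig)
  expect_identical(attr(tab, "duplicated_configs"), 1L)
})

test_that("the acceptor-variant demonstration locus yields MSSS", {
  a3 <- alpha3_splice_locus()
  gm <- lapply(a3$transcripts, map_transcript, contig = a3$contig)
  ev <- diff_isoforms(gm, a3$contig, primary = "primary")
  expect_identical(ev$kind, "alt_acceptor")
  expect_identical(ev$shift_nt, 12L)
  expect_true(ev$in_frame)
  expect_identical(ev$added_peptide, "MSSS")
})

test_that("the pHCl-type locus reproduces the seven-variant feature table", {
  ph <- phcl_splice_locus()
  gm <- lapply(ph$transcripts, map_transcript, contig = ph$contig)
  tab <- config_table(gm, ph$contig, primary = "x7")
  expect_identical(ncol(tab), 4L)
  expect_identical(nrow(tab), 7L)
  # expected presence marks per variant (cassette a, cassette b, acceptor, donor)
  marks <- format_config_table(tab)
  expect_identical(unname(unlist(marks["x1", ])), c("X", "X", "X", "-"))
  expect_identical(unname(unlist(marks["x2", ])), c("X", "X", "-", "X"))
  expect_identical(unname(unlist(marks["x7", ])), c("-", "-", "-", "-"))
  # co-occurrence of both cassette exons in x1-x3
  expect_true(all(tab[c("x1", "x2", "x3"), 1] & tab[c("x1", "x2", "x3"), 2]))
  # donor extension adds VNIN (single-event comparison x3 vs x2)
  ev_d <- diff_isoforms(gm[c("x3", "x2")], ph$contig, primary = "x3")
  expect_identical(ev_d$kind, "alt_donor")
  expect_identical(ev_d$added_peptide, "VNIN")
  # acceptor extension adds SCLLQ (single-event comparison x7 vs x6)
  ev_a <- diff_isoforms(gm[c("x7", "x6")], ph$contig, primary = "x7")
  expect_identical(ev_a$added_peptide, "SCLLQ")
  expect_identical(ev_a$shift_nt, 15L)
})

test_that("in-frame events leave the downstream protein unchanged", {
  ph <- phcl_splice_locus()
  gm <- lapply(ph$transcripts, map_transcript, contig = ph$contig)
  p7 <- tsitescreen:::orf_translate(spliced_transcript(
    gm$x7, Biostrings::DNAStringSet(c(contig = ph$contig))))
  p6 <- tsitescreen:::orf_translate(spliced_transcript(
    gm$x6, Biostrings::DNAStringSet(c(contig = ph$contig))))
  # the variant protein ends with the same residues as the reference
  expect_identical(substring(p6, nchar(p6) - 20, nchar(p6)),
                   substring(p7, nchar(p7) - 20, nchar(p7)))
  expect_identical(nchar(p6) - nchar(p7), 5L)
})

test_that("exon search finds planted and diverged exons and reports absence", {
  set.seed(60)
  exon <- random_dna_string(120)
  genomic <- paste0(random_dna_string(300), exon, random_dna_string(300))
  hit <- find_missing_exon(exon, genomic)
  expect_identical(hit$interval, c(300L, 420L))
  expect_equal(hit$identity, 100)
  # diverged copy (~18 % mutated) is still found, identity reported
  v <- strsplit(exon, "")[[1]]
  idx <- sample(length(v), 22)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  genomic2 <- paste0(random_dna_string(300), paste(v, collapse = ""),
                     random_dna_string(300))
  hit2 <- find_missing_exon(exon, genomic2)
  expect_false(is.null(hit2))
  expect_lt(hit2$identity, 95)
  expect_gt(hit2$identity, 70)
  # absent exon: random locus
  expect_null(find_missing_exon(exon, random_dna_string(700)))
  # protein-mode search on a translated frame
  cds <- paste0("ATG", paste(sample(tsitescreen:::NONSTOP_CODONS, 40,
                                    replace = TRUE), collapse = ""))
  genomic3 <- paste0(random_dna_string(200), cds, random_dna_string(200))
  expect_false(is.null(find_missing_exon(cds, genomic3, as_protein = TRUE)))
})
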