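#' Demonstration loci reproducing published splice arithmetic
#'
#' Two fully synthetic loci whose alternative-splicing geometry reproduces
#' the splice arithmetic reported for small-hive-beetle channel genes: an
#' alpha3-type nAChR locus where a 12-nt upstream intron-acceptor variant
#' adds the in-frame peptide MSSS, and a pHCl-type locus with two cassette
#' exons (9a/9b) plus a 12-nt donor extension (adds VNIN) and a 15-nt
#' acceptor extension (adds SCLLQ) of the downstream intron -- four
#' independent features, hence an isoform space of 16.  All sequences are
#' synthetic; only the junction geometry and the added peptides match the
#' published gene models.
#'
#' @name splice_demo_loci
NULL

with_fixed_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

filler_codons <- function(k) {
  paste(sample(NONSTOP_CODONS, k, replace = TRUE), collapse = "")
}

#' @rdname splice_demo_loci
#' @return `alpha3_splice_locus()`: list with `contig`, `transcripts`
#'   (primary + acceptor-variant), and `expected` (shift 12, peptide MSSS).
#'   The exon junction sits at codon phase 2, as in the annotated gene, so
#'   the 12 added nucleotides read MSSS in the transcript frame while the
#'   flanking protein is unchanged.
#' @export
alpha3_splice_locus <- function() {
  with_fixed_rng(20160311L, {
    # exon 1 ends mid-codon on "CA"; exon 2 starts with "T" (CAT = H).
    # The 12-nt acceptor extension CATGTCTTCAAG ends with the AG that forms
    # the primary acceptor and reads (C)AC-ATG-TCT-TCA-AG(T) = H,M,S,S,S in
    # the shifted frame: the variant protein gains exactly MSSS.
    e1 <- paste0("ATG", filler_codons(30L), "CA")
    e2 <- paste0("T", filler_codons(30L), "TAA")
    ext <- "CATGTCTTCAAG"
    intron_core <- paste0("GT", filler_codons(20L), "AG")
    contig <- paste0(filler_codons(10L), e1, intron_core, ext, e2,
                     filler_codons(10L))
    list(contig = contig,
         transcripts = c(primary = paste0(e1, e2),
                         acceptor_variant = paste0(e1, ext, e2)),
         expected = list(kind = "alt_acceptor", shift_nt = 12L,
                         added_peptide = "MSSS"))
  })
}

#' @rdname splice_demo_loci
#' @return `phcl_splice_locus()`: list with `contig`, `transcripts` (the
#'   seven annotated variants x1-x7), `features` (the four independent
#'   splice features), and `expected` peptides for the intron-10 donor
#'   (VNIN) and acceptor (SCLLQ) extensions.
#' @export
phcl_splice_locus <- function() {
  with_fixed_rng(20160312L, {
    e8 <- paste0("ATG", filler_codons(40L))
    ex9a <- filler_codons(12L)
    ex9b <- filler_codons(14L)
    e10 <- filler_codons(35L)
    e11 <- paste0(filler_codons(30L), "TAA")
    # donor extension starts with the GT of the primary donor site and
    # reads GTC-AAT-ATT-AAT = VNIN; acceptor extension ends with the AG of
    # the primary acceptor and reads AGC-TGT-CTT-CTT-CAG = SCLLQ.
    ext_d <- "GTCAATATTAAT"
    ext_a <- "AGCTGTCTTCTTCAG"
    i8 <- paste0("GT", filler_codons(15L), "AG")
    i8b <- paste0("GT", filler_codons(16L), "AG")
    i9 <- paste0("GT", filler_codons(17L), "AG")
    i10core <- paste0("GT", filler_codons(18L), "AG")
    contig <- paste0(filler_codons(8L), e8, i8, ex9a, i8b, ex9b, i9, e10,
                     ext_d, i10core, ext_a, e11, filler_codons(8L))
    tx <- function(a9a, a9b, don, acc) {
      paste0(e8, if (a9a) ex9a else "", if (a9b) ex9b else "", e10,
             if (don) ext_d else "", if (acc) ext_a else "", e11)
    }
    transcripts <- c(
      x1 = tx(TRUE, TRUE, FALSE, TRUE),
      x2 = tx(TRUE, TRUE, TRUE, FALSE),
      x3 = tx(TRUE, TRUE, FALSE, FALSE),
      x4 = tx(FALSE, TRUE, FALSE, TRUE),
      x5 = tx(TRUE, FALSE, FALSE, TRUE),
      x6 = tx(FALSE, FALSE, FALSE, TRUE),
      x7 = tx(FALSE, FALSE, FALSE, FALSE))
    list(contig = contig, transcripts = transcripts,
         features = c("exon9a", "exon9b", "intron10_donor_ext",
                      "intron10_acceptor_ext"),
         expected = list(donor_peptide = "VNIN", donor_shift = 12L,
                         acceptor_peptide = "SCLLQ", acceptor_shift = 15L))
  })
}
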