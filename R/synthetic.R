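#' Synthetic genome bundles with truth tables
#'
#' Generates multi-exon genes with GT-AG introns on both strands, cassette
#' exons and alternative donor/acceptor sites, planted A>G editing sites in
#' the transcript evidence, planted resistance alleles at cataloged codons,
#' embedded channel/PTM motifs, and a protein family diverged along a known
#' tree -- together with a truth table recording every planted feature.
#' Every stage of the screen can therefore be validated end-to-end against
#' known ground truth.
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults describe a desk-scale susceptible genome: 20 genes of 250-450
#' codons in 3-6 exons, introns of 40-120 nt, 40 % of genes on the minus
#' strand, a quarter of genes with a cassette exon and a quarter with an
#' alternative splice site (frame-preserving 12/15-nt shifts), one planted
#' A>G edit per gene on average, reference orthologs diverged 7 % from their
#' queries, and resistance alleles planted at 30 % of cataloged sites.
#'
#' @param seed master seed; all per-output RNG streams derive from it.
#' @param n_genes number of genes (one contig per gene).
#' @param exons_per_gene integer range `c(min, max)`.
#' @param codons_per_gene range of CDS length in codons (excluding stop).
#' @param intron_len range of intron lengths, minimum 30 nt.
#' @param flank_len range of intergenic flank lengths.
#' @param minus_strand_frac fraction of genes simulated on the minus strand.
#' @param cassette_prob probability a gene carries a cassette exon.
#' @param alt_site_prob probability a gene carries an alternative
#'   donor/acceptor site.
#' @param alt_site_shifts candidate shifts in nt (frame-preserving values,
#'   i.e. multiples of 3, keep variant ORFs intact).
#' @param edit_mean Poisson mean of planted A>G edits per gene (capped at 2
#'   per exon, the mapper's default mismatch budget).
#' @param resistance_plant_rate probability a gene's cataloged site carries
#'   the resistant allele.
#' @param ref_divergence per-residue substitution rate between query and
#'   reference ortholog.
#' @param embed_motifs plant channel-feature motifs in the first genes.
#' @param family_tree Newick string for the diverged family.
#' @param subst_rate_per_edge per-site, per-edge substitution probability
#'   for the family.
#' @param family_root_len root protein length for the family.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = c(3L, 6L),
                       codons_per_gene = c(250L, 450L),
                       intron_len = c(40L, 120L), flank_len = c(60L, 150L),
                       minus_strand_frac = 0.4, cassette_prob = 0.25,
                       alt_site_prob = 0.25, alt_site_shifts = c(12L, 15L),
                       edit_mean = 1, resistance_plant_rate = 0.3,
                       ref_divergence = 0.07, embed_motifs = TRUE,
                       family_tree = "((A:1,B:1):1,(C:1,D:1):1,(E:1,(F:1,(G:1,H:1):1):1):1);",
                       subst_rate_per_edge = 0.05,
                       family_root_len = 200L) {
  if (min(intron_len) < 30L) stop("infeasible config: intron range below 30 nt")
  stopifnot(cassette_prob >= 0, cassette_prob <= 1,
            alt_site_prob >= 0, alt_site_prob <= 1,
            all(alt_site_shifts != 0L))
  structure(as.list(environment()), class = "sim_config")
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
NONSTOP_CODONS <- unlist(CODON_TABLE[names(CODON_TABLE) != "*"], use.names = FALSE)
AA20 <- setdiff(names(CODON_TABLE), "*")

derive_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + stream * 1009L) %% .Machine$integer.max
}

random_protein <- function(ncodon) {
  paste(c("M", sample(AA20, ncodon - 1L, replace = TRUE)), collapse = "")
}

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- CODON_TABLE[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intron filler that avoids premature acceptor-like AG in the last bases
random_intron <- function(len) {
  filler <- random_dna(len - 4L)
  paste0("GT", filler, "AG")
}

# acceptor-extension sequence: s nt of non-stop codons whose final codon
# ends with the AG that forms the primary acceptor site
acceptor_ext <- function(s) {
  stopifnot(s %% 3L == 0L)
  k <- s %/% 3L
  last <- sample(c("AAG", "CAG", "GAG"), 1L)
  paste0(paste(sample(NONSTOP_CODONS, k - 1L, replace = TRUE), collapse = ""),
         last)
}

# donor-extension: starts with the GT that forms the primary donor site
donor_ext <- function(s) {
  stopifnot(s %% 3L == 0L)
  k <- s %/% 3L
  first <- sample(paste0("GT", c("A", "C", "G", "T")), 1L)
  paste0(first, paste(sample(NONSTOP_CODONS, k - 1L, replace = TRUE),
                      collapse = ""))
}

#' Generate a synthetic screening bundle
#'
#' @param config a [sim_config()].
#' @return list with `contigs` (`DNAStringSet`, one per gene), `models`
#'   (named list of `gene_model`s, one per emitted transcript),
#'   `transcripts` (`DNAStringSet`, planted edits applied to the primary
#'   transcript's evidence), `proteome` (`AAStringSet`, one primary protein
#'   per gene), `refs` (diverged reference orthologs), `catalog` (synthetic
#'   resistance catalog), `family` (sequences diverged along
#'   `config$family_tree`), and `truth` (per-gene records of exon
#'   coordinates, features, planted edits/alleles/motifs and the family
#'   tree).
#' @export
simulate_screen_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))

  set.seed(derive_seed(config$seed, 1L))   # structure stream
  genes <- lapply(seq_len(config$n_genes), function(i)
    plan_gene(i, config))
  names(genes) <- vapply(genes, `[[`, "", "gene_id")

  if (config$embed_motifs) {
    set.seed(derive_seed(config$seed, 2L)) # motif stream
    genes <- plant_motifs(genes)
  }

  set.seed(derive_seed(config$seed, 3L))   # resistance stream
  res <- plant_resistance(genes, config)
  genes <- res$genes

  set.seed(derive_seed(config$seed, 4L))   # sequence-realization stream
  genes <- lapply(genes, realize_gene, config = config)

  set.seed(derive_seed(config$seed, 5L))   # editing stream
  genes <- lapply(genes, plant_edits, config = config)

  set.seed(derive_seed(config$seed, 6L))   # family stream
  root <- random_protein(config$family_root_len)
  family <- diverge_family(root, config$family_tree,
                           config$subst_rate_per_edge)

  bundle_from_genes(genes, res$catalog, res$refs, family, config)
}

plan_gene <- function(i, config) {
  gene_id <- sprintf("g%02d", i)
  strand <- if (runif(1) < config$minus_strand_frac) "-" else "+"
  n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
  ncodon <- sample(seq(config$codons_per_gene[1], config$codons_per_gene[2]), 1L)
  protein <- random_protein(ncodon)
  # codon-aligned cut points -> exon lengths in codons (each >= 20 codons)
  min_c <- 20L
  cuts <- sort(sample(seq(min_c, ncodon - min_c), n_ex - 1L))
  while (n_ex > 2L && min(diff(c(0L, cuts, ncodon))) < min_c) {
    cuts <- sort(sample(seq(min_c, ncodon - min_c), n_ex - 1L))
  }
  has_cassette <- runif(1) < config$cassette_prob && n_ex >= 2L
  alt <- NULL
  if (runif(1) < config$alt_site_prob && n_ex >= 2L) {
    alt <- list(intron = sample(n_ex - 1L, 1L),
                kind = sample(c("alt_acceptor", "alt_donor"), 1L),
                shift = sample(config$alt_site_shifts, 1L))
  }
  cassette <- NULL
  if (has_cassette) {
    cass_intron <- sample(n_ex - 1L, 1L)
    if (!is.null(alt) && alt$intron == cass_intron)
      alt$intron <- if (cass_intron > 1L) cass_intron - 1L else
        if (n_ex - 1L >= cass_intron + 1L) cass_intron + 1L else
          { has_cassette <- FALSE; alt$intron }
    if (has_cassette)
      cassette <- list(intron = cass_intron,
                       codons = sample(10:30, 1L))
  }
  list(gene_id = gene_id, strand = strand, n_ex = n_ex, ncodon = ncodon,
       protein = protein, cuts = cuts, cassette = cassette, alt = alt,
       motifs = NULL, resistance = NULL)
}

plant_motifs <- function(genes) {
  plans <- list(
    list(features = c(selectivity_filter_DEEA = "DEEA",
                      fast_inactivation_MFL = "MFL")),
    list(features = c(cys_loop = paste0("C", paste(rep("A", 13), collapse = ""), "C"),
                      pore_filter_GEK = "GEK"), tm2_after_pore = TRUE),
    list(features = c(pore_filter_PAR = "PAR"), tm2_after_pore = TRUE),
    list(features = c(gpcr_DRY = "DRY"), tm3_at = TRUE))
  for (k in seq_len(min(length(plans), length(genes)))) {
    g <- genes[[k]]
    aa <- strsplit(g$protein, "")[[1]]
    pos <- 30L
    planted <- list()
    ann <- list()
    for (f in names(plans[[k]]$features)) {
      motif <- plans[[k]]$features[[f]]
      aa[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
      planted[[f]] <- list(feature = f, motif = motif, position = pos)
      if (isTRUE(plans[[k]]$tm2_after_pore) && grepl("pore", f))
        ann$TM2 <- c(pos + nchar(motif), pos + nchar(motif) + 19L)
      if (isTRUE(plans[[k]]$tm3_at) && f == "gpcr_DRY")
        ann$TM3 <- c(pos - 20L, pos + 2L)
      pos <- pos + nchar(motif) + 17L
    }
    g$protein <- paste(aa, collapse = "")
    g$motifs <- planted
    g$annotations <- ann
    genes[[k]] <- g
  }
  genes
}

plant_resistance <- function(genes, config) {
  catalog <- NULL
  refs <- character()
  for (id in names(genes)) {
    g <- genes[[id]]
    aa <- strsplit(g$protein, "")[[1]]
    occupied <- integer()
    for (mt in g$motifs)
      occupied <- c(occupied, seq(mt$position, mt$position + nchar(mt$motif)))
    for (an in g$annotations)
      occupied <- c(occupied, seq(an[1], an[2]))
    cand <- setdiff(seq(15L, length(aa) - 15L), occupied)
    p <- sample(cand, 1L)
    wt <- aa[p]
    resistant <- sample(setdiff(AA20, wt), 1L)
    planted <- runif(1) < config$resistance_plant_rate
    if (planted) aa[p] <- resistant
    # reference ortholog: wild type at the site, diverged elsewhere
    ref <- aa
    ref[p] <- wt
    subs <- which(runif(length(ref)) < config$ref_divergence)
    subs <- setdiff(subs, c(1L, p))
    for (sp in subs) ref[sp] <- sample(setdiff(AA20, ref[sp]), 1L)
    refs[paste0("REF_", id)] <- paste(ref, collapse = "")
    catalog <- rbind(catalog, data.frame(
      target_gene = id, reference_species = "synthetic_reference",
      reference_seq_id = paste0("REF_", id), position = p,
      wild_type_aa = wt, resistant_aa = resistant,
      insecticide_class = "synthetic", stringsAsFactors = FALSE))
    g$protein <- paste(aa, collapse = "")
    g$resistance <- list(position = p, wild_type = wt, resistant = resistant,
                         planted = planted)
    genes[[id]] <- g
  }
  list(genes = genes, catalog = catalog, refs = refs)
}

realize_gene <- function(g, config) {
  cds <- paste0(reverse_translate(g$protein),
                sample(c("TAA", "TGA"), 1L))   # avoid TAG: keeps AG planting unambiguous? no -- stop codon sits inside the last exon; TAG is fine too but TAA/TGA chosen for simplicity
  ncodon_tot <- nchar(cds) %/% 3L
  cut_nt <- g$cuts * 3L
  exon_seqs <- substring(cds, c(1L, cut_nt + 1L), c(cut_nt, nchar(cds)))
  n_ex <- length(exon_seqs)
  introns <- vapply(seq_len(n_ex - 1L), function(i)
    random_intron(sample(seq(config$intron_len[1], config$intron_len[2]), 1L)),
    "")
  # alternative-site extension sequences live at the intron boundary
  alt <- g$alt
  ext <- NULL
  if (!is.null(alt)) {
    if (alt$kind == "alt_acceptor") {
      ext <- acceptor_ext(alt$shift)
      introns[alt$intron] <- paste0(introns[alt$intron], ext)
    } else {
      ext <- donor_ext(alt$shift)
      introns[alt$intron] <- paste0(ext, introns[alt$intron])
    }
  }
  cassette <- g$cassette
  cass_seq <- NULL
  cass_intron2 <- NULL
  if (!is.null(cassette)) {
    cass_seq <- paste(sample(NONSTOP_CODONS, cassette$codons, replace = TRUE),
                      collapse = "")
    cass_intron2 <- random_intron(
      sample(seq(config$intron_len[1], config$intron_len[2]), 1L))
  }
  flankL <- random_dna(sample(seq(config$flank_len[1], config$flank_len[2]), 1L))
  flankR <- random_dna(sample(seq(config$flank_len[1], config$flank_len[2]), 1L))
  # assemble the sense-strand locus and record exon intervals
  pieces <- character()
  exon_iv <- matrix(0L, 0L, 2L)
  cass_iv <- NULL
  pos <- nchar(flankL)
  pieces <- flankL
  for (i in seq_len(n_ex)) {
    exon_iv <- rbind(exon_iv, c(pos, pos + nchar(exon_seqs[i])))
    pieces <- c(pieces, exon_seqs[i])
    pos <- pos + nchar(exon_seqs[i])
    if (i < n_ex) {
      if (!is.null(cassette) && cassette$intron == i) {
        pieces <- c(pieces, introns[i], cass_seq, cass_intron2)
        cass_iv <- c(pos + nchar(introns[i]),
                     pos + nchar(introns[i]) + nchar(cass_seq))
        pos <- pos + nchar(introns[i]) + nchar(cass_seq) + nchar(cass_intron2)
      } else {
        pieces <- c(pieces, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
  }
  pieces <- c(pieces, flankR)
  locus <- paste(pieces, collapse = "")
  g$locus_sense <- locus
  g$exon_iv_sense <- exon_iv
  g$cass_iv_sense <- cass_iv
  g$alt_ext <- ext
  g$contig_id <- paste0("ctg_", g$gene_id)
  L <- nchar(locus)
  g$contig <- if (g$strand == "+") locus else revcomp(locus)
  to_genomic <- function(iv) {
    if (g$strand == "+") iv else cbind(L - iv[, 2], L - iv[, 1])
  }
  g$exon_iv <- to_genomic(exon_iv)
  if (!is.null(cass_iv))
    g$cass_iv <- to_genomic(matrix(cass_iv, ncol = 2L))
  g
}

# transcript variants for one realized gene (sense-space exon chains)
gene_isoforms <- function(g) {
  iso <- list(t1 = g$exon_iv_sense)
  nxt <- 2L
  if (!is.null(g$cassette)) {
    iv <- g$exon_iv_sense
    i <- g$cassette$intron
    with_cass <- rbind(iv[seq_len(i), , drop = FALSE],
                       matrix(g$cass_iv_sense, ncol = 2L),
                       iv[seq(i + 1L, nrow(iv)), , drop = FALSE])
    iso[[paste0("t", nxt)]] <- with_cass
    nxt <- nxt + 1L
  }
  if (!is.null(g$alt)) {
    iv <- g$exon_iv_sense
    i <- g$alt$intron
    s <- g$alt$shift
    if (g$alt$kind == "alt_acceptor") {
      iv[i + 1L, 1] <- iv[i + 1L, 1] - s
    } else {
      iv[i, 2] <- iv[i, 2] + s
    }
    iso[[paste0("t", nxt)]] <- iv
    nxt <- nxt + 1L
    if (!is.null(g$cassette)) {
      i2 <- g$cassette$intron
      both <- rbind(iv[seq_len(i2), , drop = FALSE],
                    matrix(g$cass_iv_sense, ncol = 2L),
                    iv[seq(i2 + 1L, nrow(iv)), , drop = FALSE])
      iso[[paste0("t", nxt)]] <- both
    }
  }
  iso
}

plant_edits <- function(g, config) {
  iso <- gene_isoforms(g)
  tx1 <- paste(substring(g$locus_sense, iso$t1[, 1] + 1L, iso$t1[, 2]),
               collapse = "")
  lens <- iso$t1[, 2] - iso$t1[, 1]
  cum <- cumsum(lens)
  k <- min(rpois(1L, config$edit_mean), 2L * length(lens))
  edits <- NULL
  if (k > 0L) {
    chars <- strsplit(tx1, "")[[1]]
    cand <- which(chars == "A")
    # keep sites seedable and away from junctions
    cand <- cand[cand > 25L & cand < length(chars) - 10L]
    near_junction <- function(p) {
      i <- which(p <= cum)[1]
      off <- p - c(0L, cum)[i]
      (i > 1L && off <= 6L) || (i < length(lens) && lens[i] - off < 6L)
    }
    cand <- cand[!vapply(cand, near_junction, TRUE)]
    per_exon <- integer(length(lens))
    picked <- integer()
    for (p in sample(cand)) {
      i <- which(p <= cum)[1]
      if (per_exon[i] >= 2L) next
      per_exon[i] <- per_exon[i] + 1L
      picked <- c(picked, p)
      if (length(picked) == k) break
    }
    picked <- sort(picked)
    if (length(picked)) {
      chars[picked] <- "G"
      tx1 <- paste(chars, collapse = "")
      sense_pos <- vapply(picked, function(p) {
        i <- which(p <= cum)[1]
        iso$t1[i, 1] + (p - c(0L, cum)[i]) - 1L   # 0-based sense pos
      }, 0L)
      L <- nchar(g$locus_sense)
      gpos <- if (g$strand == "+") sense_pos else L - 1L - sense_pos
      edits <- data.frame(gene = g$gene_id, transcript = "t1",
                          transcript_pos = picked,
                          genomic_pos = gpos + 1L, strand = g$strand,
                          sense_change = "A>G", stringsAsFactors = FALSE)
    }
  }
  g$tx1_evidence <- tx1
  g$edits <- edits
  g
}

bundle_from_genes <- function(genes, catalog, refs, family, config) {
  contigs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "contig"))
  names(contigs) <- vapply(genes, `[[`, "", "contig_id")
  models <- list()
  transcripts <- character()
  truth_tx <- list()
  for (g in genes) {
    iso <- gene_isoforms(g)
    L <- nchar(g$locus_sense)
    for (tid in names(iso)) {
      full_id <- paste0(g$gene_id, ".", tid)
      iv_sense <- iso[[tid]]
      iv <- if (g$strand == "+") iv_sense
            else cbind(L - iv_sense[, 2], L - iv_sense[, 1])
      ann <- if (!is.null(g$annotations)) g$annotations else list()
      models[[full_id]] <- gene_model(g$gene_id, g$contig_id, g$strand, iv,
                                      annotations = ann)
      tx <- if (tid == "t1") g$tx1_evidence
            else paste(substring(g$locus_sense, iv_sense[, 1] + 1L,
                                 iv_sense[, 2]), collapse = "")
      transcripts[full_id] <- tx
      truth_tx[[full_id]] <- list(gene = g$gene_id, transcript = tid,
                                  exons_genomic = unname(iv),
                                  strand = g$strand)
    }
  }
  proteome <- vapply(genes, `[[`, "", "protein")
  names(proteome) <- names(genes)
  truth <- list(
    seed = config$seed,
    genes = lapply(genes, function(g)
      list(gene_id = g$gene_id, contig_id = g$contig_id, strand = g$strand,
           exons_genomic = unname(g$exon_iv),
           cassette = g$cassette, alt = g$alt,
           annotations = g$annotations,
           motifs = g$motifs, resistance = g$resistance,
           edits = g$edits)),
    transcripts = truth_tx,
    edits = {
      el <- Filter(Negate(is.null), lapply(genes, `[[`, "edits"))
      if (length(el)) do.call(rbind, c(el, list(make.row.names = FALSE)))
      else NULL
    },
    family_tree = config$family_tree)
  list(contigs = contigs, models = models,
       transcripts = Biostrings::DNAStringSet(transcripts),
       proteome = Biostrings::AAStringSet(proteome),
       refs = Biostrings::AAStringSet(refs), catalog = catalog,
       family = family, truth = truth, config = config)
}

#' Write a synthetic bundle to disk
#'
#' Emits the same FASTA/GFF3/TSV dialects the pipeline reads, plus the truth
#' table as JSON.
#'
#' @param bundle from [simulate_screen_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$contigs, file.path(dir, "genome.fasta"))
  write_fasta(bundle$transcripts, file.path(dir, "transcripts.fasta"))
  write_fasta(bundle$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(bundle$refs, file.path(dir, "references.fasta"))
  write_gff3(bundle$models, file.path(dir, "annotation.gff3"))
  write_catalog(bundle$catalog, file.path(dir, "catalog.tsv"))
  write_fasta(Biostrings::AAStringSet(bundle$family),
              file.path(dir, "family.fasta"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
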