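#' End-to-end target-site screen
#'
#' Orchestrates homology -> splicing -> editing -> resistance -> motifs ->
#' phylogeny over a screening bundle and writes a deterministic report
#' directory: per-stage TSV tables, Newick trees, a per-gene text summary,
#' and a MANIFEST with an md5 checksum for every output.  Reports use
#' 1-based coordinates; all internal computation is 0-based.
#'
#' @param bundle an in-memory bundle as produced by
#'   [simulate_screen_data()], or a directory written by [write_bundle()].
#' @param out_dir output directory (created; existing files overwritten).
#' @param thresholds ortholog thresholds, see [search_thresholds()].
#' @param bootstrap_reps bootstrap replicates for the family tree.
#' @param seed seed for the bootstrap resampling.
#' @return (invisibly) a list with the per-stage tables and the tree.
#' @export
run_screen <- function(bundle, out_dir, thresholds = search_thresholds(),
                       bootstrap_reps = 100L, seed = 1L) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  proteome <- as_named_chr(bundle$proteome)
  refs <- as_named_chr(bundle$refs)

  ## 1. homology: ortholog assignment + identity of assigned pairs
  omap <- assign_orthologs(bundle$proteome, bundle$refs, thresholds)
  id_rows <- lapply(names(omap)[!is.na(omap)], function(q)
    global_identity(proteome[q], refs[omap[q]]))
  ortho <- data.frame(query_id = names(omap), ref_id = unname(omap),
                      stringsAsFactors = FALSE)
  idtab <- if (length(id_rows)) do.call(rbind, id_rows) else
    data.frame(id_a = character(), id_b = character(),
               percent_identity = numeric(), divergence = numeric(),
               columns = integer())
  ortho$percent_identity <-
    idtab$percent_identity[match(ortho$query_id, idtab$id_a)]
  ortho$divergence <- idtab$divergence[match(ortho$query_id, idtab$id_a)]
  emit(ortho, "orthologs.tsv")

  ## 2. splicing: map every transcript, classify events per gene
  tx <- if (length(bundle$transcripts)) as_named_chr(bundle$transcripts)
        else list()
  gene_of <- sub("\\..*$", "", names(tx))
  mapped <- list()
  splice_rows <- list()
  config_rows <- list()
  for (gid in unique(gene_of)) {
    tids <- names(tx)[gene_of == gid]
    contig_id <- bundle$models[[tids[1]]]$contig_id
    contig <- as.character(bundle$contigs[[contig_id]])
    gm <- lapply(tids, function(tid)
      map_transcript(tx[[tid]], contig, gene_id = gid,
                     contig_id = contig_id))
    names(gm) <- tids
    mapped[[gid]] <- gm
    ev <- diff_isoforms(gm, contig)
    if (nrow(ev)) {
      ev$gene <- gid
      splice_rows[[gid]] <- ev[, c("gene", setdiff(names(ev), "gene"))]
    }
    if (length(gm) > 1L) {
      tab <- config_table(gm, contig)
      ftab <- format_config_table(tab)
      ftab <- cbind(transcript = rownames(ftab), gene = gid, ftab)
      config_rows[[gid]] <- data.frame(
        transcript = ftab$transcript, gene = gid,
        features = paste(colnames(tab), collapse = ","),
        config = apply(format_config_table(tab), 1L, paste, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  splices <- if (length(splice_rows)) do.call(rbind, splice_rows) else
    data.frame(gene = character(), transcript = character(),
               kind = character(), intron_index = integer(),
               shift_nt = integer(), in_frame = logical(),
               added_peptide = character())
  rownames(splices) <- NULL
  emit(splices, "splice_events.tsv")
  configs <- if (length(config_rows)) do.call(rbind, config_rows) else
    data.frame(transcript = character(), gene = character(),
               features = character(), config = character())
  rownames(configs) <- NULL
  emit(configs, "isoform_configs.tsv")

  ## 3. editing: primary transcript evidence vs genome
  edit_rows <- list()
  for (gid in unique(gene_of)) {
    gm <- mapped[[gid]]
    for (tid in names(gm)) {
      contig <- bundle$contigs[gm[[tid]]$contig_id]
      calls <- call_editing(gm[[tid]], contig, tx[[tid]])
      if (nrow(calls)) {
        calls$transcript <- tid
        edit_rows[[tid]] <- calls
      }
    }
  }
  edits <- if (length(edit_rows)) do.call(rbind, edit_rows) else
    cbind(empty_edit_calls(), data.frame(transcript = character()))
  # a site supported by several isoforms is one genomic event
  edits <- edits[!duplicated(edits[, c("gene", "genomic_pos", "status")]), ,
                 drop = FALSE]
  rownames(edits) <- NULL
  emit(edits, "editing.tsv")

  ## 4. resistance screen over assigned orthologs
  res_map <- setNames(bundle$catalog$target_gene, bundle$catalog$target_gene)
  res_map[] <- ifelse(res_map %in% names(omap) & !is.na(omap[res_map]),
                      res_map, NA)
  calls <- screen_catalog(bundle$catalog, bundle$refs, bundle$proteome,
                          as.list(res_map))
  emit(calls, "resistance.tsv")

  ## 5. motifs: PTM scan + channel features where annotations exist
  ptm_rows <- list()
  feat_rows <- list()
  cat <- read_pattern_catalog()
  for (gid in names(proteome)) {
    hits <- scan_catalog(proteome[gid], cat)
    if (nrow(hits)) ptm_rows[[gid]] <- hits
    ann <- bundle$models[[paste0(gid, ".t1")]]$annotations
    if (length(ann)) {
      fr <- check_features(proteome[gid], ann)
      fr$gene <- gid
      feat_rows[[gid]] <- fr[, c("gene", "feature_id", "status", "observed",
                                 "position")]
    }
  }
  ptm <- if (length(ptm_rows)) do.call(rbind, ptm_rows) else
    data.frame(pattern_id = character(), seq_id = character(),
               start = integer(), matched = character(), name = character())
  rownames(ptm) <- NULL
  emit(ptm, "ptm_hits.tsv")
  feats <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    data.frame(gene = character(), feature_id = character(),
               status = character(), observed = character(),
               position = integer())
  rownames(feats) <- NULL
  emit(feats, "channel_features.tsv")

  ## 6. phylogeny of the diverged family
  tree <- NULL
  if (length(bundle$family) >= 3L) {
    msa <- progressive_msa(bundle$family)
    tree <- bootstrap_nj(msa, reps = bootstrap_reps, seed = seed)
    tree_path <- file.path(out_dir, "family_tree.nwk")
    writeLines(write_newick(tree), tree_path)
    outputs <- c(outputs, tree_path)
  }

  ## per-gene text summary
  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  for (gid in sort(names(proteome))) {
    cat(sprintf("== %s ==\n", gid), file = con)
    cat(sprintf("ortholog: %s (identity %.1f%%)\n",
                ifelse(is.na(omap[gid]), "none", omap[gid]),
                ortho$percent_identity[ortho$query_id == gid]), file = con)
    gs <- splices[splices$gene == gid, , drop = FALSE]
    cat(sprintf("splice events: %d\n", nrow(gs)), file = con)
    ge <- edits[edits$gene == gid & edits$status == "candidate_edit", ,
                drop = FALSE]
    cat(sprintf("candidate A>G edits: %d\n", nrow(ge)), file = con)
    gr <- calls[calls$target_gene == gid, , drop = FALSE]
    cat(sprintf("resistance sites: %s\n",
                paste(sprintf("%s%d%s:%s", gr$wild_type_aa, gr$position,
                              gr$resistant_aa, gr$state), collapse = ", ")),
        file = con)
    cat("\n", file = con)
  }
  close(con)
  outputs <- c(outputs, summary_path)

  ## run log + manifest
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("tsitescreen version: ",
           as.character(utils::packageVersion("tsitescreen"))),
    paste0("seed: ", seed),
    paste0("bootstrap_reps: ", bootstrap_reps),
    paste0("min_query_coverage: ", thresholds$min_query_coverage),
    paste0("max_evalue: ", format(thresholds$max_evalue)),
    paste0("n_genes: ", length(proteome)),
    paste0("n_transcripts: ", length(tx))), log_path)
  outputs <- c(outputs, log_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "MANIFEST"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(orthologs = ortho, splice_events = splices,
                 isoform_configs = configs, editing = edits,
                 resistance = calls, ptm_hits = ptm,
                 channel_features = feats, tree = tree, mapped = mapped))
}

#' Read a screening bundle from a directory written by [write_bundle()]
#' @param dir bundle directory.
#' @return bundle list (truth table included when present).
#' @export
read_bundle <- function(dir) {
  models <- read_gff3(file.path(dir, "annotation.gff3"))
  truth_path <- file.path(dir, "truth.json")
  ann_by_gene <- list()
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path)
    for (g in truth$genes) {
      if (length(g$annotations))
        ann_by_gene[[g$gene_id]] <- lapply(g$annotations, function(iv)
          as.integer(unlist(iv)))
    }
  }
  for (mid in names(models)) {
    gid <- models[[mid]]$gene_id
    gid <- sub("^gene:", "", gid)
    models[[mid]]$gene_id <- gid
    if (!is.null(ann_by_gene[[gid]]))
      models[[mid]]$annotations <- ann_by_gene[[gid]]
  }
  fam_path <- file.path(dir, "family.fasta")
  list(contigs = read_fasta(file.path(dir, "genome.fasta"), "dna"),
       models = models,
       transcripts = read_fasta(file.path(dir, "transcripts.fasta"), "dna"),
       proteome = read_fasta(file.path(dir, "proteome.fasta"), "protein"),
       refs = read_fasta(file.path(dir, "references.fasta"), "protein"),
       catalog = read_catalog(file.path(dir, "catalog.tsv")),
       family = if (file.exists(fam_path))
         as.character(read_fasta(fam_path, "protein")) else character(),
       truth = truth)
}
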