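#' Resistance-mutation screening
#'
#' A catalog of known target-site resistance mutations (each defined in the
#' coordinates of a reference species' protein) is projected onto query
#' orthologs by semi-global alignment (terminal gaps free), and the state of
#' each site is called: `susceptible` (query carries the wild-type residue),
#' `resistant` (the cataloged resistance residue), `divergent` (aligned but
#' neither), or `unalignable` (the reference position falls in a gap or an
#' unaligned terminus).  A low-confidence flag is raised when local identity
#' in the +/-20-residue window around the site falls below 50 %.
#'
#' @name resistance
NULL

#' Read / write the resistance-mutation catalog
#'
#' The package ships a catalog of nine published target-site mutations
#' (`system.file("extdata", "resistance_catalog.tsv", package =
#' "tsitescreen")`): positions are kept in each source's own reference
#' numbering and are never renumbered.
#'
#' @param path TSV with columns target_gene, reference_species,
#'   reference_seq_id, position, wild_type_aa, resistant_aa,
#'   insecticide_class.
#' @return data.frame.
#' @export
read_catalog <- function(path = system.file("extdata",
                                            "resistance_catalog.tsv",
                                            package = "tsitescreen")) {
  cat <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("target_gene", "reference_species", "reference_seq_id",
            "position", "wild_type_aa", "resistant_aa", "insecticide_class")
  if (!all(need %in% names(cat)))
    stop("catalog missing columns: ", paste(setdiff(need, names(cat)), collapse = ", "))
  if (any(cat$wild_type_aa == cat$resistant_aa))
    stop("catalog entry with wild_type_aa == resistant_aa")
  cat
}

#' @rdname read_catalog
#' @param catalog data.frame to write.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project one cataloged site onto a query protein
#'
#' @param entry one catalog row (list or single-row data.frame).
#' @param reference named reference protein (the species/accession the
#'   position is numbered in).
#' @param query named query protein.
#' @param matrix substitution matrix (default Gonnet-250, the package's
#'   projection matrix); gap penalties 10 / 0.2.
#' @return one-row data.frame: target_gene, query_id, query_position,
#'   query_aa, state, low_confidence, plus the catalog fields.
#' @export
project_site <- function(entry, reference, query, matrix = gonnet_matrix(),
                         gap_open = 10, gap_extend = 0.2) {
  entry <- as.list(entry)
  ref <- as_named_chr(reference)
  qry <- as_named_chr(query)
  if (!nzchar(qry[[1]])) stop("empty query sequence")
  pos <- as.integer(entry$position)
  if (pos > nchar(ref[[1]]))
    stop("catalog position ", pos, " beyond reference length")
  ref_aa <- substring(ref[[1]], pos, pos)
  if (ref_aa != entry$wild_type_aa)
    warning("reference '", names(ref)[1], "' has ", ref_aa, " at position ",
            pos, ", catalog expects ", entry$wild_type_aa,
            " (accession/version drift?)")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref[[1]]), Biostrings::AAString(qry[[1]]),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "overlap")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # overlap alignments clip unaligned termini; track original coordinates
  rstart <- IRanges::start(pa@pattern@range)
  qstart <- IRanges::start(pa@subject@range)
  ref_col <- cumsum(x != "-") + rstart - 1L
  qry_col <- cumsum(y != "-") + qstart - 1L
  col <- which(ref_col == pos & x != "-")[1]
  state <- "unalignable"
  qpos <- NA_integer_
  qaa <- NA_character_
  lowconf <- NA
  if (!is.na(col) && y[col] != "-") {
    qpos <- qry_col[col]
    qaa <- y[col]
    state <- if (qaa == entry$wild_type_aa) "susceptible"
             else if (qaa == entry$resistant_aa) "resistant"
             else "divergent"
    win <- max(1L, col - 20L):min(length(x), col + 20L)
    lowconf <- mean(x[win] == y[win] & x[win] != "-") < 0.5
  }
  data.frame(target_gene = entry$target_gene,
             reference_species = entry$reference_species,
             reference_seq_id = entry$reference_seq_id,
             position = pos, wild_type_aa = entry$wild_type_aa,
             resistant_aa = entry$resistant_aa,
             insecticide_class = entry$insecticide_class,
             query_id = names(qry)[1], query_position = qpos,
             query_aa = qaa, state = state, low_confidence = lowconf,
             stringsAsFactors = FALSE)
}

#' Screen a set of query orthologs against the mutation catalog
#'
#' One call per (catalog entry, mapped query).  Catalog entries whose target
#' gene has no assigned ortholog are reported with state `no_ortholog`.
#'
#' @param catalog data.frame from [read_catalog()].
#' @param references named protein set containing the catalog's reference
#'   sequences (by `reference_seq_id`).
#' @param queries named protein set of candidate orthologs.
#' @param ortholog_map named character vector: target_gene -> query id
#'   (`NA` = no ortholog assigned).
#' @inheritParams project_site
#' @return data.frame of calls (one row per entry).
#' @export
screen_catalog <- function(catalog, references, queries, ortholog_map,
                           matrix = gonnet_matrix(), gap_open = 10,
                           gap_extend = 0.2) {
  refs <- as_named_chr(references)
  qrys <- as_named_chr(queries)
  rows <- lapply(seq_len(nrow(catalog)), function(r) {
    entry <- catalog[r, ]
    qid <- ortholog_map[[entry$target_gene]]
    if (is.null(qid) || is.na(qid) || !qid %in% names(qrys)) {
      out <- data.frame(entry, query_id = NA_character_,
                        query_position = NA_integer_,
                        query_aa = NA_character_, state = "no_ortholog",
                        low_confidence = NA, stringsAsFactors = FALSE)
      return(out)
    }
    if (!entry$reference_seq_id %in% names(refs))
      stop("reference sequence ", entry$reference_seq_id, " not supplied")
    project_site(entry, refs[entry$reference_seq_id], qrys[qid],
                 matrix, gap_open, gap_extend)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
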