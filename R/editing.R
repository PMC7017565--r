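#' A-to-I RNA-editing detection
#'
#' Candidate editing sites are exonic mismatches between the genome-encoded
#' spliced transcript and an assembled transcript evidence sequence.  A
#' mismatch is a candidate A-to-I event when the sense strand reads A in the
#' genome and G in the evidence (operationally, A-to-I is A>G); every other
#' mismatch is logged but excluded from the edit list.  Sites within 3 nt of
#' a splice junction are flagged junction-proximal (low confidence).
#'
#' @name editing
NULL

JUNCTION_FLANK <- 3L

#' Call candidate editing sites for one gene
#'
#' @param model a `gene_model` (the genomic annotation).
#' @param contig the model's contig sequence.
#' @param evidence assembled transcript sequence; must have the same spliced
#'   length as the model (substitutions only).
#' @return data.frame: gene, transcript_pos (1-based on the transcript),
#'   genomic_pos (1-based on the contig), strand, genomic_base,
#'   transcript_base, sense_change, status
#'   (`candidate_edit` / `non-AG-mismatch`), junction_proximal.
#' @export
call_editing <- function(model, contig, evidence) {
  genomic_tx <- spliced_transcript(model, as_contig_set(contig, model$contig_id))
  ev <- toupper(as.character(evidence))
  if (nchar(ev) != nchar(genomic_tx))
    stop("unmappable evidence: spliced lengths differ (",
         nchar(genomic_tx), " vs ", nchar(ev), ")")
  g <- s2raw(genomic_tx)
  t <- s2raw(ev)
  mis <- which(g != t)
  if (!length(mis)) return(empty_edit_calls())
  ex <- exons_tx_order(model)
  lens <- ex[, 2] - ex[, 1]
  cum <- cumsum(lens)
  res <- lapply(mis, function(p) {
    gb <- rawToChar(g[p])
    tb <- rawToChar(t[p])
    gpos <- transcript_to_genome(model, p - 1L)
    i <- which(p <= cum)[1]
    off_in_exon <- p - c(0L, cum)[i]
    near <- (i > 1L && off_in_exon <= JUNCTION_FLANK) ||
            (i < nrow(ex) && lens[i] - off_in_exon < JUNCTION_FLANK)
    data.frame(gene = model$gene_id, transcript_pos = p,
               genomic_pos = gpos + 1L, strand = model$strand,
               genomic_base = gb, transcript_base = tb,
               sense_change = paste0(gb, ">", tb),
               status = if (gb == "A" && tb == "G") "candidate_edit"
                        else "non-AG-mismatch",
               junction_proximal = near, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

empty_edit_calls <- function() {
  data.frame(gene = character(), transcript_pos = integer(),
             genomic_pos = integer(), strand = character(),
             genomic_base = character(), transcript_base = character(),
             sense_change = character(), status = character(),
             junction_proximal = logical(), stringsAsFactors = FALSE)
}

#' Classify cataloged editing sites
#'
#' Each cataloged site (1-based transcript position and expected edited base)
#' is labeled `candidate_edit` when the genome reads A and the evidence the
#' edited base, `genomically_encoded` when the genome already carries the
#' edited base, and `not_detected` otherwise.
#'
#' @param catalog data.frame with columns `transcript_pos`, `edited_base`
#'   (and optionally `site_label` for externally numbered sites).
#' @inheritParams call_editing
#' @return data.frame: site_label, transcript_pos, genomic_pos, genomic_base,
#'   transcript_base, status.
#' @export
classify_known_sites <- function(catalog, model, contig, evidence) {
  genomic_tx <- spliced_transcript(model, as_contig_set(contig, model$contig_id))
  ev <- toupper(as.character(evidence))
  if (nchar(ev) != nchar(genomic_tx))
    stop("unmappable evidence: spliced lengths differ")
  labels <- if ("site_label" %in% names(catalog)) catalog$site_label
            else as.character(seq_len(nrow(catalog)))
  res <- lapply(seq_len(nrow(catalog)), function(r) {
    p <- catalog$transcript_pos[r]
    eb <- toupper(catalog$edited_base[r])
    gb <- substring(genomic_tx, p, p)
    tb <- substring(ev, p, p)
    status <- if (gb == eb) "genomically_encoded"
              else if (gb == "A" && tb == eb) "candidate_edit"
              else "not_detected"
    data.frame(site_label = labels[r], transcript_pos = p,
               genomic_pos = transcript_to_genome(model, p - 1L) + 1L,
               genomic_base = gb, transcript_base = tb, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

as_contig_set <- function(contig, id) {
  if (methods::is(contig, "DNAStringSet")) return(contig)
  out <- Biostrings::DNAStringSet(setNames(as.character(contig), id))
  out
}
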