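#' Sequence and gene-model input/output
#'
#' Sequences are held as [Biostrings::DNAStringSet] / [Biostrings::AAStringSet]
#' objects; gene models are lightweight `gene_model` S3 objects holding
#' strand-aware exon coordinates on a contig.  Coordinates are 0-based
#' half-open everywhere inside the package; the 1-based closed convention is
#' used only at the GFF3 and report boundaries.
#'
#' @name seqio
NULL

DNA_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*")

#' Read a FASTA file with validation
#'
#' Thin wrapper around the Biostrings readers that uppercases sequences,
#' validates the declared alphabet, and fails loudly on records with empty
#' sequences (naming the offending record).
#'
#' @param path path to a FASTA file (multi-record, wrapped lines allowed).
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `DNAStringSet` (dna) or `AAStringSet` (protein); names are the
#'   first whitespace-delimited token of each header, the full header is kept
#'   in the `description` metadata column.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty))
    stop("FASTA parse error: record '", ids[empty[1]], "' has no sequence")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") DNA_LETTERS else AA_LETTERS
  bad <- !vapply(strsplit(seqs, ""), function(ch) all(ch %in% allowed), logical(1))
  if (any(bad))
    stop("record '", ids[which(bad)[1]], "' contains characters outside the ",
         alphabet, " alphabet")
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- headers
  out
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param seqs a named `XStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Gene model: strand-aware exon chain on a contig
#'
#' @param gene_id,contig_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end`: 0-based half-open
#'   genomic intervals, non-overlapping, sorted by start (genomic order,
#'   regardless of strand).
#' @param cds_phase_offset 0, 1 or 2: number of bases to skip before the first
#'   complete codon of the CDS.
#' @param annotations named list of protein-coordinate intervals
#'   (`c(start, end)`, 1-based closed), e.g. transmembrane segments TM1-TM4.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons,
                       cds_phase_offset = 0L, annotations = list()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (any(exons[, 1] >= exons[, 2])) stop("exon with start >= end")
  ord <- order(exons[, 1])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene model ", gene_id)
  structure(list(gene_id = gene_id, contig_id = contig_id, strand = strand,
                 exons = exons, cds_phase_offset = as.integer(cds_phase_offset),
                 annotations = annotations),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s), %d exon(s), %d nt\n",
              x$gene_id, x$contig_id, x$strand, nrow(x$exons),
              sum(x$exons[, 2] - x$exons[, 1])))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (via [rtracklayer::import]) into one
#' `gene_model` per mRNA.  GFF3 1-based closed intervals are converted to the
#' package's 0-based half-open convention; minus-strand exons keep genomic
#' order (transcription order is computed on demand by downstream code).
#' The CDS phase of the transcription-wise first CDS segment becomes
#' `cds_phase_offset`.
#'
#' @param path GFF3 file.
#' @param contigs optional `DNAStringSet` providing contig bounds; exons
#'   outside their contig raise an error.
#' @return named list of `gene_model` objects (names = mRNA IDs).
#' @export
read_gff3 <- function(path, contigs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) == 0L) stop("no mRNA features in ", path)
  sub <- gr[typ %in% c("exon", "CDS")]
  parent <- vapply(as.list(sub$Parent), function(x)
    if (length(x)) x[1] else NA_character_, "")
  if (anyNA(parent) || any(!nzchar(parent)))
    stop("exon/CDS feature without Parent linkage in ", path)
  out <- list()
  for (k in seq_along(mrna)) {
    mid <- as.character(mrna$ID[k])
    mine <- sub[parent == mid]
    ex <- mine[as.character(mine$type) == "exon"]
    cds <- mine[as.character(mine$type) == "CDS"]
    if (length(ex) == 0L) ex <- cds
    if (length(ex) == 0L) stop("mRNA ", mid, " has no exon/CDS children")
    contig <- as.character(GenomicRanges::seqnames(ex))[1]
    strand <- as.character(GenomicRanges::strand(mrna))[k]
    if (!strand %in% c("+", "-")) strand <- "+"
    exons <- cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
    if (!is.null(contigs)) {
      if (!contig %in% names(contigs)) stop("contig ", contig, " not supplied")
      if (max(exons[, 2]) > length(contigs[[contig]]))
        stop("exon outside contig bounds for mRNA ", mid)
    }
    phase <- 0L
    if (length(cds)) {
      ph <- suppressWarnings(as.integer(as.character(cds$phase)))
      first <- if (strand == "+") which.min(GenomicRanges::start(cds))
               else which.max(GenomicRanges::end(cds))
      if (!is.na(ph[first])) phase <- ph[first]
    }
    gid <- as.character(mrna$Parent[k])
    if (length(gid) == 0L || !nzchar(gid)) gid <- mid
    out[[mid]] <- gene_model(gid, contig, strand, exons, phase)
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS rows (1-based closed coordinates) with Parent
#' linkage; exons double as CDS segments with computed phase.
#'
#' @param models named list of `gene_model` objects (names = mRNA ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (mid in names(models)) {
    m <- models[[mid]]
    lo <- min(m$exons[, 1]) + 1L
    hi <- max(m$exons[, 2])
    gid <- paste0("gene:", m$gene_id)
    lines <- c(lines,
      sprintf("%s\ttsitescreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s", m$contig_id,
              lo, hi, m$strand, gid),
      sprintf("%s\ttsitescreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$contig_id, lo, hi, m$strand, mid, gid))
    n <- nrow(m$exons)
    # phase of each CDS segment in transcription order
    lens <- m$exons[, 2] - m$exons[, 1]
    tord <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
    phase <- integer(n)
    carry <- m$cds_phase_offset
    for (i in tord) {
      phase[i] <- carry
      carry <- (3L - ((lens[i] - carry) %% 3L)) %% 3L
    }
    for (i in seq_len(n)) {
      lines <- c(lines,
        sprintf("%s\ttsitescreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                m$contig_id, m$exons[i, 1] + 1L, m$exons[i, 2], m$strand,
                mid, i, mid),
        sprintf("%s\ttsitescreen\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
                m$contig_id, m$exons[i, 1] + 1L, m$exons[i, 2], m$strand,
                phase[i], mid, i, mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand models).
#'
#' @param model a `gene_model`.
#' @param contigs `DNAStringSet` containing the model's contig.
#' @return single-character DNA string.
#' @export
spliced_transcript <- function(model, contigs) {
  contig <- as.character(contigs[[model$contig_id]])
  if (max(model$exons[, 2]) > nchar(contig))
    stop("exon outside contig bounds")
  parts <- substring(contig, model$exons[, 1] + 1L, model$exons[, 2])
  tx <- paste(parts, collapse = "")
  if (model$strand == "-") tx <- revcomp(tx)
  tx
}

#' Reverse complement of a DNA string
#' @param x character scalar (IUPAC letters allowed).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence
#'
#' Standard genetic code (table 1).  Translation runs to the first stop codon;
#' codons containing N or other ambiguity letters yield `X`.
#'
#' @param cds character scalar or `DNAString`, length >= 3.
#' @param skip bases to skip before the first codon (CDS phase offset).
#' @return character scalar protein.  Attribute `incomplete` is `TRUE` when
#'   the translated length is not a multiple of 3.
#' @export
translate_cds <- function(cds, skip = 0L) {
  cds <- as.character(cds)
  if (skip > 0L) cds <- substring(cds, skip + 1L)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  usable <- n - (n %% 3L)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substring(cds, 1L, usable)),
    if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substring(aa, 1L, stop_at - 1L)
  attr(aa, "incomplete") <- (n %% 3L) != 0L
  aa
}

#' Exon intervals in transcription order
#' @param model a `gene_model`.
#' @return exon matrix ordered 5' to 3' along the transcript.
#' @keywords internal
exons_tx_order <- function(model) {
  if (model$strand == "+") model$exons
  else model$exons[rev(seq_len(nrow(model$exons))), , drop = FALSE]
}

#' Map a transcript coordinate to a genomic coordinate
#'
#' @param model a `gene_model`.
#' @param pos 0-based position on the spliced transcript.
#' @return 0-based genomic position on the contig.
#' @export
transcript_to_genome <- function(model, pos) {
  ex <- exons_tx_order(model)
  lens <- ex[, 2] - ex[, 1]
  cum <- cumsum(lens)
  i <- which(pos < cum)[1]
  if (is.na(i)) stop("transcript position beyond spliced length")
  off <- pos - c(0L, cum)[i]
  if (model$strand == "+") ex[i, 1] + off
  else ex[i, 2] - 1L - off
}
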