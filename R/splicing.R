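#' Transcript-to-genome mapping and alternative-splicing analysis
#'
#' Transcripts are mapped back to their genomic locus by exact-match
#' seed-and-extend (transcripts are assumed to match the genome exactly up to
#' a small per-exon mismatch budget that accommodates RNA-editing sites).
#' Every intron must begin with the donor consensus and end with the acceptor
#' consensus (GT..AG by default); among equal-scoring exon chains the mapper
#' prefers consensus-satisfying introns, then leftmost donors.
#'
#' @name splicing
NULL

#' Splice-site consensus
#' @param donor,acceptor 2-nt DNA strings (defaults GT / AG).
#' @export
splice_consensus <- function(donor = "GT", acceptor = "AG") {
  stopifnot(nchar(donor) == 2L, nchar(acceptor) == 2L)
  list(donor = toupper(donor), acceptor = toupper(acceptor))
}

s2raw <- function(x) charToRaw(as.character(x))

# Extend an exact match from Tr[p1] / Sr[g1] (1-based), tolerating up to
# `budget` mismatches; stops at the first mismatch past the budget.  The
# chain search backtracks over the stall region, so an extension that runs a
# few bases into an intron is recovered by the donor slide window.
extend_match <- function(Tr, Sr, p1, g1, budget = 2L) {
  L <- min(length(Tr) - p1, length(Sr) - g1) + 1L
  if (L <= 0L) return(list(len = 0L, mismatches = integer()))
  d <- which(Tr[p1:(p1 + L - 1L)] != Sr[g1:(g1 + L - 1L)])
  if (length(d) <= budget)
    return(list(len = L, mismatches = d))
  e <- d[budget + 1L] - 1L
  list(len = e, mismatches = d[d <= e])
}

#' Map a transcript onto a genomic contig as a GT-AG exon chain
#'
#' Seed-and-extend mapping: the transcript must reproduce the spliced exon
#' chain exactly, up to `mismatch_budget` isolated substitutions per exon
#' (candidate RNA-editing sites).  Both strands are tried; introns shorter
#' than `min_intron` are never opened.  Fails with "unmappable transcript"
#' when no consensus-consistent chain exists.
#'
#' @param transcript,contig character scalars (or `DNAString`s).
#' @param consensus from [splice_consensus()].
#' @param min_intron minimum intron length in nt (default 30).
#' @param mismatch_budget tolerated substitutions per exon (default 2).
#' @param gene_id,contig_id identifiers stored in the returned model.
#' @return a [gene_model()] whose spliced transcript equals `transcript`
#'   (up to tolerated mismatches).
#' @export
map_transcript <- function(transcript, contig, consensus = splice_consensus(),
                           min_intron = 30L, mismatch_budget = 2L,
                           gene_id = "gene", contig_id = "contig") {
  tx <- toupper(as.character(transcript))
  ct <- toupper(as.character(contig))
  Tr <- s2raw(tx)
  for (strand in c("+", "-")) {
    S <- if (strand == "+") ct else revcomp(ct)
    chain <- map_one_strand(Tr, s2raw(S), consensus, min_intron,
                            mismatch_budget)
    if (!is.null(chain)) {
      ex0 <- cbind(chain[, 1] - 1L, chain[, 2])  # 1-based closed -> 0-based
      if (strand == "-") {
        L <- nchar(ct)
        ex0 <- cbind(L - ex0[, 2], L - ex0[, 1])
      }
      return(gene_model(gene_id, contig_id, strand, ex0))
    }
  }
  stop("unmappable transcript: no consensus-consistent exon chain found")
}

map_one_strand <- function(Tr, Sr, consensus, min_intron, budget,
                           seed_len = 20L, donor_window = 18L) {
  n <- length(Tr)
  m <- length(Sr)
  if (n < 3L || m < n) return(NULL)
  don <- s2raw(consensus$donor)
  acc <- s2raw(consensus$acceptor)
  k <- min(seed_len, n)
  # acceptor candidate index: genomic positions i where Sr[i:i+1] == acceptor
  accpos <- which(Sr[-m] == acc[1] & Sr[-1] == acc[2])
  starts <- which(Sr == Tr[1])
  starts <- starts[starts + k - 1L <= m]
  if (k > 1L)
    starts <- starts[vapply(starts, function(g)
      sum(Tr[1:k] != Sr[g:(g + k - 1L)]) <= budget, logical(1))]
  for (g0 in starts) {
    chain <- build_chain(Tr, Sr, g0, don, acc, accpos, min_intron, budget,
                         donor_window)
    if (!is.null(chain)) return(chain)
  }
  NULL
}

# Depth-first search over consensus-consistent exon chains: donors are
# tried leftmost-first within the slide window, acceptors shortest-intron
# first, and a junction that later proves inconsistent is backtracked.
build_chain <- function(Tr, Sr, g0, don, acc, accpos, min_intron, budget,
                        donor_window, depth = 0L) {
  if (depth > 200L) return(NULL)
  n <- length(Tr)
  m <- length(Sr)
  chain_from <- function(p, g, depth) {
    ext <- extend_match(Tr, Sr, p, g, budget)
    e <- ext$len
    if (e <= 0L) return(NULL)
    if (p + e - 1L == n) return(matrix(c(g, g + e - 1L), 1L))
    for (delta in seq(min(donor_window, e - 1L), 0L)) {
      q <- p + e - delta        # first transcript base of the next exon
      gq <- g + e - delta       # genomic position of the donor dinucleotide
      if (q <= p || gq + 1L > m) next
      if (Sr[gq] != don[1] || Sr[gq + 1L] != don[2]) next
      for (g2 in find_acceptors(Tr, Sr, q, gq, acc, accpos, min_intron,
                                budget)) {
        rest <- chain_from(q, g2, depth + 1L)
        if (!is.null(rest))
          return(rbind(c(g, gq - 1L), rest))
      }
    }
    NULL
  }
  ch <- chain_from(1L, g0, depth)
  if (is.null(ch)) return(NULL)
  # chain_from records (exon_start, exon_end) with exon_start = alignment
  # resume point, which is already the first base of each exon
  ch
}

# Acceptor candidates (shortest intron first) whose downstream sequence
# continues the transcript: the first 3 bases after the acceptor must match
# exactly, the rest of the confirmation window within the mismatch budget.
find_acceptors <- function(Tr, Sr, q, gq, acc, accpos, min_intron, budget,
                           confirm_len = 20L, max_candidates = 8L) {
  n <- length(Tr)
  m <- length(Sr)
  rest <- n - q + 1L
  w <- min(confirm_len, rest)
  exact <- min(3L, w)
  cands <- accpos[accpos >= gq + min_intron - 2L & accpos + 2L + w - 1L <= m]
  out <- integer()
  for (h in cands) {
    g2 <- h + 2L
    if (any(Tr[q:(q + exact - 1L)] != Sr[g2:(g2 + exact - 1L)])) next
    if (sum(Tr[q:(q + w - 1L)] != Sr[g2:(g2 + w - 1L)]) <= budget) {
      out <- c(out, g2)
      if (length(out) >= max_candidates) break
    }
  }
  out
}

#' Introns of a gene model in transcription order, sense-space coordinates
#'
#' @param model a `gene_model`.
#' @param contig_len length of the contig (needed for minus-strand models).
#' @return matrix of 0-based half-open intervals on the sense strand
#'   (i.e. on the reverse complement for minus-strand genes).
#' @keywords internal
sense_exons <- function(model, contig_len) {
  ex <- model$exons
  if (model$strand == "-")
    ex <- cbind(contig_len - ex[, 2], contig_len - ex[, 1])[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Classify alternative-splicing events between isoforms of one gene
#'
#' Pairwise structural comparison of each transcript model against the
#' designated primary transcript (longest spliced length, ties by id).
#' Events are cassette exons, alternative donor/acceptor sites (signed shift
#' in nt, positive = exon extension relative to the primary), and intron
#' retention.  For single-event in-frame differences the peptide gained by
#' the variant is recovered by diffing the translated open reading frames.
#'
#' @param models named list of `gene_model`s on the same contig/strand.
#' @param contig the shared contig sequence.
#' @param primary id of the primary transcript; default picks the longest.
#' @return data.frame: transcript, kind, intron_index, shift_nt, in_frame,
#'   added_peptide.
#' @export
diff_isoforms <- function(models, contig, primary = NULL) {
  stopifnot(length(models) >= 1L)
  ctg <- unique(vapply(models, `[[`, "", "contig_id"))
  if (length(ctg) != 1L) stop("models lie on different contigs")
  if (length(unique(vapply(models, `[[`, "", "strand"))) != 1L)
    stop("models lie on different strands")
  if (is.null(primary)) primary <- primary_transcript(models)
  L <- nchar(as.character(contig))
  pm <- models[[primary]]
  pex <- sense_exons(pm, L)
  S <- if (pm$strand == "+") as.character(contig) else revcomp(as.character(contig))
  ptx <- paste(substring(S, pex[, 1] + 1L, pex[, 2]), collapse = "")
  out <- list()
  for (id in setdiff(names(models), primary)) {
    vex <- sense_exons(models[[id]], L)
    vtx <- paste(substring(S, vex[, 1] + 1L, vex[, 2]), collapse = "")
    ev <- classify_events(pex, vex)
    if (nrow(ev)) {
      ev$transcript <- id
      ev$added_peptide <- ""
      one_alt <- nrow(ev) == 1L && ev$kind[1] %in% c("alt_acceptor", "alt_donor")
      if (one_alt && ev$shift_nt[1] > 0L && ev$in_frame[1])
        ev$added_peptide[1] <- inserted_peptide(ptx, vtx)
      out[[id]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(transcript = character(), kind = character(),
                      intron_index = integer(), shift_nt = integer(),
                      in_frame = logical(), added_peptide = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("transcript", "kind", "intron_index", "shift_nt", "in_frame",
          "added_peptide")]
}

#' @rdname diff_isoforms
#' @export
primary_transcript <- function(models) {
  lens <- vapply(models, function(m) sum(m$exons[, 2] - m$exons[, 1]), 0L)
  ids <- names(models)
  ids[order(-lens, ids)][1]
}

classify_events <- function(pex, vex) {
  ev <- data.frame(kind = character(), intron_index = integer(),
                   shift_nt = integer(), in_frame = logical(),
                   stringsAsFactors = FALSE)
  pints <- if (nrow(pex) > 1L)
    cbind(pex[-nrow(pex), 2], pex[-1L, 1]) else matrix(0L, 0L, 2L)
  overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
  # cassette exons: exon of one model untouched by every exon of the other
  for (i in seq_len(nrow(vex))) {
    if (!any(apply(pex, 1L, overlaps, b = vex[i, ]))) {
      idx <- which(pints[, 1] <= vex[i, 1] & pints[, 2] >= vex[i, 2])
      ev <- rbind(ev, data.frame(kind = "cassette_exon",
                                 intron_index = if (length(idx)) idx[1] else NA_integer_,
                                 shift_nt = vex[i, 2] - vex[i, 1],
                                 in_frame = (vex[i, 2] - vex[i, 1]) %% 3L == 0L,
                                 stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(nrow(pex))) {
    if (!any(apply(vex, 1L, overlaps, b = pex[i, ]))) {
      ev <- rbind(ev, data.frame(kind = "cassette_exon",
                                 intron_index = max(i - 1L, 1L),
                                 shift_nt = -(pex[i, 2] - pex[i, 1]),
                                 in_frame = (pex[i, 2] - pex[i, 1]) %% 3L == 0L,
                                 stringsAsFactors = FALSE))
    }
  }
  # matched (overlapping) exons: boundary shifts and retained introns
  for (i in seq_len(nrow(vex))) {
    js <- which(apply(pex, 1L, overlaps, b = vex[i, ]))
    if (length(js) == 1L) {
      j <- js
      if (vex[i, 1] != pex[j, 1] && j > 1L) {
        shift <- pex[j, 1] - vex[i, 1]   # + = variant acceptor upstream
        ev <- rbind(ev, data.frame(kind = "alt_acceptor", intron_index = j - 1L,
                                   shift_nt = shift,
                                   in_frame = shift %% 3L == 0L,
                                   stringsAsFactors = FALSE))
      }
      if (vex[i, 2] != pex[j, 2] && j < nrow(pex)) {
        shift <- vex[i, 2] - pex[j, 2]   # + = variant donor downstream
        ev <- rbind(ev, data.frame(kind = "alt_donor", intron_index = j,
                                   shift_nt = shift,
                                   in_frame = shift %% 3L == 0L,
                                   stringsAsFactors = FALSE))
      }
    } else if (length(js) > 1L) {
      ev <- rbind(ev, data.frame(kind = "intron_retention",
                                 intron_index = js[1],
                                 shift_nt = pex[js[2], 1] - pex[js[1], 2],
                                 in_frame = (pex[js[2], 1] - pex[js[1], 2]) %% 3L == 0L,
                                 stringsAsFactors = FALSE))
    }
  }
  ev
}

# Longest-ORF translation of a transcript.
orf_translate <- function(tx) {
  best <- ""
  n <- nchar(tx)
  for (off in 0:2) {
    usable <- n - off
    usable <- usable - usable %% 3L
    if (usable < 3L) next
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(tx, off + 1L, off + usable)),
      if.fuzzy.codon = "X")))
    for (frag in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      mpos <- regexpr("M", frag, fixed = TRUE)
      if (mpos > 0L) {
        orf <- substring(frag, mpos)
        if (nchar(orf) > nchar(best)) best <- orf
      }
    }
  }
  best
}

# Residues present in the variant protein but not the primary (single
# contiguous insertion recovered by common prefix/suffix diff).
inserted_peptide <- function(primary_tx, variant_tx) {
  a <- orf_translate(primary_tx)
  b <- orf_translate(variant_tx)
  if (nchar(b) <= nchar(a)) return("")
  ar <- s2raw(a); br <- s2raw(b)
  na <- length(ar); nb <- length(br)
  pre <- 0L
  while (pre < na && ar[pre + 1L] == br[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < na - pre && ar[na - suf] == br[nb - suf]) suf <- suf + 1L
  substring(b, pre + 1L, nb - suf)
}

#' Enumerate the isoform space of independent splice features
#'
#' All `2^n` boolean combinations in deterministic binary-counting order
#' (the all-absent reference configuration first, the first feature the
#' most significant bit).
#'
#' @param features character vector of feature names.
#' @return data.frame with one logical column per feature, `2^n` rows.
#' @export
enumerate_isoforms <- function(features) {
  n <- length(features)
  total <- 2L^n
  if (n == 0L) return(data.frame(row.names = "x1")[1, , drop = FALSE])
  cols <- lapply(seq_len(n), function(j)
    as.logical(bitwAnd(seq_len(total) - 1L, bitwShiftL(1L, n - j)) > 0L))
  out <- as.data.frame(setNames(cols, features))
  rownames(out) <- paste0("x", seq_len(total))
  out
}

#' Feature-configuration table for observed transcripts
#'
#' Derives the gene's alternative-splicing features from the structural
#' comparison of every transcript against the primary, then marks each
#' transcript's configuration.  Cassette-exon features are named in genomic
#' order with letter suffixes (`exon<intron>a`, `exon<intron>b`, ...);
#' boundary features as `intron<i>_donor_ext` / `intron<i>_acceptor_ext`.
#'
#' @inheritParams diff_isoforms
#' @return data.frame of logicals, one row per transcript, one column per
#'   feature; attribute `duplicated_configs` counts transcripts sharing a
#'   configuration with an earlier one.
#' @export
config_table <- function(models, contig, primary = NULL) {
  if (is.null(primary)) primary <- primary_transcript(models)
  L <- nchar(as.character(contig))
  # collect features across transcripts
  feats <- list()   # name -> list(kind, key...)
  for (id in setdiff(names(models), primary)) {
    ev <- diff_isoforms(models[c(primary, id)], contig, primary = primary)
    for (r in seq_len(nrow(ev))) {
      kind <- ev$kind[r]
      if (kind == "cassette_exon") {
        vex <- sense_exons(models[[id]], L)
        pex <- sense_exons(models[[primary]], L)
        exset <- if (ev$shift_nt[r] > 0L) vex else pex
        ovl <- apply(if (ev$shift_nt[r] > 0L) pex else vex, 1L,
                     function(e) exset[, 1] < e[2] & e[1] < exset[, 2])
        cass <- exset[rowSums(matrix(ovl, nrow = nrow(exset))) == 0L, ,
                      drop = FALSE]
        for (cc in seq_len(nrow(cass))) {
          key <- paste0("cassette@", cass[cc, 1], "-", cass[cc, 2])
          feats[[key]] <- list(kind = "cassette", iv = cass[cc, ])
        }
      } else if (kind %in% c("alt_acceptor", "alt_donor")) {
        key <- sprintf("intron%d_%s_ext%+d", ev$intron_index[r],
                       sub("alt_", "", kind), ev$shift_nt[r])
        feats[[key]] <- list(kind = kind, intron = ev$intron_index[r],
                             shift = ev$shift_nt[r])
      } else {
        key <- sprintf("intron%d_retained", ev$intron_index[r])
        feats[[key]] <- list(kind = kind, intron = ev$intron_index[r])
      }
    }
  }
  # order cassette features genomically and give letter suffixes
  keys <- names(feats)
  cass_keys <- keys[vapply(feats, function(f) f$kind == "cassette", TRUE)]
  if (length(cass_keys)) {
    starts <- vapply(feats[cass_keys], function(f) f$iv[1], 0L)
    cass_keys <- cass_keys[order(starts)]
  }
  other_keys <- sort(setdiff(keys, cass_keys))
  ordered <- c(cass_keys, other_keys)
  pretty <- ordered
  if (length(cass_keys)) {
    pin <- vapply(feats[cass_keys], function(f) {
      pex <- sense_exons(models[[primary]], L)
      idx <- sum(pex[, 2] <= f$iv[1])
      idx
    }, 0L)
    pretty[seq_along(cass_keys)] <- paste0("exon", pin, letters[
      stats::ave(seq_along(cass_keys), pin, FUN = seq_along)])
  }
  pex <- sense_exons(models[[primary]], L)
  rows <- lapply(names(models), function(id) {
    vex <- sense_exons(models[[id]], L)
    vapply(ordered, function(key) {
      f <- feats[[key]]
      if (f$kind == "cassette") {
        any(vex[, 1] == f$iv[1] & vex[, 2] == f$iv[2])
      } else if (f$kind == "alt_acceptor") {
        j <- f$intron + 1L
        ref_start <- pex[j, 1]
        any(vex[, 1] == ref_start - f$shift)
      } else if (f$kind == "alt_donor") {
        j <- f$intron
        ref_end <- pex[j, 2]
        any(vex[, 2] == ref_end + f$shift)
      } else {
        any(vex[, 1] < pex[f$intron, 2] & vex[, 2] > pex[f$intron + 1L, 1])
      }
    }, logical(1))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  colnames(tab) <- pretty
  rownames(tab) <- names(models)
  key <- apply(tab, 1L, paste, collapse = "")
  attr(tab, "duplicated_configs") <- sum(duplicated(key))
  tab
}

#' Render a configuration table with X / - marks
#' @param tab output of [config_table()] (or [enumerate_isoforms()]).
#' @return character data.frame with "X" for present, "-" for absent.
#' @export
format_config_table <- function(tab) {
  out <- as.data.frame(lapply(tab, function(col) ifelse(col, "X", "-")),
                       check.names = FALSE)
  rownames(out) <- rownames(tab)
  out
}

#' Search a genomic locus for a (possibly diverged) exon
#'
#' Local alignment of the exon against the locus: as nucleotide
#' (match 2 / mismatch -3, gaps 5/2, both strands) or as protein against the
#' three-frame translations of both strands (BLOSUM62, 11/1).  A hit is
#' called when the local alignment covers at least `min_coverage` of the exon
#' and scores at least `min_score_frac` of the exon's self-alignment score;
#' otherwise the exon is reported absent (`NULL`).
#'
#' @param exon_seq exon sequence (nucleotide, even for protein-mode search).
#' @param genomic locus sequence.
#' @param as_protein search the translated exon against translated frames.
#' @param min_coverage,min_score_frac documented detection floor.
#' @return `NULL`, or a list with `interval` (0-based half-open, nucleotide
#'   coordinates on the plus strand of `genomic` for nucleotide searches;
#'   frame-local protein coordinates otherwise), `identity` (percent over
#'   alignment columns), `strand`, and `frame` (protein mode).
#' @export
find_missing_exon <- function(exon_seq, genomic, as_protein = FALSE,
                              min_coverage = 0.6, min_score_frac = 0.25) {
  exon_seq <- toupper(as.character(exon_seq))
  genomic <- toupper(as.character(genomic))
  if (!as_protein) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    self <- nchar(exon_seq) * 2
    best <- NULL
    for (strand in c("+", "-")) {
      g <- if (strand == "+") genomic else revcomp(genomic)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(exon_seq), Biostrings::DNAString(g),
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
        type = "local")
      if (is.null(best) || Biostrings::score(pa) > best$score)
        best <- list(pa = pa, strand = strand, score = Biostrings::score(pa),
                     glen = nchar(g))
    }
    cov <- IRanges::width(best$pa@pattern@range) / nchar(exon_seq)
    if (cov < min_coverage || best$score < min_score_frac * self) return(NULL)
    r <- best$pa@subject@range
    iv <- c(IRanges::start(r) - 1L, IRanges::end(r))
    if (best$strand == "-") iv <- c(best$glen - iv[2], best$glen - iv[1])
    list(interval = iv, identity = alignment_identity(best$pa),
         strand = best$strand)
  } else {
    pep <- orf_translate(exon_seq)
    if (!nzchar(pep)) pep <- translate_cds(exon_seq)
    mat <- blosum62_matrix()
    self <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), Biostrings::AAString(pep),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "local"))
    best <- NULL
    for (strand in c("+", "-")) {
      g <- if (strand == "+") genomic else revcomp(genomic)
      for (off in 0:2) {
        usable <- nchar(g) - off
        usable <- usable - usable %% 3L
        if (usable < 3L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(substr(g, off + 1L, off + usable)),
          if.fuzzy.codon = "X")))
        aa <- gsub("*", "X", aa, fixed = TRUE)
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(pep), Biostrings::AAString(aa),
          substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
          type = "local")
        if (is.null(best) || Biostrings::score(pa) > best$score)
          best <- list(pa = pa, strand = strand, frame = off,
                       score = Biostrings::score(pa))
      }
    }
    cov <- IRanges::width(best$pa@pattern@range) / nchar(pep)
    if (cov < min_coverage || best$score < min_score_frac * self) return(NULL)
    r <- best$pa@subject@range
    list(interval = c(IRanges::start(r) - 1L, IRanges::end(r)),
         identity = alignment_identity(best$pa),
         strand = best$strand, frame = best$frame)
  }
}

alignment_identity <- function(pa) {
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(x == y & x != "-") / length(x)
}
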