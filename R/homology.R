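#' Ortholog assignment and pairwise protein comparison
#'
#' Local search emulates a BLASTp workflow: optimal Smith-Waterman local
#' alignments (via [Biostrings::pairwiseAlignment]) scored with BLOSUM62 and
#' affine gaps 11/1, with bit scores and E-values from ungapped
#' Karlin-Altschul statistics.  Ortholog designation uses the reciprocal-best
#' hit passing a query-coverage and E-value threshold (defaults 95 % and
#' 1e-100).  Global identity tables use Needleman-Wunsch alignments.
#'
#' @name homology
NULL

ROBINSON_FREQS <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

# Ungapped Karlin-Altschul K; lambda is computed from the matrix, K is the
# published ungapped BLOSUM62 constant (the 1e-100 ortholog threshold sits
# far from any decision boundary this approximation could move).
KA_K <- 0.13

#' Karlin-Altschul lambda for a scoring matrix
#'
#' Solves sum_ij p_i p_j exp(lambda * s_ij) = 1 over the Robinson-Robinson
#' background frequencies.
#'
#' @param matrix substitution matrix with amino-acid dimnames.
#' @return lambda (nats per score unit).
#' @export
karlin_lambda <- function(matrix) {
  aa <- names(ROBINSON_FREQS)
  s <- matrix[aa, aa]
  p <- outer(ROBINSON_FREQS, ROBINSON_FREQS)
  f <- function(lam) sum(p * exp(lam * s)) - 1
  uniroot(f, c(1e-4, 5), tol = 1e-10)$root
}

#' Substitution matrices
#'
#' `blosum62_matrix()` returns the BLOSUM62 matrix shipped with Biostrings.
#' `gonnet_matrix()` returns the Gonnet-250 log-odds table (shipped as plain
#' text with the package) in its published units, under which the default
#' gap penalties 10 / 0.2 cost roughly four average identities per gap
#' opening.  Both matrices carry `X` and `*` rows/columns scoring 0 so
#' ambiguous residues never contribute.
#'
#' @param scale optional multiplier applied to the published Gonnet values.
#' @return numeric matrix with dimnames.
#' @export
gonnet_matrix <- function(scale = 1) {
  path <- system.file("extdata", "gonnet250.tab", package = "tsitescreen")
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  m <- m * scale
  pad_matrix(m)
}

#' @rdname gonnet_matrix
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  pad_matrix(e$BLOSUM62)
}

pad_matrix <- function(m) {
  for (extra in c("X", "*")) {
    if (!extra %in% rownames(m)) {
      m <- rbind(m, 0)
      m <- cbind(m, 0)
      rownames(m)[nrow(m)] <- extra
      colnames(m)[ncol(m)] <- extra
    } else {
      m[extra, ] <- 0
      m[, extra] <- 0
    }
  }
  m
}

#' Optimal local search of a query against a protein database
#'
#' One optimal Smith-Waterman alignment per subject; hits sorted by E-value
#' ascending, ties broken by subject id.  Query coverage is the fraction of
#' query residues inside the local alignment.
#'
#' @param query named character scalar or single-sequence `AAStringSet`.
#' @param db named character vector / `AAStringSet` of subjects.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (default 11/1, BLAST-like).
#' @return data.frame with columns query_id, subject_id, raw_score, bit_score,
#'   evalue, query_coverage, q_start, q_end, s_start, s_end, q_aln, s_aln.
#' @export
local_search <- function(query, db, matrix = blosum62_matrix(),
                         gap_open = 11, gap_extend = 1) {
  q <- as_named_chr(query)
  if (length(db) == 0L)
    return(empty_hits())
  d <- as_named_chr(db)
  lambda <- karlin_lambda(matrix)
  rows <- lapply(names(d), function(sid) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q[[1]]), Biostrings::AAString(d[[sid]]),
      substitutionMatrix = matrix, gapOpening = gap_open,
      gapExtension = gap_extend, type = "local")
    s <- Biostrings::score(pa)
    qr <- pa@pattern@range
    sr <- pa@subject@range
    bit <- (lambda * s - log(KA_K)) / log(2)
    ev <- nchar(q[[1]]) * nchar(d[[sid]]) * 2^(-bit)
    data.frame(query_id = names(q)[1], subject_id = sid, raw_score = s,
               bit_score = bit, evalue = ev,
               query_coverage = IRanges::width(qr) / nchar(q[[1]]),
               q_start = IRanges::start(qr), q_end = IRanges::end(qr),
               s_start = IRanges::start(sr), s_end = IRanges::end(sr),
               q_aln = as.character(Biostrings::alignedPattern(pa)),
               s_aln = as.character(Biostrings::alignedSubject(pa)),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             raw_score = numeric(), bit_score = numeric(), evalue = numeric(),
             query_coverage = numeric(), q_start = integer(),
             q_end = integer(), s_start = integer(), s_end = integer(),
             q_aln = character(), s_aln = character(),
             stringsAsFactors = FALSE)
}

as_named_chr <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named")
  as.list(x)
}

#' Search thresholds for ortholog designation
#' @param min_query_coverage minimum query coverage (default 0.95).
#' @param max_evalue maximum E-value (default 1e-100).
#' @export
search_thresholds <- function(min_query_coverage = 0.95, max_evalue = 1e-100) {
  stopifnot(min_query_coverage > 0, min_query_coverage <= 1, max_evalue > 0)
  list(min_query_coverage = min_query_coverage, max_evalue = max_evalue)
}

#' Assign orthologs by (reciprocal) best local hit
#'
#' For every query, the best subject passing both thresholds; with
#' `reciprocal = TRUE` (default) the assignment is kept only when the
#' reference's best hit back into the queries is that query.
#'
#' @param queries,refs named character vectors / `AAStringSet`s.
#' @param thresholds from [search_thresholds()].
#' @param reciprocal require best-hit reciprocity (default TRUE).
#' @inheritParams local_search
#' @return named character vector: for each query id, the assigned reference
#'   id or `NA`.
#' @export
assign_orthologs <- function(queries, refs,
                             thresholds = search_thresholds(),
                             reciprocal = TRUE,
                             matrix = blosum62_matrix(),
                             gap_open = 11, gap_extend = 1) {
  qs <- as_named_chr(queries)
  rs <- as_named_chr(refs)
  best_of <- function(one, pool) {
    hits <- local_search(one, unlist(pool), matrix, gap_open, gap_extend)
    hits <- hits[hits$query_coverage >= thresholds$min_query_coverage &
                 hits$evalue <= thresholds$max_evalue, , drop = FALSE]
    if (nrow(hits) == 0L) NA_character_ else hits$subject_id[1]
  }
  out <- setNames(rep(NA_character_, length(qs)), names(qs))
  back <- new.env()
  for (qid in sort(names(qs))) {
    rid <- best_of(qs[qid], rs)
    if (is.na(rid)) next
    if (reciprocal) {
      key <- rid
      if (is.null(back[[key]])) back[[key]] <- best_of(rs[rid], qs)
      if (is.na(back[[key]]) || back[[key]] != qid) next
    }
    out[qid] <- rid
  }
  out
}

#' Global identity and divergence of two proteins
#'
#' Needleman-Wunsch global alignment.  Percent identity is 100 x identical
#' columns / alignment columns.  Divergence is reported as
#' 100 x (substitutions + indel events) / ungapped aligned columns -- an
#' explicitly approximate companion statistic, never used for decisions.
#'
#' @param a,b named single sequences.
#' @inheritParams local_search
#' @return data.frame with id_a, id_b, percent_identity, divergence, columns.
#' @export
global_identity <- function(a, b, matrix = blosum62_matrix(),
                            gap_open = 11, gap_extend = 1) {
  a <- as_named_chr(a); b <- as_named_chr(b)
  if (!nzchar(a[[1]]) || !nzchar(b[[1]])) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a[[1]]), Biostrings::AAString(b[[1]]),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ident <- sum(x == y & x != "-")
  cols <- length(x)
  gap <- x == "-" | y == "-"
  subs <- sum(!gap & x != y)
  indel_events <- count_runs(gap)
  ungapped <- sum(!gap)
  data.frame(id_a = names(a)[1], id_b = names(b)[1],
             percent_identity = 100 * ident / cols,
             divergence = 100 * (subs + indel_events) / ungapped,
             columns = cols, stringsAsFactors = FALSE)
}

count_runs <- function(flag) {
  if (!any(flag)) return(0L)
  sum(diff(c(FALSE, flag)) == 1L)
}

#' Pairwise identity table for two sequence panels
#'
#' @param set_a,set_b named sequence sets.
#' @inheritParams local_search
#' @return long-format data.frame of [global_identity()] rows.
#' @export
identity_table <- function(set_a, set_b, matrix = blosum62_matrix(),
                           gap_open = 11, gap_extend = 1) {
  a <- as_named_chr(set_a); b <- as_named_chr(set_b)
  do.call(rbind, lapply(names(a), function(i)
    do.call(rbind, lapply(names(b), function(j)
      global_identity(a[i], b[j], matrix, gap_open, gap_extend)))))
}

#' Merge two protein fragments with an exact suffix/prefix overlap
#'
#' If a suffix of `frag_a` equals a prefix of `frag_b` exactly and is at least
#' `min_overlap` residues, returns the concatenation with the (maximal)
#' overlap counted once; otherwise `NULL`.
#'
#' @param frag_a,frag_b character scalars (proteins).
#' @param min_overlap minimum overlap length in residues.
#' @return merged character scalar with attribute `overlap`, or `NULL`.
#' @export
merge_fragments <- function(frag_a, frag_b, min_overlap = 20L) {
  frag_a <- as.character(frag_a)[1]; frag_b <- as.character(frag_b)[1]
  na <- nchar(frag_a); nb <- nchar(frag_b)
  if (min(na, nb) < min_overlap) return(NULL)
  for (k in seq(min(na, nb), min_overlap)) {
    if (substring(frag_a, na - k + 1L, na) == substring(frag_b, 1L, k)) {
      out <- paste0(frag_a, substring(frag_b, k + 1L))
      attr(out, "overlap") <- k
      return(out)
    }
  }
  NULL
}

#' Residues of one sequence deleted relative to another
#'
#' Total residues of `b` aligned opposite gaps in `a` under a global
#' alignment -- e.g. the span of a genomic deletion seen from the intact
#' ortholog.
#'
#' @param a,b named single protein sequences.
#' @inheritParams local_search
#' @return integer count.
#' @export
deletion_span <- function(a, b, matrix = blosum62_matrix(),
                          gap_open = 11, gap_extend = 1) {
  a <- as_named_chr(a); b <- as_named_chr(b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a[[1]]), Biostrings::AAString(b[[1]]),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(x == "-" & y != "-")
}
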