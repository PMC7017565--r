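#' PROSITE-pattern engine and channel-feature catalog
#'
#' Supports the PROSITE pattern grammar used by ScanProsite for pattern
#' entries: residue letters, `x` (any residue), `[...]` residue sets, `{...}`
#' negated sets, `(n)` / `(n,m)` repeat counts, `-` separators, optional `<`
#' / `>` anchors, and an optional trailing period.  Negated sets accept any
#' residue not listed (so `X` passes a negated set but fails a positive
#' set).  All overlapping matches are reported, ascending start; a greedy
#' non-overlap mode is available behind a flag.
#'
#' @name motifs
NULL

#' Parse a PROSITE pattern
#'
#' @param raw pattern string, e.g. `"N-{P}-[ST]-{P}"` or `"C-x(13)-C"`.
#' @param pattern_id,name optional identifiers carried into hits.
#' @return object of class `prosite_pattern` with compiled elements and
#'   width range.
#' @export
parse_pattern <- function(raw, pattern_id = raw, name = pattern_id) {
  txt <- gsub("\\s", "", raw)
  txt <- sub("\\.$", "", txt)
  anchor_start <- grepl("^<", txt)
  anchor_end <- grepl(">$", txt)
  txt <- sub("^<", "", txt)
  txt <- sub(">$", "", txt)
  if (!nzchar(txt)) stop("empty pattern")
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  rx <- "^(?:([A-Za-z])|\\[([A-Z]+)\\]|\\{([A-Z]+)\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$"
  elements <- lapply(toks, function(tok) {
    m <- regmatches(tok, regexec(rx, tok))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("unsupported PROSITE construct: '", tok, "'")
    # regexec groups: 2 = single letter or x, 3 = [set], 4 = {set}, 5/6 = n,m
    set <- NULL
    negated <- FALSE
    if (nzchar(m[2])) {
      if (toupper(m[2]) != "X") set <- toupper(m[2])
    } else if (nzchar(m[3])) {
      set <- strsplit(m[3], "")[[1]]
    } else {
      set <- strsplit(m[4], "")[[1]]
      negated <- TRUE
    }
    lo <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    hi <- if (nzchar(m[6])) as.integer(m[6]) else lo
    if (hi < lo) stop("invalid repeat count in '", tok, "'")
    list(set = set, negated = negated, min = lo, max = hi)
  })
  wmin <- sum(vapply(elements, `[[`, 0L, "min"))
  wmax <- sum(vapply(elements, `[[`, 0L, "max"))
  structure(list(pattern_id = pattern_id, name = name, raw = raw,
                 elements = elements, width_min = wmin, width_max = wmax,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "prosite_pattern")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("<prosite_pattern> %s: %s (width %d%s)\n", x$pattern_id, x$raw,
              x$width_min,
              if (x$width_max > x$width_min) paste0("-", x$width_max) else ""))
  invisible(x)
}

element_ok <- function(el, ch) {
  if (is.null(el$set)) return(TRUE)
  hit <- ch %in% el$set
  if (el$negated) !hit else hit
}

# greedy match of elements starting at position i (1-based); returns match
# length or NA.
match_here <- function(elements, chars, i) {
  if (length(elements) == 0L) return(0L)
  el <- elements[[1]]
  rest <- elements[-1]
  for (cnt in seq(el$max, el$min)) {
    if (i + cnt - 1L > length(chars)) next
    ok <- cnt == 0L ||
      all(vapply(chars[i:(i + cnt - 1L)], element_ok, logical(1), el = el))
    if (ok) {
      sub <- match_here(rest, chars, i + cnt)
      if (!is.na(sub)) return(cnt + sub)
    }
  }
  NA_integer_
}

#' Scan a sequence with a PROSITE pattern
#'
#' @param pattern a `prosite_pattern` (or raw pattern string).
#' @param seq named protein sequence (character scalar, named, or
#'   `AAStringSet` of length 1).
#' @param overlapping report all overlapping matches (default, ScanProsite
#'   behavior); `FALSE` = greedy non-overlapping.
#' @return data.frame: pattern_id, seq_id, start (1-based), matched.
#' @export
scan_prosite <- function(pattern, seq, overlapping = TRUE) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  sq <- as_named_chr(seq)
  chars <- strsplit(sq[[1]], "")[[1]]
  n <- length(chars)
  fixed <- pattern$width_min == pattern$width_max &&
    all(vapply(pattern$elements, function(e) e$min == e$max, TRUE))
  starts <- integer()
  lens <- integer()
  if (n >= pattern$width_min) {
    if (fixed) {
      w <- pattern$width_min
      cand <- rep(TRUE, n - w + 1L)
      off <- 0L
      for (el in pattern$elements) {
        for (r in seq_len(el$min)) {
          idx <- seq_len(n - w + 1L) + off
          if (!is.null(el$set)) {
            hit <- chars[idx] %in% el$set
            cand <- cand & (if (el$negated) !hit else hit)
          }
          off <- off + 1L
        }
      }
      starts <- which(cand)
      lens <- rep(w, length(starts))
    } else {
      i <- 1L
      while (i <= n - pattern$width_min + 1L) {
        len <- match_here(pattern$elements, chars, i)
        if (!is.na(len)) {
          starts <- c(starts, i)
          lens <- c(lens, len)
        }
        i <- i + 1L
      }
    }
  }
  if (pattern$anchor_start) {
    keep <- starts == 1L
    starts <- starts[keep]; lens <- lens[keep]
  }
  if (pattern$anchor_end) {
    keep <- starts + lens - 1L == n
    starts <- starts[keep]; lens <- lens[keep]
  }
  if (!overlapping && length(starts)) {
    keep <- logical(length(starts))
    last_end <- 0L
    for (j in seq_along(starts)) {
      if (starts[j] > last_end) {
        keep[j] <- TRUE
        last_end <- starts[j] + lens[j] - 1L
      }
    }
    starts <- starts[keep]; lens <- lens[keep]
  }
  if (!length(starts))
    return(data.frame(pattern_id = character(), seq_id = character(),
                      start = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  data.frame(pattern_id = rep(pattern$pattern_id, length(starts)),
             seq_id = rep(names(sq)[1], length(starts)),
             start = starts,
             matched = substring(sq[[1]], starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Read a PROSITE-style flat-text pattern catalog
#'
#' Records of the form `ID <name>; PATTERN.` / `AC <accession>;` /
#' `PA <pattern>.` separated by `//`.  The package ships the six canonical
#' post-translational-modification patterns used for phenolamine-receptor
#' annotation (N-glycosylation, CK2 and PKC phosphorylation,
#' N-myristoylation, amidation, cAMP/cGMP kinase phosphorylation).
#'
#' @param path flat file (default: shipped catalog).
#' @return named list of `prosite_pattern` objects (names = accessions).
#' @export
read_pattern_catalog <- function(path = system.file("extdata",
                                                    "ptm_patterns.dat",
                                                    package = "tsitescreen")) {
  lines <- readLines(path)
  out <- list()
  id <- ac <- pa <- NULL
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) id <- sub(";.*$", "", sub("^ID\\s+", "", ln))
    if (grepl("^AC\\s", ln)) ac <- sub(";.*$", "", sub("^AC\\s+", "", ln))
    if (grepl("^PA\\s", ln)) pa <- paste0(if (is.null(pa)) "" else pa,
                                          sub("^PA\\s+", "", ln))
    if (grepl("^//", ln)) {
      if (!is.null(pa)) out[[ac]] <- parse_pattern(sub("\\.$", "", pa),
                                                   pattern_id = ac, name = id)
      id <- ac <- pa <- NULL
    }
  }
  out
}

#' Scan a protein with every pattern of a catalog
#' @param protein named protein sequence.
#' @param catalog list from [read_pattern_catalog()].
#' @inheritParams scan_prosite
#' @return data.frame of hits with a `name` column.
#' @export
scan_catalog <- function(protein, catalog = read_pattern_catalog(),
                         overlapping = TRUE) {
  rows <- lapply(catalog, function(p) {
    h <- scan_prosite(p, protein, overlapping)
    if (nrow(h)) h$name <- p$name
    h
  })
  rows <- rows[vapply(rows, nrow, 0L) > 0L]
  if (!length(rows))
    return(data.frame(pattern_id = character(), seq_id = character(),
                      start = integer(), matched = character(),
                      name = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start), ]
}

#' Channel-feature catalog
#'
#' Diagnostic sequence features of insecticide-target channels: the DEEA /
#' DEKA sodium-channel selectivity filters, the MFL fast-inactivation motif,
#' the cys-loop `C-x(13)-C` signature, the pore selectivity triplet
#' immediately preceding TM2 in cys-loop subunits (GEK in nAChRs; PAR / ADR /
#' SAR in chloride-channel subunits, with KDR a known divergent variant), and
#' the DRY activation motif at the end of TM3 in phenolamine GPCRs.
#'
#' @return data.frame: feature_id, pattern, anchor (`absolute`,
#'   `before_annotation`, `at_annotation_end`), annotation_key, window,
#'   description.
#' @export
channel_features <- function() {
  data.frame(
    feature_id = c("selectivity_filter_DEKA", "selectivity_filter_DEEA",
                   "fast_inactivation_MFL", "cys_loop", "pore_filter_GEK",
                   "pore_filter_PAR", "pore_filter_ADR", "pore_filter_SAR",
                   "gpcr_DRY"),
    pattern = c("D-E-K-A", "D-E-E-A", "M-F-L", "C-x(13)-C", "G-E-K",
                "P-A-R", "A-D-R", "S-A-R", "D-R-Y"),
    anchor = c("absolute", "absolute", "absolute", "absolute",
               rep("before_annotation", 4L), "at_annotation_end"),
    annotation_key = c(NA, NA, NA, NA, "TM2", "TM2", "TM2", "TM2", "TM3"),
    window = c(NA, NA, NA, NA, 10L, 10L, 10L, 10L, 5L),
    description = c("sodium-channel ion-selectivity filter",
                    "SC1-type cation selectivity filter",
                    "fast inactivation particle",
                    "cys-loop disulfide signature",
                    "cation pore filter preceding TM2",
                    "anion pore filter preceding TM2 (RDL/HisCl type)",
                    "anion pore filter preceding TM2 (GRD type)",
                    "anion pore filter preceding TM2 (LCCH3 type)",
                    "GPCR activation motif at the TM3 boundary"),
    stringsAsFactors = FALSE)
}

#' Evaluate channel features on a protein
#'
#' Absolute features are scanned over the whole protein (`present` /
#' `absent`).  Annotation-relative features are evaluated in the stated
#' window: pore filters in the `window` residues immediately N-terminal to
#' the annotation start, reporting `present` when the expected motif occurs
#' there, otherwise `variant` with the triplet immediately preceding the
#' annotation as the observed residues; features whose annotation is missing
#' are `not_evaluable`.
#'
#' @param protein named protein sequence.
#' @param annotations named list of 1-based closed protein intervals
#'   (`list(TM2 = c(start, end), ...)`).
#' @param features data.frame like [channel_features()] (rows may be
#'   subset by the caller).
#' @return data.frame: feature_id, status, observed, position.
#' @export
check_features <- function(protein, annotations = list(),
                           features = channel_features()) {
  sq <- as_named_chr(protein)
  s <- sq[[1]]
  rows <- lapply(seq_len(nrow(features)), function(r) {
    f <- features[r, ]
    pat <- parse_pattern(f$pattern, pattern_id = f$feature_id)
    if (f$anchor == "absolute") {
      hits <- scan_prosite(pat, setNames(s, names(sq)[1]))
      if (nrow(hits))
        return(data.frame(feature_id = f$feature_id, status = "present",
                          observed = hits$matched[1], position = hits$start[1],
                          stringsAsFactors = FALSE))
      return(data.frame(feature_id = f$feature_id, status = "absent",
                        observed = NA_character_, position = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    key <- f$annotation_key
    if (is.null(annotations[[key]]))
      return(data.frame(feature_id = f$feature_id, status = "not_evaluable",
                        observed = NA_character_, position = NA_integer_,
                        stringsAsFactors = FALSE))
    iv <- annotations[[key]]
    if (f$anchor == "before_annotation") {
      lo <- max(1L, iv[1] - f$window)
      hi <- iv[1] - 1L
    } else {  # at_annotation_end
      lo <- max(1L, iv[2] - f$window)
      hi <- min(nchar(s), iv[2] + f$window)
    }
    if (hi < lo)
      return(data.frame(feature_id = f$feature_id, status = "not_evaluable",
                        observed = NA_character_, position = NA_integer_,
                        stringsAsFactors = FALSE))
    winseq <- substring(s, lo, hi)
    hits <- scan_prosite(pat, setNames(winseq, names(sq)[1]))
    if (nrow(hits))
      return(data.frame(feature_id = f$feature_id, status = "present",
                        observed = hits$matched[1],
                        position = lo + hits$start[1] - 1L,
                        stringsAsFactors = FALSE))
    w <- pat$width_min
    obs_lo <- if (f$anchor == "before_annotation") max(1L, iv[1] - w) else lo
    observed <- substring(s, obs_lo, obs_lo + w - 1L)
    data.frame(feature_id = f$feature_id,
               status = if (f$anchor == "before_annotation") "variant"
                        else "absent",
               observed = if (f$anchor == "before_annotation") observed
                          else NA_character_,
               position = if (f$anchor == "before_annotation") obs_lo
                          else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Propose transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Sliding-window mean hydropathy; contiguous runs of window centers above
#' the threshold are reported as candidate TM segments.  A helper only --
#' proposed segments are never auto-trusted as annotations.
#'
#' @param protein named protein sequence.
#' @param window window size (default 19).
#' @param threshold mean-hydropathy threshold (default 1.6).
#' @return data.frame: start, end (1-based closed), peak.
#' @export
kyte_doolittle_tm <- function(protein, window = 19L, threshold = 1.6) {
  sq <- as_named_chr(protein)
  ch <- strsplit(sq[[1]], "")[[1]]
  h <- KD_HYDROPATHY[ch]
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < window)
    return(data.frame(start = integer(), end = integer(), peak = numeric()))
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  centers <- seq_along(means) + (window - 1L) %/% 2L
  above <- means > threshold
  if (!any(above))
    return(data.frame(start = integer(), end = integer(), peak = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = pmax(1L, centers[starts[keep]] - (window - 1L) %/% 2L),
             end = pmin(n, centers[ends[keep]] + (window - 1L) %/% 2L),
             peak = vapply(keep, function(k)
               max(means[starts[k]:ends[k]]), 0))
}
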