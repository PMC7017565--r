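# Independent oracles and small fixture builders used across test files.

# Exhaustive local-alignment oracle: enumerates every set of aligned residue
# pairs (monotone in both sequences) and charges affine gaps between
# consecutive pairs; terminal gaps are free (local alignment).  The empty
# alignment scores 0.  Independent of any dynamic-programming recursion.
sw_enumeration_oracle <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av)
  nb <- length(bv)
  best <- 0
  for (k in seq_len(min(na, nb))) {
    subA <- utils::combn(na, k)
    subB <- utils::combn(nb, k)
    for (ia in seq_len(ncol(subA))) {
      ii <- subA[, ia]
      base_ga <- diff(ii) - 1L
      for (ib in seq_len(ncol(subB))) {
        jj <- subB[, ib]
        sc <- sum(mat[cbind(av[ii], bv[jj])])
        if (k > 1L) {
          gb <- diff(jj) - 1L
          sc <- sc - sum(ifelse(base_ga > 0, gap_open + gap_extend * base_ga, 0)) -
                sum(ifelse(gb > 0, gap_open + gap_extend * gb, 0))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Independent PROSITE oracle: translate the pattern to a PCRE and find all
# overlapping matches with a capturing lookahead.
prosite_regex_oracle <- function(raw, seq) {
  txt <- gsub("\\s", "", sub("\\.$", "", raw))
  anchor_start <- grepl("^<", txt)
  anchor_end <- grepl(">$", txt)
  txt <- sub("^<", "", sub(">$", "", txt))
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^(?:([A-Za-z])|\\[([A-Z]+)\\]|\\{([A-Z]+)\\})(?:\\((\\d+)(?:,(\\d+))?\\))?$",
      tok))[[1]]
    core <- if (nzchar(m[2])) {
      if (toupper(m[2]) == "X") "." else m[2]
    } else if (nzchar(m[3])) {
      paste0("[", m[3], "]")
    } else {
      paste0("[^", m[4], "]")
    }
    rep_suffix <- if (nzchar(m[5]) && nzchar(m[6])) {
      sprintf("{%s,%s}", m[5], m[6])
    } else if (nzchar(m[5])) {
      sprintf("{%s}", m[5])
    } else ""
    paste0(core, rep_suffix)
  }, "")
  rx <- paste0(if (anchor_start) "^" else "", paste(parts, collapse = ""),
               if (anchor_end) "$" else "")
  mm <- gregexpr(paste0("(?=(", rx, "))"), seq, perl = TRUE)[[1]]
  if (mm[1] == -1) {
    return(data.frame(start = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(mm, "capture.length")[, 1]
  data.frame(start = as.integer(mm),
             matched = substring(seq, mm, mm + len - 1L),
             stringsAsFactors = FALSE)
}

random_aa_string <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force 4-taxon topology oracle: least-squares edge fit for each of
# the three unrooted topologies; returns the sister pair of the best fit.
four_taxon_oracle <- function(dm) {
  labs <- rownames(dm)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  sse <- vapply(splits, function(pr) {
    other <- setdiff(1:4, pr)
    a <- pr[1]; b <- pr[2]; c <- other[1]; d <- other[2]
    # path-length model with internal edge m and pendant edges ea..ed
    X <- rbind(c(1, 1, 0, 0, 0),   # d(a,b)
               c(1, 0, 1, 0, 1),   # d(a,c)
               c(1, 0, 0, 1, 1),   # d(a,d)
               c(0, 1, 1, 0, 1),   # d(b,c)
               c(0, 1, 0, 1, 1),   # d(b,d)
               c(0, 0, 1, 1, 0))   # d(c,d)
    y <- c(dm[a, b], dm[a, c], dm[a, d], dm[b, c], dm[b, d], dm[c, d])
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }, 0)
  pr <- splits[[which.min(sse)]]
  sort(labs[pr])
}

# sister pair of leaf `x` and its cherry partner in an unrooted 4-taxon
# nj_tree / phylo
sister_pair <- function(tree) {
  ph <- if (inherits(tree, "nj_tree")) tsitescreen::as_phylo(tree) else tree
  ph <- ape::unroot(ph)
  # in an unrooted 4-taxon tree the two cherries hang off one internal edge
  tips <- ph$tip.label
  for (pair in utils::combn(tips, 2, simplify = FALSE)) {
    mrca_ok <- ape::is.monophyletic(ph, pair)
    if (mrca_ok) return(sort(pair))
  }
  sort(tips[1:2])
}

# distance between two leaves along the tree (sum of branch lengths)
tree_path_length <- function(tree, from, to) {
  ph <- if (inherits(tree, "nj_tree")) tsitescreen::as_phylo(tree) else tree
  ape::cophenetic.phylo(ph)[from, to]
}
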