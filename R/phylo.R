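#' Progressive alignment, distances, neighbor-joining and bootstrap
#'
#' The tree machinery mirrors a MEGA-style protein workflow: progressive
#' multiple alignment under the Gonnet-250 matrix with gap penalties 10 /
#' 0.2, p-distances (or Poisson distances) with pairwise deletion of gap
#' sites, Saitou-Nei neighbor-joining with deterministic tie-breaking, and
#' nonparametric bootstrap supports from column resampling.
#'
#' @name phylo
NULL

#' Alignment parameters
#' @param matrix_name `"Gonnet"` (default) or `"BLOSUM62"`.
#' @param gap_open,gap_extend affine penalties (defaults 10 / 0.2).
#' @export
align_params <- function(matrix_name = "Gonnet", gap_open = 10,
                         gap_extend = 0.2) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  mat <- switch(matrix_name,
                Gonnet = gonnet_matrix(),
                BLOSUM62 = blosum62_matrix(),
                stop("unknown matrix: ", matrix_name))
  list(matrix_name = matrix_name, matrix = mat, gap_open = gap_open,
       gap_extend = gap_extend)
}

PROFILE_ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "-")

seq_profile <- function(block) {
  # block: character matrix (rows = sequences, cols = alignment columns)
  nc <- ncol(block)
  f <- matrix(0, nrow = length(PROFILE_ALPHA), ncol = nc,
              dimnames = list(PROFILE_ALPHA, NULL))
  for (j in seq_len(nc)) {
    tab <- table(factor(block[, j], levels = PROFILE_ALPHA))
    f[, j] <- tab / sum(tab)
  }
  f
}

#' Progressive multiple sequence alignment
#'
#' UPGMA guide tree from pairwise global-alignment p-distances; profiles are
#' merged in guide-tree order with an affine-gap profile-profile aligner.
#' Sequences are canonically sorted by name first, so the result is invariant
#' to input order.
#'
#' @param seqs named character vector / `AAStringSet` (>= 2 sequences).
#' @param params from [align_params()].
#' @return named character vector of equal-length aligned sequences, with
#'   the guide tree (`hclust`) as attribute `guide`.
#' @export
progressive_msa <- function(seqs, params = align_params()) {
  s <- unlist(as_named_chr(seqs))
  if (length(s) < 2L) stop("progressive alignment needs at least 2 sequences")
  s <- s[order(names(s))]
  n <- length(s)
  m <- params$matrix
  if (!"-" %in% rownames(m)) {
    m <- rbind(m, 0)
    m <- cbind(m, 0)
    rownames(m)[nrow(m)] <- colnames(m)[ncol(m)] <- "-"
  }
  sub <- m[PROFILE_ALPHA, PROFILE_ALPHA]
  sub["-", ] <- 0
  sub[, "-"] <- 0
  # guide distances from pairwise global alignments
  D <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(s[[i]]), Biostrings::AAString(s[[j]]),
        substitutionMatrix = params$matrix, gapOpening = params$gap_open,
        gapExtension = params$gap_extend, type = "global")
      D[i, j] <- D[j, i] <- 1 - alignment_identity(pa) / 100
    }
  }
  if (n == 2L) {
    hc <- NULL
    blocks <- align_blocks(matrix(strsplit(s[[1]], "")[[1]], nrow = 1,
                                  dimnames = list(names(s)[1], NULL)),
                           matrix(strsplit(s[[2]], "")[[1]], nrow = 1,
                                  dimnames = list(names(s)[2], NULL)),
                           sub, params$gap_open, params$gap_extend)
    out <- apply(blocks, 1L, paste, collapse = "")
    return(structure(out, guide = NULL))
  }
  hc <- hclust(as.dist(D), method = "average")
  blocks <- lapply(seq_len(n), function(i)
    matrix(strsplit(s[[i]], "")[[1]], nrow = 1,
           dimnames = list(names(s)[i], NULL)))
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(idx) if (idx < 0) blocks[[-idx]] else merged[[idx]]
    merged[[k]] <- align_blocks(pick(hc$merge[k, 1]), pick(hc$merge[k, 2]),
                                sub, params$gap_open, params$gap_extend)
  }
  final <- merged[[nrow(hc$merge)]]
  final <- final[order(rownames(final)), , drop = FALSE]
  out <- apply(final, 1L, paste, collapse = "")
  structure(out, guide = hc)
}

align_blocks <- function(a, b, sub, gap_open, gap_extend) {
  fa <- seq_profile(a)
  fb <- seq_profile(b)
  path <- profile_align_cpp(fa, fb, sub, gap_open, gap_extend)
  nc <- length(path$a)
  out <- matrix("-", nrow = nrow(a) + nrow(b), ncol = nc,
                dimnames = list(c(rownames(a), rownames(b)), NULL))
  ia <- path$a > 0
  ib <- path$b > 0
  out[seq_len(nrow(a)), ia] <- a[, path$a[ia], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), ib] <- b[, path$b[ib], drop = FALSE]
  out
}

#' Pairwise distances from a multiple alignment
#'
#' Pairwise deletion: for each pair, only columns where both sequences carry
#' a residue are compared.  `p_distance` = mismatches / compared columns;
#' `poisson` = -ln(1 - p).
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return symmetric labeled distance matrix.
#' @export
msa_distances <- function(msa, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  msa <- unlist(as_named_chr(msa))
  chars <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(chars)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) stop("no comparable columns between ", names(msa)[i],
                         " and ", names(msa)[j])
      p <- mean(chars[i, ok] != chars[j, ok])
      d <- if (model == "poisson") {
        if (p >= 1) stop("saturated Poisson distance")
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion.  Ties in Q (within 1e-12)
#' are broken by the lexicographically smallest pair of cluster labels (a
#' cluster is labeled by its smallest member).  Negative branch-length
#' estimates are clamped to zero (attribute `clamped` counts them).
#'
#' @param dm symmetric labeled distance matrix (>= 3 taxa).
#' @return an `nj_tree`: nested-list unrooted tree with a trifurcating root,
#'   edge lengths, and leaf labels.
#' @export
neighbor_joining <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  nodes <- lapply(labels, function(l) list(label = l, children = NULL,
                                           edge_length = NA_real_))
  minlab <- labels
  d <- dm
  clamped <- 0L
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(d[active, active])
    best <- NULL
    for (ii in seq_len(m - 1L)) {
      for (jj in seq(ii + 1L, m)) {
        i <- active[ii]; j <- active[jj]
        q <- (m - 2) * d[i, j] - r[ii] - r[jj]
        pair <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(q = q, i = i, j = j, ii = ii, jj = jj, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    dij <- d[i, j]
    li <- dij / 2 + (r[best$ii] - r[best$jj]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { clamped <- clamped + 1L; lj <- min(dij, lj - li); li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- min(dij, li - lj); lj <- 0 }
    ni <- nodes[[i]]; ni$edge_length <- li
    njn <- nodes[[j]]; njn$edge_length <- lj
    new <- list(label = NA_character_, children = list(ni, njn),
                edge_length = NA_real_)
    # distances to the new node
    others <- setdiff(active, c(i, j))
    dnew <- numeric(nrow(d))
    for (k in others) dnew[k] <- (d[i, k] + d[j, k] - dij) / 2
    d <- rbind(cbind(d, dnew[seq_len(ncol(d))]), c(dnew, 0))
    idx <- nrow(d)
    nodes[[idx]] <- new
    minlab[idx] <- min(minlab[i], minlab[j])
    active <- c(others, idx)
  }
  i <- active[1]; j <- active[2]; k <- active[3]
  li <- (d[i, j] + d[i, k] - d[j, k]) / 2
  lj <- (d[i, j] + d[j, k] - d[i, k]) / 2
  lk <- (d[i, k] + d[j, k] - d[i, j]) / 2
  kids <- list()
  for (nn in list(list(i, li), list(j, lj), list(k, lk))) {
    node <- nodes[[nn[[1]]]]
    ln <- nn[[2]]
    if (ln < 0) { clamped <- clamped + 1L; ln <- 0 }
    node$edge_length <- ln
    kids[[length(kids) + 1L]] <- node
  }
  ord <- order(vapply(list(kids[[1]], kids[[2]], kids[[3]]),
                      node_minlab, ""))
  structure(list(label = NA_character_, children = kids[ord],
                 edge_length = NA_real_),
            class = "nj_tree", clamped = clamped)
}

node_minlab <- function(node) {
  if (is.null(node$children)) return(node$label)
  min(vapply(node$children, node_minlab, ""))
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("<nj_tree> ", length(tree_leaves(x)), " leaves: ",
      write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Leaf labels of an `nj_tree`
#' @param tree an `nj_tree` (or internal node).
#' @export
tree_leaves <- function(tree) {
  if (is.null(tree$children)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Write a tree as Newick
#'
#' Bootstrap supports (when present) are emitted as internal-node labels
#' after the closing parenthesis, the convention iTOL and most viewers read.
#'
#' @param tree an `nj_tree`.
#' @param digits branch-length digits.
#' @return Newick string (terminated with `;`).
#' @export
write_newick <- function(tree, digits = 12L) {
  fmt <- function(node, top = FALSE) {
    if (is.null(node$children)) {
      out <- node$label
    } else {
      out <- paste0("(", paste(vapply(node$children, fmt, ""),
                               collapse = ","), ")")
      if (!is.null(node$support) && !top)
        out <- paste0(out, format(node$support, digits = 4))
    }
    if (!top && !is.na(node$edge_length))
      out <- paste0(out, ":", format(node$edge_length, digits = digits))
    out
  }
  paste0(fmt(tree, top = TRUE), ";")
}

#' Convert an `nj_tree` to an ape `phylo`
#' @param tree an `nj_tree`.
#' @return `ape::phylo` object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

# canonical bipartitions (internal edges) of an nj_tree: each internal
# non-root node's leaf set, canonicalized against the full leaf set.
tree_bipartitions <- function(tree) {
  all_leaves <- sort(tree_leaves(tree))
  ref <- all_leaves[1]
  out <- character()
  walk <- function(node, is_root) {
    if (is.null(node$children)) return(invisible())
    if (!is_root) {
      side <- sort(tree_leaves(node))
      if (ref %in% side) side <- setdiff(all_leaves, side)
      if (length(side) >= 2L && length(side) <= length(all_leaves) - 2L)
        out <<- c(out, paste(side, collapse = "|"))
    }
    for (ch in node$children) walk(ch, FALSE)
  }
  walk(tree, TRUE)
  out
}

#' Neighbor-joining with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `reps` times; each internal edge's support is the percentage
#' of replicate trees containing the same bipartition.  Reproducible under a
#' fixed seed.
#'
#' @param msa named aligned sequences (equal length).
#' @param reps bootstrap replicates (study-scale default 1000; tests use
#'   desk-scale values).
#' @param seed integer seed for the resampling RNG.
#' @param model distance model, see [msa_distances()].
#' @return `nj_tree` with `support` fields (0-100) on internal edges.
#' @export
bootstrap_nj <- function(msa, reps = 1000L, seed = 1L,
                         model = "p_distance") {
  msa <- unlist(as_named_chr(msa))
  full <- neighbor_joining(msa_distances(msa, model))
  bips <- tree_bipartitions(full)
  counts <- setNames(numeric(length(bips)), bips)
  chars <- do.call(rbind, strsplit(msa, ""))
  nc <- ncol(chars)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    sub <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(sub) <- names(msa)
    rep_tree <- try(neighbor_joining(msa_distances(sub, model)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rb <- tree_bipartitions(rep_tree)
    hit <- bips %in% rb
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / reps
  decorate <- function(node, is_root) {
    if (is.null(node$children)) return(node)
    if (!is_root) {
      all_leaves <- sort(tree_leaves(full))
      side <- sort(tree_leaves(node))
      if (all_leaves[1] %in% side) side <- setdiff(all_leaves, side)
      key <- paste(side, collapse = "|")
      if (key %in% names(supports)) node$support <- unname(supports[key])
    }
    node$children <- lapply(node$children, decorate, is_root = FALSE)
    node
  }
  decorate(full, TRUE)
}

#' Write a distance matrix in square PHYLIP format
#' @param dm labeled symmetric matrix.
#' @param path output path.
#' @export
write_phylip <- function(dm, path) {
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i)
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a sequence family along a tree
#'
#' Independent residue substitutions along each edge: each site substitutes
#' with probability `rate` per edge (uniformly to one of the 19 other
#' residues).  Leaves are labeled by the tree's tip labels.
#'
#' @param root character scalar root protein.
#' @param tree `ape::phylo` or `nj_tree` or Newick string.
#' @param rate per-site, per-edge substitution probability.
#' @return named character vector of leaf sequences.
#' @export
diverge_family <- function(root, tree, rate) {
  if (inherits(tree, "nj_tree")) tree <- as_phylo(tree)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  aa <- setdiff(names(ROBINSON_FREQS), NULL)
  rootv <- strsplit(as.character(root), "")[[1]]
  n <- length(rootv)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  rootnode <- ntip + 1L
  seqs[[rootnode]] <- rootv
  # edges in preorder
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1]
    to <- ord$edge[e, 2]
    parent <- seqs[[from]]
    child <- parent
    hits <- which(runif(n) < rate)
    for (h in hits) {
      child[h] <- sample(setdiff(aa, child[h]), 1L)
    }
    seqs[[to]] <- child
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  out
}
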