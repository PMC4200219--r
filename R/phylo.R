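# Distance phylogeny for peptide families: p-distances on a fixed
# alignment, Saitou-Nei neighbor joining (implemented here, exact on
# additive matrices), and column-resampling bootstrap with collapse of
# weakly supported bipartitions.  Trees use the 'ape' phylo container
# and Newick I/O.

# coerce aligned input (named character vector of equal-length strings,
# or a character matrix taxa x sites) into a character matrix
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment)))
      rownames(alignment) <- paste0("t", seq_len(nrow(alignment)))
    return(alignment)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- if (is.null(names(alignment)))
    paste0("t", seq_along(alignment)) else names(alignment)
  m
}

#' Stack equal-length peptides into a gap-free alignment
#'
#' Convenience for short peptide families that align without gaps; a
#' genuine multiple aligner is out of scope and pre-aligned FASTA is
#' accepted everywhere.
#'
#' @param sequences named character vector of equal-length peptides.
#' @return Character matrix (taxa x sites).
#' @export
stack_alignment <- function(sequences) {
  alignment_matrix(sequences)
}

#' Pairwise p-distances of an alignment
#'
#' `d_ij` = mismatches / number of sites where neither sequence has a
#' gap (`-` or `.`).  Pairs with no comparable site are an error.
#'
#' @param alignment named character vector of equal-length aligned
#'   strings, or a character matrix (taxa x sites).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  gap <- m == "-" | m == "."
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("no comparable (gap-free) sites between ", rownames(m)[i],
             " and ", rownames(m)[j])
      d <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion.
#' Ties in the Q matrix are broken by the lowest index pair, so the
#' result is deterministic.  On an additive distance matrix the
#' algorithm is exact: the tree's path lengths reproduce the input
#' distances.  Negative branch lengths (possible on non-additive input)
#' are clamped to zero with a warning, following common practice.
#'
#' @param D symmetric distance matrix with dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  # working copies; node "labels" are newick subtree strings
  labs <- rownames(D)
  sub <- labs                      # newick fragments per active node
  d <- D
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  while (length(sub) > 3) {
    r <- length(sub)
    Rsum <- rowSums(d)
    Q <- (r - 2) * d - outer(Rsum, Rsum, `+`)
    diag(Q) <- Inf
    # lowest-index tie-break: scan in (i < j) row-major order
    best <- c(1L, 2L); bestq <- Inf
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    newsub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":",
                     fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
  }
  # resolve the final three nodes around one internal vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", sub[1], ":", fmt(la), ",", sub[2], ":", fmt(lb),
                ",", sub[3], ":", fmt(lc), ");")
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  ape::read.tree(text = nwk)
}

# internal-edge bipartitions of an unrooted tree, canonicalized as the
# side not containing the first taxon (sorted label vectors)
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  out <- list()
  for (p in parts) {
    side <- sort(tips[p])
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    if (tips[1] %in% side) side <- sort(setdiff(tips, side))
    out[[paste(side, collapse = "|")]] <- side
  }
  out
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' for each replicate, and reports for every internal bipartition of
#' the full-data tree the percentage of replicates containing it.
#' Bipartitions below the cutoff are collapsed into polytomies in the
#' returned tree; supports of retained bipartitions are stored as
#' internal node labels (so they appear in Newick output).
#'
#' @param alignment as in [p_distance()].
#' @param n_reps bootstrap replicates (default 1000).
#' @param cutoff support percentage below which bipartitions are
#'   collapsed (default 50).
#' @param seed RNG seed for reproducibility.
#' @return List of class `boot_tree`: `tree` (collapsed `phylo` with
#'   node labels = support), `full_tree`, `support` (named vector, one
#'   entry per internal bipartition of the full tree), `n_reps`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, cutoff = 50,
                              seed = 1L) {
  stopifnot(n_reps >= 1)
  m <- alignment_matrix(alignment)
  full <- nj_tree(p_distance(m))
  ref <- tree_bipartitions(full)
  counts <- stats::setNames(numeric(length(ref)), names(ref))
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_tree <- tryCatch(
      suppressWarnings(nj_tree(p_distance(m[, cols, drop = FALSE]))),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    hits <- names(tree_bipartitions(rep_tree))
    counts[names(counts) %in% hits] <- counts[names(counts) %in% hits] + 1
  }
  support <- 100 * counts / n_reps
  tree <- collapse_bipartitions(full, support, cutoff)
  structure(list(tree = tree, full_tree = full, support = support,
                 n_reps = n_reps, cutoff = cutoff),
            class = "boot_tree")
}

#' @export
print.boot_tree <- function(x, ...) {
  cat("<boot_tree> ", length(x$tree$tip.label), " taxa, ",
      sum(x$support >= x$cutoff), "/", length(x$support),
      " bipartitions retained at cutoff ", x$cutoff, " (",
      x$n_reps, " replicates)\n", sep = "")
  invisible(x)
}

# collapse internal edges of an unrooted tree whose bipartition support
# is below the cutoff; retained internal nodes are labelled with their
# rounded support
collapse_bipartitions <- function(tree, support, cutoff) {
  tips <- tree$tip.label
  ntip <- length(tips)
  node_key <- function(node) {
    desc <- tips[unlist(phangorn_descendants(tree, node))]
    side <- sort(desc)
    if (tips[1] %in% side) side <- sort(setdiff(tips, side))
    paste(side, collapse = "|")
  }
  internal <- (ntip + 1):(ntip + tree$Nnode)
  labels <- rep("", tree$Nnode)
  drop_edges <- integer(0)
  for (node in internal) {
    parent_edge <- which(tree$edge[, 2] == node)
    if (length(parent_edge) == 0) next  # root of the unrooted embedding
    key <- node_key(node)
    sup <- support[key]
    if (is.na(sup)) next
    if (sup < cutoff) drop_edges <- c(drop_edges, parent_edge)
    else labels[node - ntip] <- as.character(round(sup))
  }
  tree$node.label <- labels
  if (length(drop_edges) == 0) return(tree)
  # contract: reattach children of each dropped node to its parent
  for (e in drop_edges) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    tree$edge[tree$edge[, 1] == child, 1] <- parent
  }
  keep <- setdiff(seq_len(nrow(tree$edge)), drop_edges)
  dropped_nodes <- tree$edge[drop_edges, 2]
  tree$edge <- tree$edge[keep, , drop = FALSE]
  tree$edge.length <- tree$edge.length[keep]
  # renumber remaining internal nodes consecutively
  old_internal <- sort(setdiff(unique(as.vector(tree$edge)),
                               seq_len(ntip)))
  map <- stats::setNames(ntip + seq_along(old_internal), old_internal)
  tree$edge[tree$edge > ntip] <- map[as.character(
    tree$edge[tree$edge > ntip])]
  tree$node.label <- labels[old_internal - ntip]
  tree$Nnode <- length(old_internal)
  tree
}

# tips descending from a node (simple edge-table walk; avoids importing
# a whole tree-manipulation package for one helper)
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_descendants, tree = tree))
}

#' Write a tree to Newick
#' @param tree a `phylo` or `boot_tree`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "boot_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
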