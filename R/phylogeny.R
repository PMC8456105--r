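#' Pairwise distance matrix from an alignment
#'
#' p-distance over shared non-gap columns, optionally Poisson-corrected
#' (`d = -ln(1 - p)`). Symmetric with a zero diagonal.
#'
#' @param msa a `protein_msa`.
#' @param model `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return symmetric numeric matrix with row/col names from the MSA.
#' @export
distance_matrix <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(inherits(msa, "protein_msa"))
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(mat) <- names(msa)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- mat[i, ] != "-" & mat[j, ] != "-"
    ns <- sum(shared)
    if (ns == 0)
      stop("sequences ", sQuote(names(msa)[i]), " and ", sQuote(names(msa)[j]),
           " share no aligned columns")
    p <- sum(mat[i, shared] != mat[j, shared]) / ns
    d <- if (model == "p") p else {
      if (p >= 1)
        stop("saturated distance (p = 1) between ", sQuote(names(msa)[i]),
             " and ", sQuote(names(msa)[j]))
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic NJ agglomeration (Saitou-Nei with the standard Q criterion),
#' exact on additive distance matrices. Negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch of the same join, so
#' leaf-to-leaf path lengths are preserved. Returns an unrooted `ape::phylo`
#' tree.
#'
#' @param D symmetric distance matrix with >= 3 labelled taxa.
#' @return an object of class `phylo`.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # node bookkeeping: tips are 1..n; internal nodes numbered n+1.. as in ape
  n_internal <- n - 2
  next_node <- n + 2L  # ape convention: root-ish first internal node is n+1
  active <- seq_len(n)               # current cluster ids (ape node numbers)
  node_of <- seq_len(n)
  Dm <- D
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  ids <- seq_len(n)                  # row indices into Dm mapped to node numbers
  nodes <- seq_len(n)

  while (length(nodes) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # deterministic tie-break
    i <- min(idx); j <- max(idx)
    d_ij <- Dm[i, j]
    li <- 0.5 * d_ij + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d_ij - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new, nodes[i]), c(new, nodes[j]))
    lens <- c(lens, li, lj)
    d_new <- 0.5 * (Dm[i, ] + Dm[j, ] - d_ij)
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], d_new[keep]),
                 c(d_new[keep], 0))
    Dm <- Dm2
    nodes <- c(nodes[keep], new)
  }
  # final three-way join at the root node n+1
  root <- n + 1L
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  ls <- c(l1, l2, l3)
  for (k in 1:3) if (ls[k] < 0) {
    others <- setdiff(1:3, k)
    ls[others] <- ls[others] + ls[k] / 2
    ls[k] <- 0
  }
  edges <- rbind(edges, c(root, nodes[1]), c(root, nodes[2]), c(root, nodes[3]))
  lens <- c(lens, ls)

  tree <- list(edge = edges, edge.length = as.numeric(unname(lens)),
               tip.label = labels, Nnode = max(c(edges)) - n)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# canonical bipartition strings for the internal edges of an unrooted tree:
# each internal edge splits the tips; the side not containing the first tip
# label (alphabetically) is sorted and collapsed with "|"
.bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  out <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next  # tip edge, not an internal bipartition
    tips <- tree$tip.label[.tips_below(tree, child)]
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2 || length(tips) > n - 2) next  # trivial
    out <- c(out, paste(sort(tips), collapse = "|"))
    nodes <- c(nodes, child)
  }
  setNames(nodes, out)
}

.tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer(0)
  for (k in kids)
    out <- c(out, if (k <= n) k else .tips_below(tree, k))
  out
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilds the NJ tree for each
#' replicate, and reports for every internal bipartition of the full-data
#' tree the fraction of replicates containing it. Supports (in `[0,1]`) are
#' stored as internal node labels. Replicates whose resampled columns leave
#' a pair with no shared sites are dropped with a warning.
#'
#' @param msa a `protein_msa` with >= 4 rows.
#' @param n_reps number of bootstrap replicates (>= 10; default 100).
#' @param seed RNG seed.
#' @param model distance model, as in [distance_matrix()].
#' @return a `phylo` tree with `node.label` supports.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = 1, model = "poisson") {
  stopifnot(inherits(msa, "protein_msa"))
  if (n_reps < 10) stop("n_reps must be >= 10 for meaningful supports")
  full <- neighbor_joining(distance_matrix(msa, model))
  bip <- .bipartitions(full)
  counts <- setNames(rep(0, length(bip)), names(bip))
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(mat) <- names(msa)
  L <- ncol(mat)
  used <- 0
  .with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- as_msa(setNames(apply(mat[, cols, drop = FALSE], 1,
                                       paste, collapse = ""), names(msa)))
      tr <- try(neighbor_joining(distance_matrix(rep_msa, model)), silent = TRUE)
      if (inherits(tr, "try-error")) next
      used <- used + 1
      rb <- names(.bipartitions(tr))
      hit <- names(counts) %in% rb
      counts[hit] <- counts[hit] + 1
    }
  })
  if (used < n_reps)
    warning(n_reps - used, " bootstrap replicate(s) dropped (no shared columns)")
  support <- counts / max(used, 1)
  n <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  for (k in seq_along(bip))
    labs[bip[k] - n] <- format(support[k])
  full$node.label <- labs
  full
}

#' Collapse poorly supported branches
#'
#' Internal edges whose support is below `min_support` (strict: exactly
#' `min_support` survives) are collapsed into polytomies; the collapsed
#' edge's length is added to the parent edge (or dropped when the collapsed
#' edge hangs off the root of the representation) and the leaf set is
#' unchanged.
#'
#' @param tree a `phylo` with numeric `node.label` supports (fractions).
#' @param min_support support threshold (default 0.5).
#' @return the pruned `phylo`.
#' @export
prune_low_support <- function(tree, min_support = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) stop("tree has no support labels")
  n <- length(tree$tip.label)
  repeat {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    drop_e <- NA
    for (e in seq_len(nrow(tree$edge))) {
      child <- tree$edge[e, 2]
      if (child <= n) next
      s <- sup[child - n]
      if (!is.na(s) && s < min_support) { drop_e <- e; break }
    }
    if (is.na(drop_e)) break
    parent <- tree$edge[drop_e, 1]
    child <- tree$edge[drop_e, 2]
    clen <- tree$edge.length[drop_e]
    # reattach child's children to parent
    kid_edges <- which(tree$edge[, 1] == child)
    tree$edge[kid_edges, 1] <- parent
    # add the collapsed edge length to the parent's own incoming edge
    pe <- which(tree$edge[, 2] == parent)
    if (length(pe) == 1)
      tree$edge.length[pe] <- tree$edge.length[pe] + clen
    tree$edge <- tree$edge[-drop_e, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-drop_e]
    # renumber internal nodes to stay a valid phylo object
    old_nodes <- sort(unique(tree$edge[, 1]))
    map <- setNames(seq_along(old_nodes) + n, old_nodes)
    labs <- tree$node.label[old_nodes - n]
    tree$edge[, 1] <- as.integer(map[as.character(tree$edge[, 1])])
    internal_child <- tree$edge[, 2] > n
    tree$edge[internal_child, 2] <-
      as.integer(map[as.character(tree$edge[internal_child, 2])])
    tree$node.label <- labs
    tree$Nnode <- length(old_nodes)
  }
  tree
}

#' Write a tree in Newick format
#'
#' Supports, if present, are written as internal node labels.
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path input path.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- cumsum(strsplit(txt, "")[[1]] == "(") -
    cumsum(strsplit(txt, "")[[1]] == ")")
  if (any(open < 0) || tail(open, 1) != 0)
    stop("Newick parse error in ", path, ": unbalanced parentheses near character ",
         which(open < 0)[1])
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}
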