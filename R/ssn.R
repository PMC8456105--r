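#' Collapse near-identical sequences into representative nodes
#'
#' Greedy single-linkage grouping: sequences joined whenever their global
#' percent identity (gaps in the denominator) reaches `identity_min`; each
#' group is represented by its longest member (ties by lexicographically
#' smallest id). Single linkage is the most permissive reading of
#' "collapsed at a similarity of 90%".
#'
#' @param seqs named character vector of proteins (>= 1).
#' @param identity_min collapse threshold in percent (default 90).
#' @return Named list mapping representative id to the character vector of
#'   member ids (every input appears in exactly one group).
#' @export
collapse_nodes <- function(seqs, identity_min = 90) {
  if (length(seqs) == 0) stop("collapse_nodes needs at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must have unique names")
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pid <- percent_identity(needleman_wunsch(seqs[[i]], seqs[[j]]))
      if (pid >= identity_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(names(seqs), roots)
  reps <- vapply(groups, function(ids) {
    lens <- nchar(seqs[ids])
    ids[order(-lens, ids)][1]
  }, character(1))
  out <- setNames(unname(groups), unname(reps))
  out[order(names(out))]
}

#' Build a sequence similarity network
#'
#' All-vs-all local (Smith-Waterman) alignment of the representative
#' sequences; an undirected edge is drawn whenever the raw alignment score
#' reaches `score_min`. Raw affine-gap BLOSUM62 scores are a monotone
#' equivalent of the web tools' "alignment score" threshold and keep the
#' construction self-contained.
#'
#' @param representatives named character vector of >= 2 representative
#'   sequences (e.g. names of the [collapse_nodes()] output).
#' @param score_min edge threshold (default 100).
#' @param members optional named list mapping representative id to member
#'   ids (as from [collapse_nodes()]).
#' @param metadata optional data.frame of node metadata with a `gene_id`
#'   column.
#' @return An `ssn_graph`: list with `graph` (igraph), `representatives`
#'   (member map), `clusters` (NULL until [connected_components()]) and
#'   `labels`.
#' @export
build_network <- function(representatives, score_min = 100, members = NULL,
                          metadata = NULL) {
  if (length(representatives) < 2)
    stop("build_network needs at least 2 representatives")
  ids <- names(representatives)
  if (is.null(members)) members <- setNames(as.list(ids), ids)
  n <- length(ids)
  ea <- character(0); eb <- character(0); ew <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- smith_waterman(representatives[[i]], representatives[[j]])$score
    if (s >= score_min) {
      ea <- c(ea, ids[i]); eb <- c(eb, ids[j]); ew <- c(ew, s)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids,
                            n_members = vapply(members[ids], length, integer(1)))
  if (length(ea) > 0) {
    g <- igraph::add_edges(g, rbind(match(ea, ids), match(eb, ids)))
    igraph::E(g)$score <- ew
  }
  structure(list(graph = g, representatives = members[ids],
                 metadata = metadata, clusters = NULL, labels = NULL),
            class = "ssn_graph")
}

#' Cluster an SSN by connected components
#'
#' Clusters are the connected components of the thresholded network, with
#' deterministic ids: components are numbered by their lexicographically
#' smallest member id.
#'
#' @param ssn an `ssn_graph`.
#' @return The `ssn_graph` with `clusters` set (named integer vector,
#'   node -> cluster id).
#' @export
connected_components <- function(ssn) {
  stopifnot(inherits(ssn, "ssn_graph"))
  comp <- igraph::components(ssn$graph)
  memb <- setNames(comp$membership, igraph::V(ssn$graph)$name)
  anchor <- tapply(names(memb), memb, min)
  newid <- setNames(rank(anchor, ties.method = "first"), names(anchor))
  ssn$clusters <- setNames(as.integer(newid[as.character(memb)]), names(memb))
  ssn
}

#' Label SSN clusters via exemplar sequences
#'
#' A cluster receives label L iff it contains the exemplar sequence mapped
#' to L (exemplars may be collapsed members, not only representatives). Two
#' different labels landing in one cluster raise a warning and both labels
#' are kept.
#'
#' @param ssn an `ssn_graph` with clusters assigned.
#' @param exemplars named character vector, label -> sequence id.
#' @return The `ssn_graph` with `labels`: a named list, cluster id (as
#'   character) -> character vector of labels.
#' @export
label_clusters <- function(ssn, exemplars) {
  stopifnot(inherits(ssn, "ssn_graph"))
  if (is.null(ssn$clusters)) ssn <- connected_components(ssn)
  rep_of <- rep(names(ssn$representatives),
                vapply(ssn$representatives, length, integer(1)))
  names(rep_of) <- unlist(ssn$representatives)
  labels <- list()
  for (lab in names(exemplars)) {
    sid <- exemplars[[lab]]
    r <- rep_of[sid]
    if (is.na(r)) stop("exemplar sequence ", sQuote(sid), " (label ",
                       sQuote(lab), ") is absent from the network")
    cl <- as.character(ssn$clusters[[r]])
    labels[[cl]] <- c(labels[[cl]], lab)
  }
  multi <- names(labels)[vapply(labels, length, integer(1)) > 1]
  if (length(multi) > 0)
    warning("cluster(s) ", paste(multi, collapse = ", "),
            " received multiple labels; all kept")
  ssn$labels <- labels
  ssn
}

#' Gene ids of a labelled SSN cluster
#'
#' All member sequences (through their representatives) of the cluster
#' carrying `label`.
#'
#' @param ssn a labelled `ssn_graph`.
#' @param label cluster label.
#' @return character vector of member ids.
#' @export
cluster_members <- function(ssn, label) {
  stopifnot(inherits(ssn, "ssn_graph"))
  if (is.null(ssn$labels)) stop("SSN has no labels; run label_clusters()")
  cl <- names(ssn$labels)[vapply(ssn$labels, function(x) label %in% x, logical(1))]
  if (length(cl) == 0) stop("no cluster labelled ", sQuote(label))
  nodes <- names(ssn$clusters)[ssn$clusters == as.integer(cl[1])]
  unname(unlist(ssn$representatives[nodes]))
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat(sprintf("<ssn_graph> %d nodes (%d sequences), %d edges",
              igraph::vcount(x$graph),
              length(unlist(x$representatives)), igraph::ecount(x$graph)))
  if (!is.null(x$clusters))
    cat(sprintf(", %d clusters", length(unique(x$clusters))))
  cat("\n")
  if (!is.null(x$labels))
    for (cl in names(x$labels))
      cat(sprintf("  cluster %s: %s\n", cl,
                  paste(x$labels[[cl]], collapse = ", ")))
  invisible(x)
}

#' Export an SSN to GraphML
#' @param ssn an `ssn_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssn_graphml <- function(ssn, path) {
  g <- ssn$graph
  if (!is.null(ssn$clusters))
    igraph::V(g)$cluster <- unname(ssn$clusters[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export SSN edges as TSV
#' @param ssn an `ssn_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssn_edges <- function(ssn, path) {
  e <- igraph::as_data_frame(ssn$graph, what = "edges")
  names(e)[1:2] <- c("node_a", "node_b")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
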