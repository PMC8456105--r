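#' Find anchor genes by domain content
#'
#' An anchor is any gene carrying at least one of the listed Pfam-style
#' domain accessions at or below the E-value ceiling (e.g. the two
#' cupredoxin domains PF00394/PF07731 that define multicopper-oxidase
#' homologs).
#'
#' @param gs a `genome_set` with domain hits attached.
#' @param required_any character vector of domain accessions; a single
#'   qualifying hit suffices.
#' @param evalue_max E-value ceiling for a hit to count.
#' @return Character vector of anchor gene ids (each listed once, in gene
#'   table order).
#' @export
find_anchors <- function(gs, required_any = c("PF00394", "PF07731"),
                         evalue_max = 1e-5) {
  stopifnot(inherits(gs, "genome_set"))
  if (length(required_any) == 0)
    stop("required_any must name at least one domain accession")
  h <- gs$domain_hits
  ids <- unique(h$gene_id[h$domain_acc %in% required_any & h$evalue <= evalue_max])
  gs$genes$gene_id[gs$genes$gene_id %in% ids]
}

#' Find full copper-oxidase genes by domain content
#'
#' Requires ALL listed domains (default: the three cupredoxin domains
#' PF00394, PF07731 and PF07732 that define the sequence-similarity-network
#' input set).
#'
#' @inheritParams find_anchors
#' @param required_all accessions that must all be present.
#' @return Character vector of gene ids.
#' @export
find_cu_oxidases <- function(gs, required_all = c("PF00394", "PF07731", "PF07732"),
                             evalue_max = 1e-5) {
  stopifnot(inherits(gs, "genome_set"))
  if (length(required_all) == 0)
    stop("required_all must name at least one domain accession")
  h <- gs$domain_hits
  h <- h[h$domain_acc %in% required_all & h$evalue <= evalue_max, , drop = FALSE]
  n_dom <- tapply(h$domain_acc, h$gene_id, function(x) length(unique(x)))
  ids <- names(n_dom)[n_dom == length(unique(required_all))]
  gs$genes$gene_id[gs$genes$gene_id %in% ids]
}

#' Extract the gene window around an anchor
#'
#' Up to `radius` genes on each side of the anchor by rank, on the anchor's
#' contig only (windows never cross contig boundaries; they are truncated at
#' contig ends).
#'
#' @param gs a `genome_set`.
#' @param anchor_id anchor gene id.
#' @param radius genes per side (default 10).
#' @return A `gene_window`: list with `anchor_id`, `member_ids` (rank order,
#'   anchor included) and `radius`.
#' @export
extract_window <- function(gs, anchor_id, radius = 10) {
  a <- .gene_row(gs, anchor_id)
  g <- gs$genes
  same <- g$genome_id == a$genome_id & g$contig_id == a$contig_id
  sel <- same & abs(g$rank - a$rank) <= radius
  members <- g$gene_id[sel][order(g$rank[sel])]
  structure(list(anchor_id = anchor_id, member_ids = members,
                 radius = radius), class = "gene_window")
}

#' Infer the operon context within a window
#'
#' Maximal run of genes contiguous in rank with the anchor where each
#' consecutive pair is on the same strand (if required) and separated by at
#' most `max_gap_bp` of intergenic sequence. This is a standard prokaryotic
#' operon heuristic; it labels the "neighborhood" subset of a window and is
#' not used by the discovery filter itself.
#'
#' @param window a `gene_window`.
#' @param gs the `genome_set` it came from.
#' @param max_gap_bp maximum intergenic gap in base pairs (default 150).
#' @param require_same_strand require consecutive genes to share strand.
#' @return An `operon_context`: list with `anchor_id` and
#'   `operon_member_ids` (contiguous, anchor included).
#' @export
infer_operon <- function(window, gs, max_gap_bp = 150,
                         require_same_strand = TRUE) {
  stopifnot(inherits(window, "gene_window"))
  g <- gs$genes
  rows <- g[match(window$member_ids, g$gene_id), , drop = FALSE]
  i0 <- match(window$anchor_id, rows$gene_id)
  link <- function(a, b) {  # can rows a and b be in one operon?
    gap <- rows$start[b] - rows$end[a]
    (!require_same_strand || rows$strand[a] == rows$strand[b]) && gap <= max_gap_bp
  }
  lo <- hi <- i0
  while (lo > 1 && link(lo - 1, lo)) lo <- lo - 1
  while (hi < nrow(rows) && link(hi, hi + 1)) hi <- hi + 1
  structure(list(anchor_id = window$anchor_id,
                 operon_member_ids = rows$gene_id[lo:hi]),
            class = "operon_context")
}

#' Window/operon report for a set of anchors
#'
#' One row per (anchor, window member) with the signed gene offset and an
#' in-operon flag; the TSV dialect shared by the pipeline.
#'
#' @param gs a `genome_set`.
#' @param anchor_ids anchors to report.
#' @param radius window radius.
#' @param max_gap_bp,require_same_strand passed to [infer_operon()].
#' @param path optional output TSV path.
#' @return The report data.frame (invisibly if `path` is given).
#' @export
window_report <- function(gs, anchor_ids, radius = 10, max_gap_bp = 150,
                          require_same_strand = TRUE, path = NULL) {
  out <- lapply(anchor_ids, function(a) {
    w <- extract_window(gs, a, radius)
    op <- infer_operon(w, gs, max_gap_bp, require_same_strand)
    ranks <- gs$genes$rank[match(w$member_ids, gs$genes$gene_id)]
    a_rank <- gs$genes$rank[match(a, gs$genes$gene_id)]
    data.frame(anchor_id = a, member_id = w$member_ids,
               offset = ranks - a_rank,
               in_operon = w$member_ids %in% op$operon_member_ids,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
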