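#' Assemble a genome set
#'
#' Container for annotated coding genes across one or more genomes, plus
#' externally computed Pfam-style domain annotations and a taxonomy map.
#' Coordinates are stored 0-based half-open; per-contig gene ranks (0-based,
#' ordered by start coordinate) are assigned here.
#'
#' @param genes data.frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `protein`.
#' @param domain_hits data.frame with columns `gene_id`, `domain_acc`,
#'   `evalue`, or `NULL`.
#' @param taxonomy named character vector mapping genome_id to a class label
#'   (e.g. `"alpha"`). Genomes missing from it are labelled `"unknown"`.
#' @return An object of class `genome_set`: a list with elements `genes`
#'   (with `rank` and `length_aa` columns added), `domain_hits`, `taxonomy`
#'   and `proteome_counts` (genomes per class).
#' @export
genome_set <- function(genes, domain_hits = NULL, taxonomy = NULL) {
  req <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand", "protein")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0)
    stop("genes is missing column(s): ", paste(miss, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id values: ",
         paste(head(unique(genes$gene_id[duplicated(genes$gene_id)]), 3), collapse = ", "))
  bad <- which(genes$start >= genes$end)
  if (length(bad) > 0)
    stop("start >= end for gene(s): ", paste(head(genes$gene_id[bad], 3), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(!nzchar(genes$protein)))
    stop("empty protein sequence for gene(s): ",
         paste(head(genes$gene_id[!nzchar(genes$protein)], 3), collapse = ", "))
  ok <- grepl(sprintf("^[%sX]+$", paste(AA20, collapse = "")), genes$protein)
  if (!all(ok))
    stop("non-amino-acid characters in protein for gene(s): ",
         paste(head(genes$gene_id[!ok], 3), collapse = ", "))
  genes$length_aa <- nchar(genes$protein)

  # ranks: 0-based by start within each (genome, contig)
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  ord <- order(key, genes$start)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(genes$start, paste(genes$genome_id, genes$contig_id, sep = "\r"),
                           FUN = function(x) seq_along(x) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL

  if (is.null(taxonomy)) taxonomy <- character(0)
  gids <- unique(genes$genome_id)
  tax <- setNames(rep("unknown", length(gids)), gids)
  tax[names(taxonomy)[names(taxonomy) %in% gids]] <-
    taxonomy[names(taxonomy) %in% gids]

  gs <- structure(list(
    genes = genes,
    domain_hits = data.frame(gene_id = character(0), domain_acc = character(0),
                             evalue = numeric(0), stringsAsFactors = FALSE),
    taxonomy = tax,
    proteome_counts = c(table(tax))
  ), class = "genome_set")
  if (!is.null(domain_hits)) gs <- add_domain_hits(gs, domain_hits)
  gs
}

#' Attach domain hits to a genome set
#'
#' @param gs a `genome_set`.
#' @param hits data.frame with columns `gene_id`, `domain_acc`, `evalue`.
#' @param unknown_gene what to do with hits whose `gene_id` is not in the
#'   genome set: `"error"` (default) or `"skip"` with a warning.
#' @return The updated `genome_set`.
#' @export
add_domain_hits <- function(gs, hits, unknown_gene = c("error", "skip")) {
  unknown_gene <- match.arg(unknown_gene)
  stopifnot(inherits(gs, "genome_set"))
  req <- c("gene_id", "domain_acc", "evalue")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0)
    stop("domain hits missing column(s): ", paste(miss, collapse = ", "))
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)[req]
  if (any(hits$evalue < 0))
    stop("negative E-value in domain hits (row ",
         which(hits$evalue < 0)[1], ")")
  if (any(!nzchar(hits$domain_acc))) stop("empty domain_acc in domain hits")
  unknown <- !(hits$gene_id %in% gs$genes$gene_id)
  if (any(unknown)) {
    msg <- paste0(sum(unknown), " domain hit(s) reference unknown gene_id(s), e.g. ",
                  paste(head(unique(hits$gene_id[unknown]), 3), collapse = ", "))
    if (unknown_gene == "error") stop(msg)
    warning(msg, "; skipped")
    hits <- hits[!unknown, , drop = FALSE]
  }
  gs$domain_hits <- rbind(gs$domain_hits, hits)
  rownames(gs$domain_hits) <- NULL
  gs
}

#' Read a gene-table TSV
#'
#' The file dialect is 1-based inclusive coordinates with header columns
#' `genome_id`, `contig`, `start`, `end`, `strand`, `locus_tag`, `protein`,
#' `class`; coordinates are converted to the internal 0-based half-open
#' convention on load.
#'
#' @param path path to a tab-separated gene table.
#' @return A `genome_set`.
#' @export
read_gene_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("genome_id", "contig", "start", "end", "strand", "locus_tag",
           "protein", "class")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("gene table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    return(genome_set(data.frame(
      gene_id = character(0), genome_id = character(0), contig_id = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      protein = character(0), stringsAsFactors = FALSE)))
  }
  start1 <- as.integer(tab$start); end1 <- as.integer(tab$end)
  bad <- which(is.na(start1) | is.na(end1) | start1 >= end1)
  if (length(bad) > 0)
    stop("invalid coordinates (need start < end) at data line(s) ",
         paste(head(bad, 5), collapse = ", "), " of ", path)
  okaa <- grepl(sprintf("^[%sX]+$", paste(AA20, collapse = "")), tab$protein)
  if (!all(okaa))
    stop("non-amino-acid protein characters at data line(s) ",
         paste(head(which(!okaa), 5), collapse = ", "), " of ", path)
  genes <- data.frame(
    gene_id = tab$locus_tag, genome_id = tab$genome_id, contig_id = tab$contig,
    start = start1 - 1L, end = end1, strand = tab$strand,
    protein = toupper(tab$protein), stringsAsFactors = FALSE)
  tax <- tapply(tab$class, tab$genome_id, function(x) x[1])
  genome_set(genes, taxonomy = setNames(as.character(tax), names(tax)))
}

#' Write a gene-table TSV
#'
#' Inverse of [read_gene_table()]: coordinates are emitted 1-based inclusive.
#'
#' @param gs a `genome_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(gs, path) {
  g <- gs$genes
  out <- data.frame(
    genome_id = g$genome_id, contig = g$contig_id,
    start = g$start + 1L, end = g$end, strand = g$strand,
    locus_tag = g$gene_id, protein = g$protein,
    class = unname(gs$taxonomy[g$genome_id]), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genes from GFF3 + protein FASTA
#'
#' CDS features are matched to protein FASTA records via their `ID` (or
#' `locus_tag`) attribute. CDS without a matching protein are skipped with a
#' warning; the count is recorded in the `load_report` attribute.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param protein_fasta_path protein FASTA whose headers (first token) match
#'   CDS IDs.
#' @param genome_id genome identifier to assign (default: GFF file stem).
#' @param taxonomy optional named class label map, as in [genome_set()].
#' @return A `genome_set` with attribute `load_report` (list with `n_loaded`,
#'   `n_skipped`, `skipped_ids`).
#' @export
read_gff3_fasta <- function(gff_path, protein_fasta_path,
                            genome_id = sub("\\.gff3?$", "", basename(gff_path)),
                            taxonomy = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3_fasta() requires the rtracklayer package")
  gff <- as.data.frame(rtracklayer::readGFF(gff_path))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  ids <- if ("ID" %in% names(cds)) as.character(cds$ID) else rep(NA_character_, nrow(cds))
  if ("locus_tag" %in% names(cds))
    ids[is.na(ids)] <- as.character(cds$locus_tag)[is.na(ids)]
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  have <- ids %in% names(aa)
  skipped <- ids[!have]
  if (length(skipped) > 0)
    warning(length(skipped), " CDS feature(s) without a matching protein were skipped")
  cds <- cds[have, , drop = FALSE]
  ids <- ids[have]
  genes <- data.frame(
    gene_id = ids, genome_id = genome_id,
    contig_id = as.character(cds$seqid),
    start = as.integer(cds$start) - 1L, end = as.integer(cds$end),
    strand = as.character(cds$strand), protein = as.character(aa[ids]),
    stringsAsFactors = FALSE)
  gs <- genome_set(genes, taxonomy = taxonomy)
  attr(gs, "load_report") <- list(n_loaded = nrow(genes),
                                  n_skipped = length(skipped),
                                  skipped_ids = skipped)
  gs
}

#' Read a domain-annotation TSV
#'
#' Tab-separated `gene_id`, `domain_acc`, `evalue`. Duplicate rows are kept
#' (multi-domain proteins). If `gs` is supplied the hits are validated and
#' attached, returning the updated genome set; otherwise the hit table is
#' returned.
#'
#' @param path TSV path.
#' @param gs optional `genome_set` to attach the hits to.
#' @param unknown_gene passed to [add_domain_hits()].
#' @return A data.frame of hits, or the updated `genome_set` when `gs` is
#'   given.
#' @export
read_domain_table <- function(path, gs = NULL, unknown_gene = c("error", "skip")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "domain_acc", "evalue")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("domain table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  tab$evalue <- as.numeric(tab$evalue)
  if (any(is.na(tab$evalue) | tab$evalue < 0))
    stop("invalid (negative or non-numeric) E-value at data line(s) ",
         paste(head(which(is.na(tab$evalue) | tab$evalue < 0), 5), collapse = ", "),
         " of ", path)
  if (is.null(gs)) return(tab[req])
  add_domain_hits(gs, tab, unknown_gene = match.arg(unknown_gene))
}

#' Write a domain-annotation TSV
#' @param hits data.frame of domain hits (or a `genome_set`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  if (inherits(hits, "genome_set")) hits <- hits$domain_hits
  write.table(hits[c("gene_id", "domain_acc", "evalue")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d genes | %d genomes | %d contigs | %d domain hits\n",
              nrow(x$genes), length(unique(x$genes$genome_id)),
              length(unique(paste(x$genes$genome_id, x$genes$contig_id))),
              nrow(x$domain_hits)))
  pc <- x$proteome_counts
  cat("  proteomes per class:",
      paste(sprintf("%s=%d", names(pc), pc), collapse = ", "), "\n")
  invisible(x)
}

# protein lookup helpers -------------------------------------------------

.proteins_of <- function(gs, ids = NULL) {
  g <- gs$genes
  p <- setNames(g$protein, g$gene_id)
  if (is.null(ids)) p else {
    miss <- setdiff(ids, names(p))
    if (length(miss) > 0)
      stop("unknown gene_id(s): ", paste(head(miss, 3), collapse = ", "))
    p[ids]
  }
}

.gene_row <- function(gs, gene_id) {
  i <- match(gene_id, gs$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  gs$genes[i, , drop = FALSE]
}
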