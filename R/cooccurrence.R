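# Window membership machinery shared by the co-occurrence statistics.
# For each query gene, the "window" is up to `radius` genes on each side by
# rank on the same contig; the "operon" scope restricts it to the inferred
# operon context.

.window_sets <- function(gs, gene_ids, radius = 10,
                         scope = c("window", "operon"), ...) {
  scope <- match.arg(scope)
  lapply(setNames(gene_ids, gene_ids), function(id) {
    w <- extract_window(gs, id, radius)
    if (scope == "operon") infer_operon(w, gs, ...)$operon_member_ids
    else w$member_ids
  })
}

#' Fraction of cluster genes with a family gene in their window
#'
#' For each gene of an (MCO) cluster, is at least one family gene within
#' the `radius`-gene window? The gene-level denominator mirrors how the
#' neighborhood statistics are phrased; `scope = "operon"` gives the
#' operon-restricted variant.
#'
#' @param gs a `genome_set`.
#' @param cluster_genes gene ids of the cluster (denominator).
#' @param family_genes gene ids of the family.
#' @param radius window radius (default 10).
#' @param scope `"window"` (default) or `"operon"`.
#' @param ... operon parameters for [infer_operon()].
#' @return numeric fraction in `[0, 1]`.
#' @export
neighbor_fraction <- function(gs, cluster_genes, family_genes, radius = 10,
                              scope = "window", ...) {
  if (length(cluster_genes) == 0) return(NaN)
  ws <- .window_sets(gs, cluster_genes, radius, scope, ...)
  mean(vapply(ws, function(m) any(m %in% family_genes), logical(1)))
}

#' Fraction of cluster genes whose genome also hosts a family gene
#'
#' @inheritParams neighbor_fraction
#' @return numeric fraction in `[0, 1]`.
#' @export
genome_cooccurrence <- function(gs, cluster_genes, family_genes) {
  if (length(cluster_genes) == 0) return(NaN)
  g <- gs$genes
  fam_genomes <- unique(g$genome_id[g$gene_id %in% family_genes])
  mean(g$genome_id[match(cluster_genes, g$gene_id)] %in% fam_genomes)
}

#' Fraction of cluster genes whose genome hosts both families
#'
#' @inheritParams neighbor_fraction
#' @param family_a,family_b gene ids of the two families.
#' @return numeric fraction in `[0, 1]`.
#' @export
multi_family_cooccurrence <- function(gs, cluster_genes, family_a, family_b) {
  if (length(cluster_genes) == 0) return(NaN)
  g <- gs$genes
  ga <- unique(g$genome_id[g$gene_id %in% family_a])
  gb <- unique(g$genome_id[g$gene_id %in% family_b])
  both <- intersect(ga, gb)
  mean(g$genome_id[match(cluster_genes, g$gene_id)] %in% both)
}

#' Fraction of family genes with a target gene in their window
#'
#' The direction-reversed neighborhood statistic: for each family gene, is
#' at least one target (e.g. Cu-oxidase) gene within its window?
#'
#' @inheritParams neighbor_fraction
#' @param family_genes family gene ids (denominator).
#' @param target_genes target gene ids.
#' @return numeric fraction in `[0, 1]`.
#' @export
family_gene_assoc_fraction <- function(gs, family_genes, target_genes,
                                       radius = 10, scope = "window", ...) {
  if (length(family_genes) == 0) return(NaN)
  ws <- .window_sets(gs, family_genes, radius, scope, ...)
  mean(vapply(ws, function(m) any(m %in% target_genes), logical(1)))
}

#' Per-taxonomy-class counts and proteome-normalized rates
#'
#' For each taxonomy class: the raw family-gene count, its share of the
#' total (percent), the number of proteomes of that class, and the count
#' per proteome (the normalization under which apparent class enrichment is
#' reassessed).
#'
#' @param gs a `genome_set` with taxonomy.
#' @param family_genes family gene ids.
#' @return data.frame `class`, `count`, `share_pct`, `proteomes`,
#'   `per_proteome`.
#' @export
per_class_rates <- function(gs, family_genes) {
  g <- gs$genes
  cls <- gs$taxonomy[g$genome_id[match(family_genes, g$gene_id)]]
  classes <- names(gs$proteome_counts)
  cnt <- vapply(classes, function(cl) sum(cls == cl, na.rm = TRUE), numeric(1))
  total <- sum(cnt)
  data.frame(class = classes, count = as.integer(cnt),
             share_pct = if (total > 0) 100 * cnt / total else rep(NaN, length(cnt)),
             proteomes = as.integer(gs$proteome_counts[classes]),
             per_proteome = cnt / as.numeric(gs$proteome_counts[classes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of family windows containing an annotated gene
#'
#' For each family gene, does its window contain at least one gene from the
#' annotation set (e.g. putative Cu-binding proteins)?
#'
#' @inheritParams family_gene_assoc_fraction
#' @param annotation character vector of annotated gene ids.
#' @return numeric fraction in `[0, 1]`.
#' @export
neighborhood_annotation_fraction <- function(gs, family_genes, annotation,
                                             radius = 10, scope = "window", ...) {
  if (length(family_genes) == 0) return(NaN)
  ws <- .window_sets(gs, family_genes, radius, scope, ...)
  mean(vapply(ws, function(m) any(m %in% annotation), logical(1)))
}

#' Full co-occurrence report
#'
#' Computes every co-occurrence statistic (window and operon scope for the
#' directional ones) in one pass.
#'
#' @param gs a `genome_set`.
#' @param cluster_genes MCO-cluster gene ids.
#' @param family_genes family gene ids.
#' @param family_b second-family gene ids (e.g. CutG-like), or NULL.
#' @param annotation annotated gene ids, or NULL.
#' @param radius window radius.
#' @return A `cooccurrence_report` list.
#' @export
cooccurrence_report <- function(gs, cluster_genes, family_genes,
                                family_b = NULL, annotation = NULL,
                                radius = 10) {
  rep <- list(
    neighbor_fraction = neighbor_fraction(gs, cluster_genes, family_genes, radius),
    neighbor_fraction_operon = neighbor_fraction(gs, cluster_genes,
                                                 family_genes, radius,
                                                 scope = "operon"),
    genome_fraction = genome_cooccurrence(gs, cluster_genes, family_genes),
    both_families_fraction = if (is.null(family_b)) NA_real_ else
      multi_family_cooccurrence(gs, cluster_genes, family_genes, family_b),
    family_gene_assoc_fraction = family_gene_assoc_fraction(gs, family_genes,
                                                            cluster_genes, radius),
    neighborhood_annotation_fraction = if (is.null(annotation)) NA_real_ else
      neighborhood_annotation_fraction(gs, family_genes, annotation, radius),
    per_class = per_class_rates(gs, family_genes),
    n_cluster_genes = length(cluster_genes),
    n_family_genes = length(family_genes))
  class(rep) <- "cooccurrence_report"
  rep
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("<cooccurrence_report>\n")
  cat("  cluster genes with family neighbor (window):", pct(x$neighbor_fraction), "\n")
  cat("  cluster genes with family neighbor (operon):", pct(x$neighbor_fraction_operon), "\n")
  cat("  cluster genes with family gene in genome:   ", pct(x$genome_fraction), "\n")
  cat("  cluster genes with both families in genome: ", pct(x$both_families_fraction), "\n")
  cat("  family genes near a cluster gene:           ", pct(x$family_gene_assoc_fraction), "\n")
  cat("  family windows with annotated Cu gene:      ", pct(x$neighborhood_annotation_fraction), "\n")
  invisible(x)
}

#' Write a co-occurrence report as TSV + JSON
#' @param rep a `cooccurrence_report`.
#' @param tsv_path,json_path output paths (either may be NULL).
#' @return `rep`, invisibly.
#' @export
write_cooccurrence_report <- function(rep, tsv_path = NULL, json_path = NULL) {
  scalars <- rep[vapply(rep, function(x) is.numeric(x) && length(x) == 1, logical(1))]
  if (!is.null(tsv_path)) {
    write.table(data.frame(statistic = names(scalars),
                           value = unlist(scalars)),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    out <- c(scalars, list(per_class = rep$per_class))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(rep)
}
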