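#' Discovery pipeline configuration
#'
#' All stage parameters with their defaults: window radius 10, strict size
#' cutoff 170 aa, CXXXC/CXXC motif in the central 20-80%, domain E-value
#' ceiling 1e-5, up to 11 search iterations at inclusion E <= 0.01, SSN
#' edge score 100 and 90% collapse identity, 100 bootstrap replicates with
#' a 0.5 support cutoff. Unknown parameter names are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    anchor_domains = c("PF00394", "PF07731"),
    oxidase_domains = c("PF00394", "PF07731", "PF07732"),
    window_radius = 10,
    max_len = 170,
    motif_patterns = c("CXXXC", "CXXC"),
    motif_region = c(0.2, 0.8),
    domain_evalue_max = 1e-5,
    max_iter = 11,
    evalue_include = 0.01,
    calib_n = 1000,
    ssn_score_min = 100,
    collapse_identity = 90,
    bootstrap_reps = 100,
    support_min = 0.5,
    operon_max_gap_bp = 150,
    operon_same_strand = TRUE,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$window_radius >= 0, cfg$max_len > 0, cfg$max_iter >= 1,
            cfg$evalue_include > 0, cfg$support_min >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] parameters.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_pipeline_config() requires the yaml package")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full discovery workflow
#'
#' Stages, in order: anchor detection on the MCO domains; 10-gene window
#' extraction; the five-rule candidate filter inside windows; progressive
#' seed alignment with Cys motif-column curation; iterative profile-HMM
#' family expansion with the Pfam-removal rule; SSN construction over the
#' full three-domain Cu-oxidase set (collapse, threshold, components,
#' optional exemplar labels); co-occurrence statistics; and a
#' neighbor-joining tree of the SSN representatives with bootstrap supports
#' and low-support pruning. Deterministic given (inputs, config seed).
#'
#' @param genomes a `genome_set` (with domain hits), or a path to a
#'   gene-table TSV.
#' @param cfg a [pipeline_config()].
#' @param domain_path optional domain-table TSV to attach (required when
#'   `genomes` lacks domain hits).
#' @param signal_path optional external signal-call TSV; covered genes use
#'   these calls instead of the built-in heuristic.
#' @param exemplars optional named character vector (label -> gene id) for
#'   SSN cluster labelling; co-occurrence statistics then use the cluster
#'   labelled `cluster_label`.
#' @param cluster_label label of the MCO cluster used as the co-occurrence
#'   reference (default `"CutO"`).
#' @param annotation optional gene ids treated as Cu-annotation for the
#'   neighborhood-annotation statistic.
#' @param family_b optional second-family gene ids (CutG-like) for the
#'   both-families statistic.
#' @param out_dir optional output directory: per-stage TSVs, family FASTA,
#'   SSN GraphML, Newick tree, co-occurrence JSON and a run log are written
#'   there.
#' @return A `discovery_report` list with every stage result.
#' @export
run_discovery <- function(genomes, cfg = pipeline_config(), domain_path = NULL,
                          signal_path = NULL, exemplars = NULL,
                          cluster_label = "CutO", annotation = NULL,
                          family_b = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.character(genomes)) genomes <- stage("load", read_gene_table(genomes))
  stopifnot(inherits(genomes, "genome_set"))
  if (!is.null(domain_path))
    genomes <- stage("load", read_domain_table(domain_path, genomes))
  if (nrow(genomes$domain_hits) == 0)
    stop("pipeline stage 'candidate_rules' failed: no domain annotations ",
         "loaded; supply a domain table (gene_id, domain_acc, evalue)",
         call. = FALSE)
  signal_calls <- if (!is.null(signal_path))
    stage("load", read_signal_table(signal_path)) else NULL
  say("loaded %d genes in %d genomes", nrow(genomes$genes),
      length(unique(genomes$genes$genome_id)))

  ## anchors + windows
  anchors <- stage("anchors",
                   find_anchors(genomes, cfg$anchor_domains, cfg$domain_evalue_max))
  if (length(anchors) == 0)
    stop("pipeline stage 'anchors' failed: no anchor genes found", call. = FALSE)
  windows <- stage("windows", lapply(anchors, function(a)
    extract_window(genomes, a, cfg$window_radius)))
  candidates <- setdiff(unique(unlist(lapply(windows, `[[`, "member_ids"))),
                        anchors)
  say("%d anchors, %d window candidate genes", length(anchors), length(candidates))

  ## rule filter
  spec <- motif_spec(cfg$motif_patterns, cfg$motif_region)
  decisions <- stage("filter",
                     apply_rules(genomes, candidates, signal_calls, spec,
                                 max_len = cfg$max_len,
                                 domain_evalue_max = cfg$domain_evalue_max))
  seeds <- decisions$gene_id[decisions$passed]
  say("%d/%d window genes pass the candidate rules", length(seeds),
      length(candidates))
  if (length(seeds) < 2)
    stop("pipeline stage 'filter' failed: fewer than 2 seed candidates; ",
         "cannot build a seed alignment", call. = FALSE)

  ## seed MSA + curation
  seed_msa <- stage("msa", progressive_msa(.proteins_of(genomes, seeds)))
  cur <- stage("msa", curate_by_motif_columns(seed_msa))
  say("seed alignment: %d rows, %d removed by motif-column curation",
      length(cur$msa), length(cur$removed_ids))

  ## iterative HMM search
  fam <- stage("hmmsearch",
               iterative_search(cur$msa, genomes,
                                max_iter = cfg$max_iter,
                                evalue_include = cfg$evalue_include,
                                seed = cfg$seed, calib_n = cfg$calib_n,
                                domain_evalue_max = cfg$domain_evalue_max))
  say("family: %d members after %d iteration(s) (%s), %d removed by Pfam rule",
      length(fam$final_members), fam$iterations_run,
      if (fam$converged) "converged" else "max_iter reached",
      length(fam$removed_pfam))

  ## SSN over the full Cu-oxidase set
  oxidases <- stage("ssn", find_cu_oxidases(genomes, cfg$oxidase_domains,
                                            cfg$domain_evalue_max))
  ssn <- NULL
  if (length(oxidases) >= 2) {
    ox_seqs <- .proteins_of(genomes, oxidases)
    groups <- stage("ssn", collapse_nodes(ox_seqs, cfg$collapse_identity))
    ssn <- stage("ssn", build_network(ox_seqs[names(groups)],
                                      score_min = cfg$ssn_score_min,
                                      members = groups))
    ssn <- stage("ssn", connected_components(ssn))
    if (!is.null(exemplars)) ssn <- stage("ssn", label_clusters(ssn, exemplars))
    say("SSN: %d nodes, %d edges, %d clusters",
        igraph::vcount(ssn$graph), igraph::ecount(ssn$graph),
        length(unique(ssn$clusters)))
  } else say("SSN skipped: fewer than 2 Cu-oxidase sequences")

  ## co-occurrence
  cluster_genes <- if (!is.null(ssn) && !is.null(ssn$labels))
    stage("cooccur", cluster_members(ssn, cluster_label)) else oxidases
  cooccur <- stage("cooccur",
                   cooccurrence_report(genomes, cluster_genes,
                                       fam$final_members, family_b = family_b,
                                       annotation = annotation,
                                       radius = cfg$window_radius))

  ## phylogeny of the SSN representatives
  tree <- NULL
  if (!is.null(ssn) && igraph::vcount(ssn$graph) >= 4) {
    reps <- names(ssn$representatives)
    rep_msa <- stage("tree", progressive_msa(.proteins_of(genomes, reps)))
    tree <- stage("tree", bootstrap_support(rep_msa, n_reps = cfg$bootstrap_reps,
                                            seed = cfg$seed))
    tree <- stage("tree", prune_low_support(tree, cfg$support_min))
    say("tree: %d leaves, %d internal nodes after pruning",
        length(tree$tip.label), tree$Nnode)
  }

  report <- structure(list(
    config = cfg, anchors = anchors, windows = windows,
    decisions = decisions, seeds = seeds, curated_seed_msa = cur$msa,
    family = fam, oxidases = oxidases, ssn = ssn, cooccurrence = cooccur,
    tree = tree, log = log_lines), class = "discovery_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write.table(decisions, p("filter_decisions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    window_report(genomes, anchors, cfg$window_radius, cfg$operon_max_gap_bp,
                  cfg$operon_same_strand, path = p("windows.tsv"))
    write_msa_fasta(fam$msa, p("family_alignment.fasta"))
    write_msa_fasta(.proteins_of(genomes, fam$final_members),
                    p("family_members.fasta"))
    if (!is.null(fam$hmm)) write_hmm(fam$hmm, p("family_model.hmm"))
    if (!is.null(fam$hits))
      write.table(fam$hits, p("family_hits.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    if (!is.null(ssn)) {
      write_ssn_graphml(ssn, p("ssn.graphml"))
      write_ssn_edges(ssn, p("ssn_edges.tsv"))
    }
    write_cooccurrence_report(cooccur, tsv_path = p("cooccurrence.tsv"),
                              json_path = p("cooccurrence.json"))
    if (!is.null(tree)) write_newick(tree, p("tree.nwk"))
    writeLines(c(sprintf("config: %s",
                         paste(names(cfg), vapply(cfg, function(v)
                           paste(format(v), collapse = ","), character(1)),
                           sep = "=", collapse = "; ")),
                 log_lines), p("run_log.txt"))
  }
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("<discovery_report>\n")
  cat(sprintf("  anchors: %d | seeds: %d | family: %d member(s) in %d iteration(s)\n",
              length(x$anchors), length(x$seeds),
              length(x$family$final_members), x$family$iterations_run))
  if (!is.null(x$ssn))
    cat(sprintf("  SSN: %d nodes / %d clusters\n",
                igraph::vcount(x$ssn$graph), length(unique(x$ssn$clusters))))
  print(x$cooccurrence)
  invisible(x)
}
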