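#' Configuration for the synthetic proteome generator
#'
#' Describes a multi-genome gene-table benchmark with planted
#' multicopper-oxidase (MCO) anchors, a CutF-like family (signal peptide +
#' central CXXXC motif + C-terminal PP tail), a CutG-like co-occurring
#' family, Cu-annotation neighbors and four decoy types. All planted rates
#' are realized as exact counts (nearest integer, halves up), not Bernoulli
#' draws, so downstream co-occurrence counting can be checked sharply
#' against the recorded truth.
#'
#' Default scale: 30 genomes x 300 genes, a 40-member family at 30%
#' divergence, 100 decoys of each type, window radius 10 — the planted
#' co-occurrence rates mirror the fractions the discovery workflow is meant
#' to estimate (neighbor 0.40, genome 0.70, both-families 0.55, annotated
#' neighborhoods 0.88).
#'
#' @param n_genomes number of genomes (one contig, one MCO anchor each).
#' @param genes_per_genome genes per genome.
#' @param class_counts named integer: genomes per taxonomy class.
#' @param family_size number of planted CutF-like members.
#' @param family_class_counts named integer: family members per class
#'   (sums to `family_size`).
#' @param seed_length family seed-protein length in residues (25-170).
#' @param divergence expected per-site substitution fraction for family
#'   members (motif/signal/tail positions protected).
#' @param p_neighbor fraction of anchors with a family gene in their window.
#' @param p_genome fraction of anchors whose genome hosts a family gene.
#' @param p_both fraction of anchors whose genome hosts family + CutG-like.
#' @param p_annot fraction of family windows containing a Cu-annotation gene.
#' @param n_cueo,n_ftsp sizes of the two out-cluster MCO families.
#' @param cueo_family_cooccur,ftsp_family_cooccur planted genome
#'   co-occurrence rates of the out-cluster families with the CutF family.
#' @param mco_length,mco_divergence MCO seed length and within-family
#'   divergence.
#' @param n_decoys named integer: decoys per type (`small_no_motif`,
#'   `motif_domain`, `motif_outside`, `large_motif`).
#' @param window_radius window radius used for the planting geometry.
#' @param filler_length_range length range of background proteins.
#' @param filler_domain_frac fraction of background genes given a random
#'   Pfam-style hit.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genomes = 30, genes_per_genome = 300,
                         class_counts = c(alpha = 14, beta = 5, gamma = 9, delta = 2),
                         family_size = 40,
                         family_class_counts = c(alpha = 23, beta = 8, gamma = 8, delta = 1),
                         seed_length = 118, divergence = 0.30,
                         p_neighbor = 0.40, p_genome = 0.70, p_both = 0.55,
                         p_annot = 0.88,
                         n_cueo = 12, n_ftsp = 10,
                         cueo_family_cooccur = 0.08, ftsp_family_cooccur = 0.02,
                         mco_length = 240, mco_divergence = 0.10,
                         n_decoys = c(small_no_motif = 100, motif_domain = 100,
                                      motif_outside = 100, large_motif = 100),
                         window_radius = 10,
                         filler_length_range = c(80, 300),
                         filler_domain_frac = 0.3, seed = 42) {
  cfg <- as.list(environment())
  probs <- c(p_neighbor = p_neighbor, p_genome = p_genome, p_both = p_both,
             p_annot = p_annot, cueo = cueo_family_cooccur,
             ftsp = ftsp_family_cooccur)
  if (any(probs < 0 | probs > 1)) stop("planted rates must be in [0, 1]")
  if (p_neighbor > p_genome)
    stop("p_neighbor cannot exceed p_genome (a window neighbor shares the genome)")
  if (p_both > p_genome)
    stop("p_both cannot exceed p_genome (both-family genomes host the family)")
  if (seed_length <= 25 || seed_length >= 170)
    stop("seed_length must lie in (25, 170)")
  if (sum(class_counts) != n_genomes)
    stop("class_counts must sum to n_genomes")
  if (sum(family_class_counts) != family_size)
    stop("family_class_counts must sum to family_size")
  if (genes_per_genome < 6 * (window_radius + 2))
    stop("genes_per_genome too small for the requested window radius")
  structure(cfg, class = "synth_config")
}

#' Mutate a protein at unprotected sites
#'
#' Per-site substitution with probability `divergence`, uniform over the 19
#' alternative residues; positions listed in `protected_positions` (e.g.
#' motif cysteines, the PP tail, the signal-peptide core) are never touched.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param protein uppercase protein string.
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param protected_positions 1-based positions to keep intact.
#' @param seed optional RNG seed.
#' @return the mutated protein string.
#' @export
mutate_member <- function(protein, divergence, protected_positions = integer(0),
                          seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 1)
  run <- function() {
    chars <- strsplit(protein, "")[[1]]
    hit <- runif(length(chars)) < divergence
    hit[protected_positions] <- FALSE
    for (i in which(hit))
      chars[i] <- sample(setdiff(AA20, chars[i]), 1)
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

# random protein over an alphabet
.rand_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Family-style scaffold: tripartite signal peptide (protected core),
# central CXXHC-type motif, PPP tail. Returns protein + protected positions
# + motif start.
.family_scaffold <- function(len) {
  chars <- sample(AA20, len, replace = TRUE)
  chars[1] <- "M"; chars[2] <- "K"; chars[3] <- "K"
  chars[4:14] <- sample(c("L", "A", "V", "F", "I"), 11, replace = TRUE)
  chars[15] <- "S"; chars[17] <- "A"; chars[19] <- "A"
  mstart <- floor(len / 2) - 2
  chars[mstart] <- "C"; chars[mstart + 3] <- "H"; chars[mstart + 4] <- "C"
  chars[(len - 4):(len - 2)] <- c("P", "P", "P")
  list(protein = paste(chars, collapse = ""),
       protected = c(1:19, mstart, mstart + 4, (len - 5):len),
       motif_start = mstart)
}

#' Generate a synthetic multi-genome benchmark
#'
#' Builds a `genome_set` of `n_genomes` single-contig genomes populated
#' with background genes, planted MCO anchors (CutO-like, one per genome,
#' carrying PF00394/PF07731/PF07732 hits), out-cluster CueO-like and
#' FtsP-like MCOs, a CutF-like family derived from one seed protein, a
#' CutG-like family, Cu-annotation neighbors and four decoy types, with all
#' co-occurrence rates realized as exact counts. Returns the genome set and
#' a `synth_truth` record used as the acceptance oracle.
#'
#' Placement geometry keeps planted windows unambiguous: family genes are at
#' least `2*radius + 2` ranks apart, non-neighbor family genes and the
#' out-cluster MCOs are kept more than `radius` ranks from each other's
#' windows, so every planted fraction equals its recorded count ratio
#' exactly under deterministic window counting.
#'
#' @param cfg a [synth_config()].
#' @return list with `genomes` (a `genome_set`) and `truth` (a
#'   `synth_truth` list: member/anchor/decoy ids, neighbor pairs, hosting
#'   genomes, exemplars and the realized `expected` fractions).
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, .generate_synthetic_impl(cfg))
}

.generate_synthetic_impl <- function(cfg) {
  n <- cfg$n_genomes
  G <- cfg$genes_per_genome
  r <- cfg$window_radius
  genome_ids <- sprintf("G%02d", seq_len(n))
  classes <- rep(names(cfg$class_counts), cfg$class_counts)
  names(classes) <- genome_ids

  ## ----- exact-count allocation ------------------------------------------
  H <- .round_half_up(cfg$p_genome * n)          # genomes hosting the family
  N_neighbor <- .round_half_up(cfg$p_neighbor * n)
  N_both <- .round_half_up(cfg$p_both * n)
  N_annot <- .round_half_up(cfg$p_annot * cfg$family_size)
  stopifnot(N_neighbor <= H, N_both <= H)

  # hosting genomes per class: cap by class size and member count, then
  # shave the largest until the total is H (deterministic)
  h_c <- pmin(cfg$class_counts, cfg$family_class_counts)
  h_c <- pmax(h_c, as.integer(cfg$family_class_counts > 0))
  while (sum(h_c) > H) {
    cand <- which(h_c > 1)
    if (length(cand) == 0)
      stop("cannot realize p_genome: every class with planted members ",
           "needs at least one hosting genome")
    k <- cand[which.max(h_c[cand])]
    h_c[k] <- h_c[k] - 1
  }
  if (sum(h_c) < H)
    stop("cannot realize p_genome: too few eligible genomes per class")
  hosting <- unlist(lapply(names(h_c), function(cl)
    genome_ids[classes == cl][seq_len(h_c[[cl]])]))
  non_hosting <- setdiff(genome_ids, hosting)
  if (length(non_hosting) == 0 && (cfg$n_cueo + cfg$n_ftsp) > 0)
    non_hosting <- genome_ids  # degenerate config: everything co-occurs

  # family members per hosting genome (within class, round-robin)
  members_of <- setNames(vector("list", length(hosting)), hosting)
  for (cl in names(h_c)) {
    gs_cl <- genome_ids[classes == cl][seq_len(h_c[[cl]])]
    m <- cfg$family_class_counts[[cl]]
    if (m == 0) next
    alloc <- rep(floor(m / length(gs_cl)), length(gs_cl))
    extra <- m - sum(alloc)
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1
    for (i in seq_along(gs_cl)) members_of[[gs_cl[i]]] <- integer(alloc[i])
  }
  members_of <- members_of[vapply(members_of, length, integer(1)) > 0 |
                             names(members_of) %in% hosting]
  neighbor_genomes <- hosting[seq_len(N_neighbor)]
  both_genomes <- hosting[seq_len(N_both)]

  ## ----- seed proteins ----------------------------------------------------
  fam <- .family_scaffold(cfg$seed_length)
  mco_seed <- list(CutO = .rand_protein(cfg$mco_length),
                   CueO = .rand_protein(cfg$mco_length),
                   FtsP = .rand_protein(cfg$mco_length))
  cutg_seed <- .rand_protein(140)
  annot_seed <- .rand_protein(200)

  ## ----- per-genome layout ------------------------------------------------
  # plan[[g]] is a data.frame: rank, type, protein, domain accs
  plan <- setNames(vector("list", n), genome_ids)
  used <- setNames(vector("list", n), genome_ids)     # occupied ranks
  fam_ranks <- setNames(vector("list", n), genome_ids)
  mco_ranks <- setNames(vector("list", n), genome_ids)

  add_gene <- function(g, rank, type, protein, doms = character(0),
                       dom_ev = numeric(0)) {
    plan[[g]][[length(plan[[g]]) + 1]] <<- list(rank = rank, type = type,
                                                protein = protein,
                                                doms = doms, dom_ev = dom_ev)
    used[[g]] <<- c(used[[g]], rank)
  }
  pick_rank <- function(g, lo = 0, hi = G - 1, avoid = integer(0)) {
    cand <- setdiff(lo:hi, c(used[[g]], avoid))
    if (length(cand) == 0) stop("no free gene slot in genome ", g,
                                "; increase genes_per_genome")
    if (length(cand) == 1) cand else sample(cand, 1)
  }
  near <- function(x, d) if (length(x) == 0) integer(0)
    else unlist(lapply(x, function(v) (v - d):(v + d)))

  # CutO anchors, one per genome
  anchor_rank <- setNames(integer(n), genome_ids)
  for (g in genome_ids) {
    plan[[g]] <- list(); used[[g]] <- integer(0)
    fam_ranks[[g]] <- integer(0); mco_ranks[[g]] <- integer(0)
    a <- sample((r + 2):(G - r - 3), 1)
    anchor_rank[g] <- a
    mco_ranks[[g]] <- a
    add_gene(g, a, "cuto", mutate_member(mco_seed$CutO, cfg$mco_divergence),
             c("PF00394", "PF07731", "PF07732"), c(1e-60, 1e-55, 1e-50))
  }

  # family members: one adjacent to the anchor in neighbor genomes, the
  # rest isolated (> radius from every MCO, >= 2r+2 from other members)
  for (g in names(members_of)) {
    n_mem <- length(members_of[[g]])
    placed <- 0
    if (g %in% neighbor_genomes) {
      rank <- anchor_rank[g] + sample(c(-1L, 1L), 1)
      add_gene(g, rank, "family", mutate_member(fam$protein, cfg$divergence,
                                                fam$protected))
      fam_ranks[[g]] <- c(fam_ranks[[g]], rank)
      placed <- 1
    }
    while (placed < max(n_mem, if (g %in% neighbor_genomes) 1 else 0)) {
      avoid <- c(near(mco_ranks[[g]], r + 1), near(fam_ranks[[g]], 2 * r + 2))
      rank <- pick_rank(g, lo = 1, hi = G - 2, avoid = avoid)
      add_gene(g, rank, "family", mutate_member(fam$protein, cfg$divergence,
                                                fam$protected))
      fam_ranks[[g]] <- c(fam_ranks[[g]], rank)
      placed <- placed + 1
    }
  }

  # CutG-like genes in the both-family genomes
  for (g in both_genomes)
    add_gene(g, pick_rank(g), "cutg", mutate_member(cutg_seed, 0.15),
             "PF04222", 1e-30)

  # out-cluster MCOs: CueO-like and FtsP-like
  place_mco <- function(fam_name, n_mem, cooccur_rate) {
    k_in <- .round_half_up(cooccur_rate * n_mem)
    targets <- c(rep(hosting, length.out = max(k_in, 0)),
                 rep(non_hosting, length.out = n_mem - k_in))
    for (g in targets) {
      avoid <- c(near(fam_ranks[[g]], r + 1), near(mco_ranks[[g]], 2))
      rank <- pick_rank(g, lo = r + 1, hi = G - r - 2, avoid = avoid)
      add_gene(g, rank, tolower(fam_name),
               mutate_member(mco_seed[[fam_name]], cfg$mco_divergence),
               c("PF00394", "PF07731", "PF07732"), c(1e-58, 1e-52, 1e-48))
      mco_ranks[[g]] <<- c(mco_ranks[[g]], rank)
    }
  }
  place_mco("CueO", cfg$n_cueo, cfg$cueo_family_cooccur)
  place_mco("FtsP", cfg$n_ftsp, cfg$ftsp_family_cooccur)

  # Cu-annotation genes inside the first N_annot family windows
  fam_slots <- do.call(rbind, lapply(genome_ids, function(g)
    if (length(fam_ranks[[g]]) > 0)
      data.frame(g = g, rank = sort(fam_ranks[[g]]), stringsAsFactors = FALSE)))
  fam_slots <- fam_slots[order(fam_slots$g, fam_slots$rank), , drop = FALSE]
  annot_accs <- c("PF04234", "PF00403", "PF05425")  # CopC, HMA, CopD
  annotated_rows <- seq_len(min(N_annot, nrow(fam_slots)))
  for (i in annotated_rows) {
    g <- fam_slots$g[i]; fr <- fam_slots$rank[i]
    rank <- pick_rank(g, lo = max(0, fr - r), hi = min(G - 1, fr + r))
    add_gene(g, rank, "annotation", mutate_member(annot_seed, 0.15),
             sample(annot_accs, 1), 1e-20)
  }

  # decoys ------------------------------------------------------------------
  decoy_protein <- function(type) {
    if (type == "small_no_motif") {
      .rand_protein(sample(60:160, 1), setdiff(AA20, c("C", "P")))
    } else if (type == "motif_domain") {
      mutate_member(fam$protein, 0.45, fam$protected)
    } else if (type == "motif_outside") {
      .family_scaffold(sample(95:160, 1))$protein
    } else {  # large_motif
      sc <- .family_scaffold(sample(180:260, 1))
      sc$protein
    }
  }
  decoy_ids <- setNames(vector("list", length(cfg$n_decoys)), names(cfg$n_decoys))
  gcycle <- rep(genome_ids, length.out = sum(cfg$n_decoys))
  ci <- 0
  for (type in names(cfg$n_decoys)) {
    for (k in seq_len(cfg$n_decoys[[type]])) {
      ci <- ci + 1
      g <- gcycle[ci]
      if (type %in% c("small_no_motif", "motif_domain")) {
        # prefer a slot inside the anchor window (exercises the rule filter)
        a <- anchor_rank[g]
        rank <- tryCatch(
          pick_rank(g, lo = max(0, a - r), hi = min(G - 1, a + r),
                    avoid = near(fam_ranks[[g]], 0)),
          error = function(e) pick_rank(g))
      } else if (type == "motif_outside") {
        avoid <- c(near(mco_ranks[[g]], r + 1), near(fam_ranks[[g]], r + 1))
        rank <- pick_rank(g, avoid = avoid)
      } else {
        rank <- pick_rank(g, avoid = near(fam_ranks[[g]], r + 1))
      }
      doms <- if (type == "motif_domain") "PF09999" else character(0)
      dev <- if (type == "motif_domain") 1e-12 else numeric(0)
      add_gene(g, rank, paste0("decoy_", type), decoy_protein(type), doms, dev)
      decoy_ids[[type]] <- c(decoy_ids[[type]], paste(g, rank, sep = "@"))
    }
  }

  ## ----- assemble gene tables ---------------------------------------------
  genes <- vector("list", n)
  hits <- list()
  id_of <- function(g, rank) sprintf("%s_g%04d", g, rank + 1)
  type_of <- list()
  for (gi in seq_len(n)) {
    g <- genome_ids[gi]
    prots <- vapply(sample(cfg$filler_length_range[1]:cfg$filler_length_range[2],
                           G, replace = TRUE),
                    function(L) .rand_protein(L), character(1))
    types <- rep("filler", G)
    doms_list <- vector("list", G)
    for (sp in plan[[g]]) {
      prots[sp$rank + 1] <- sp$protein
      types[sp$rank + 1] <- sp$type
      if (length(sp$doms) > 0)
        doms_list[[sp$rank + 1]] <- list(acc = sp$doms, ev = sp$dom_ev)
    }
    # random Pfam hits on a fraction of the background genes
    fill_idx <- which(types == "filler")
    n_dom <- floor(cfg$filler_domain_frac * length(fill_idx))
    if (n_dom > 0) {
      for (i in sample(fill_idx, n_dom))
        doms_list[[i]] <- list(acc = sprintf("PF%05d", sample(10000:99999, 1)),
                               ev = 10^runif(1, -30, -6))
    }
    lens_nt <- 3 * nchar(prots) + 3
    gaps <- sample(20:180, G, replace = TRUE)
    starts <- cumsum(c(1, head(lens_nt + gaps, -1)))
    strands <- sample(c("+", "-"), G, replace = TRUE)
    # neighbor family genes share the anchor's strand (operon-like layout)
    a <- anchor_rank[g]
    if (g %in% neighbor_genomes) {
      fr <- intersect(c(a - 1, a + 1), fam_ranks[[g]])
      strands[fr + 1] <- strands[a + 1]
    }
    ids <- id_of(g, seq_len(G) - 1)
    genes[[gi]] <- data.frame(
      gene_id = ids, genome_id = g, contig_id = paste0(g, "_c1"),
      start = starts - 1L, end = starts - 1L + lens_nt,
      strand = strands, protein = prots, stringsAsFactors = FALSE)
    for (i in seq_len(G)) {
      if (!is.null(doms_list[[i]]))
        hits[[length(hits) + 1]] <- data.frame(
          gene_id = ids[i], domain_acc = doms_list[[i]]$acc,
          evalue = doms_list[[i]]$ev, stringsAsFactors = FALSE)
    }
    type_of[[g]] <- setNames(types, ids)
  }
  gs <- genome_set(do.call(rbind, genes), domain_hits = do.call(rbind, hits),
                   taxonomy = classes)

  all_types <- unlist(unname(type_of))
  ids_by_type <- split(names(all_types), all_types)
  family_ids <- sort(ids_by_type[["family"]])
  anchor_ids <- sort(ids_by_type[["cuto"]])
  cueo_ids <- sort(ids_by_type[["cueo"]])
  ftsp_ids <- if ("ftsp" %in% names(ids_by_type)) sort(ids_by_type[["ftsp"]]) else character(0)
  cutg_ids <- if ("cutg" %in% names(ids_by_type)) sort(ids_by_type[["cutg"]]) else character(0)
  annotation_ids <- if ("annotation" %in% names(ids_by_type))
    sort(ids_by_type[["annotation"]]) else character(0)
  decoys <- lapply(setNames(nm = paste0("decoy_", names(cfg$n_decoys))),
                   function(t) if (t %in% names(ids_by_type))
                     sort(ids_by_type[[t]]) else character(0))
  names(decoys) <- names(cfg$n_decoys)

  neighbor_pairs <- do.call(rbind, lapply(neighbor_genomes, function(g) {
    fr <- intersect(c(anchor_rank[g] - 1, anchor_rank[g] + 1), fam_ranks[[g]])
    data.frame(anchor_id = id_of(g, anchor_rank[g]),
               family_id = id_of(g, fr[1]), stringsAsFactors = FALSE)
  }))
  annotated_family <- vapply(annotated_rows, function(i)
    id_of(fam_slots$g[i], fam_slots$rank[i]), character(1))

  truth <- structure(list(
    family_ids = family_ids, anchor_ids = anchor_ids,
    cueo_ids = cueo_ids, ftsp_ids = ftsp_ids, cutg_ids = cutg_ids,
    annotation_ids = annotation_ids, decoy_ids = decoys,
    neighbor_pairs = neighbor_pairs,
    hosting_genomes = hosting, both_genomes = both_genomes,
    annotated_family_ids = annotated_family,
    exemplars = c(CutO = anchor_ids[1], CueO = cueo_ids[1],
                  FtsP = if (length(ftsp_ids) > 0) ftsp_ids[1] else NA_character_),
    seed_protein = fam$protein, protected_positions = fam$protected,
    expected = list(
      neighbor_fraction = N_neighbor / n,
      genome_fraction = H / n,
      both_families_fraction = N_both / n,
      annotation_fraction = length(annotated_rows) / cfg$family_size,
      assoc_fraction = N_neighbor / cfg$family_size,
      cueo_genome_fraction = .round_half_up(cfg$cueo_family_cooccur * cfg$n_cueo) / cfg$n_cueo,
      ftsp_genome_fraction = .round_half_up(cfg$ftsp_family_cooccur * cfg$n_ftsp) /
        max(cfg$n_ftsp, 1),
      class_share_pct = 100 * cfg$family_class_counts / cfg$family_size)
  ), class = "synth_truth")

  list(genomes = gs, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d family | %d CutO anchors | %d CueO | %d FtsP | %d CutG | %d decoys\n",
              length(x$family_ids), length(x$anchor_ids), length(x$cueo_ids),
              length(x$ftsp_ids), length(x$cutg_ids),
              length(unlist(x$decoy_ids))))
  e <- x$expected
  cat(sprintf("  planted: neighbor %.3f | genome %.3f | both %.3f | annot %.3f\n",
              e$neighbor_fraction, e$genome_fraction, e$both_families_fraction,
              e$annotation_fraction))
  invisible(x)
}

#' Precision/recall of a predicted family against planted truth
#'
#' @param predicted a `family_set` (its `final_members` are used) or a
#'   character vector of gene ids.
#' @param truth a `synth_truth`.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  stopifnot(inherits(truth, "synth_truth"))
  ids <- if (inherits(predicted, "family_set")) predicted$final_members
         else as.character(predicted)
  tp <- length(intersect(ids, truth$family_ids))
  fp <- length(setdiff(ids, truth$family_ids))
  fn <- length(setdiff(truth$family_ids, ids))
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Write the synthetic truth record as JSON
#' @param truth a `synth_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
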