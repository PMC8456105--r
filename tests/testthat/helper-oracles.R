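# Shared fixtures and independent brute-force oracles for the test suite.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A small deterministic genome set: two genomes, hand-placed genes.
# Layout (ranks): G1/c1 has 10 genes; the anchor "a1" sits at rank 4 with a
# family gene "f1" at rank 5. G2/c1 has 6 genes, no family gene.
tiny_genome_set <- function() {
  mk <- function(genome, contig, n, prefix) {
    data.frame(
      gene_id = sprintf("%s_%d", prefix, seq_len(n)),
      genome_id = genome, contig_id = contig,
      start = (seq_len(n) - 1) * 1000, end = (seq_len(n) - 1) * 1000 + 300,
      strand = rep(c("+", "-"), length.out = n),
      protein = vapply(seq_len(n), function(i) rand_protein(50), character(1)),
      stringsAsFactors = FALSE)
  }
  set.seed(99)
  genes <- rbind(mk("G1", "c1", 10, "g1"), mk("G2", "c1", 6, "g2"))
  hits <- data.frame(
    gene_id = c("g1_5", "g1_5", "g2_3", "g2_3", "g2_3", "g1_9"),
    domain_acc = c("PF00394", "PF07731", "PF00394", "PF07731", "PF07732",
                   "PF07732"),
    evalue = c(1e-50, 1e-40, 1e-60, 1e-50, 1e-45, 1e-30),
    stringsAsFactors = FALSE)
  genome_set(genes, domain_hits = hits,
             taxonomy = c(G1 = "alpha", G2 = "beta"))
}

# Exhaustive local-alignment oracle (affine gaps, gap of length k costs
# open + k*ext). Enumerates every alignment path from every start cell;
# feasible only for very short sequences.
brute_local_score <- function(a, b, sub, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- 0
  rec <- function(i, j, state, sc) {
    best <<- max(best, sc)
    if (i <= n && j <= m) rec(i + 1, j + 1, 0L, sc + sub[ca[i], cb[j]])
    if (i <= n) rec(i + 1, j, 1L, sc - if (state == 1L) ext else open + ext)
    if (j <= m) rec(i, j + 1, 2L, sc - if (state == 2L) ext else open + ext)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, 0L, 0)
  best
}

# Brute-force profile-HMM path enumeration: returns log2-odds forward and
# viterbi scores by explicit enumeration of every state path.
brute_hmm_scores <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  M <- hmm$M
  me <- hmm$match_emissions; ie <- hmm$insert_emissions
  tm <- hmm$transitions$tm; ti <- hmm$transitions$ti; td <- hmm$transitions$td
  probs <- numeric(0)
  rec <- function(state, k, i, p) {
    if (p == 0) return()
    # possible successor states of (state, k)
    step <- function(s2, k2, tp) {
      if (tp == 0) return()
      if (s2 == "E") {
        if (i == n) probs <<- c(probs, p * tp)
        return()
      }
      emits <- s2 %in% c("M", "I")
      if (emits) {
        if (i + 1 > n) return()
        e <- if (s2 == "M") me[k2, chars[i + 1]] else ie[k2 + 1, chars[i + 1]]
        rec(s2, k2, i + 1, p * tp * e)
      } else rec(s2, k2, i, p * tp)
    }
    if (state == "M") {
      if (k < M) step("M", k + 1, tm[k + 1, 1]) else step("E", 0, tm[k + 1, 1])
      step("I", k, tm[k + 1, 2])
      if (k + 1 <= M) step("D", k + 1, tm[k + 1, 3])
    } else if (state == "I") {
      if (k < M) step("M", k + 1, ti[k + 1, 1]) else step("E", 0, ti[k + 1, 1])
      step("I", k, ti[k + 1, 2])
    } else {
      if (k < M) step("M", k + 1, td[k + 1, 1]) else step("E", 0, td[k + 1, 1])
      if (k + 1 <= M) step("D", k + 1, td[k + 1, 2])
    }
  }
  rec("M", 0L, 0L, 1)
  if (length(probs) == 0) return(list(forward = -Inf, viterbi = -Inf))
  null <- prod(hmm$background[match(chars, AA)])
  list(forward = log2(sum(probs) / null), viterbi = log2(max(probs) / null))
}

# sliding-window motif oracle: positions where pattern matches, literal by
# literal (X in the pattern matches anything; X in the protein matches no
# literal)
brute_motif_positions <- function(protein, pattern) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(protein, "")[[1]]
  w <- length(pc)
  hits <- integer(0)
  if (length(sc) < w) return(hits)
  for (s in 1:(length(sc) - w + 1)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (pc[k] != "X" && sc[s + k - 1] != pc[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# union-find component oracle for graphs given as an edge list over ids
uf_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges) > 0)
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  vapply(ids, find, character(1))
}

# unrooted bipartition multiset of a phylo tree, as canonical strings
tree_bipartitions <- function(tree) {
  sort(names(coppermine:::.bipartitions(tree)))
}
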