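# a genome set with hand-placed windows for the trivial cases
cooc_fixture <- function() {
  set.seed(71)
  mk <- function(genome, n) data.frame(
    gene_id = sprintf("%s_g%02d", genome, 1:n), genome_id = genome,
    contig_id = paste0(genome, "_c"), start = (1:n) * 1000,
    end = (1:n) * 1000 + 400, strand = "+",
    protein = replicate(n, rand_protein(40)), stringsAsFactors = FALSE)
  genome_set(rbind(mk("A", 30), mk("B", 30), mk("C", 30)),
             taxonomy = c(A = "alpha", B = "alpha", C = "beta"))
}

test_that("neighbor fraction handles the 0 and 1 extremes", {
  gs <- cooc_fixture()
  cluster <- c("A_g15", "B_g15", "C_g15")
  expect_equal(neighbor_fraction(gs, cluster, character(0)), 0)
  adjacent <- c("A_g16", "B_g14", "C_g16")
  expect_equal(neighbor_fraction(gs, cluster, adjacent), 1)
  # beyond the radius the neighbor is invisible
  expect_equal(neighbor_fraction(gs, "A_g15", "A_g28", radius = 10), 0)
  expect_equal(neighbor_fraction(gs, "A_g15", "A_g28", radius = 13), 1)
})

test_that("genome and multi-family co-occurrence count genome membership", {
  gs <- cooc_fixture()
  cluster <- c("A_g15", "B_g15", "C_g15")
  expect_equal(genome_cooccurrence(gs, cluster, c("A_g01", "B_g01", "C_g01")), 1)
  expect_equal(genome_cooccurrence(gs, cluster, character(0)), 0)
  expect_equal(genome_cooccurrence(gs, cluster, "A_g01"), 1 / 3)
  expect_equal(multi_family_cooccurrence(gs, cluster, c("A_g01", "B_g01"),
                                         character(0)), 0)
  expect_equal(multi_family_cooccurrence(gs, cluster,
                                         c("A_g01", "B_g01", "C_g01"),
                                         c("A_g02", "B_g02", "C_g02")), 1)
  expect_equal(multi_family_cooccurrence(gs, cluster,
                                         c("A_g01", "B_g01"), "A_g02"), 1 / 3)
})

test_that("reversed association and annotation fractions mirror the window logic", {
  gs <- cooc_fixture()
  fam <- c("A_g10", "B_g10", "C_g10")
  expect_equal(family_gene_assoc_fraction(gs, fam, character(0)), 0)
  expect_equal(family_gene_assoc_fraction(gs, fam, c("A_g11", "B_g09", "C_g12")), 1)
  expect_equal(family_gene_assoc_fraction(gs, fam, "A_g11"), 1 / 3)
  expect_equal(neighborhood_annotation_fraction(gs, fam, character(0)), 0)
  expect_equal(neighborhood_annotation_fraction(gs, fam, gs$genes$gene_id), 1)
})

test_that("per-class rates normalize by proteome counts", {
  gs <- cooc_fixture()  # alpha: 2 proteomes (A, B); beta: 1 (C)
  fam <- c(sprintf("A_g%02d", 1:4), sprintf("C_g%02d", 1:2))
  pc <- per_class_rates(gs, fam)
  alpha <- pc[pc$class == "alpha", ]; beta <- pc[pc$class == "beta", ]
  expect_equal(alpha$count, 4); expect_equal(beta$count, 2)
  expect_equal(alpha$share_pct, 100 * 4 / 6)
  expect_equal(beta$share_pct, 100 * 2 / 6)
  expect_equal(alpha$per_proteome, 2)       # 4 genes over 2 proteomes
  expect_equal(beta$per_proteome, 2)        # equal rate despite half the count
  expect_equal(sum(pc$share_pct), 100, tolerance = 1e-9)
  one <- per_class_rates(gs, "C_g01")
  expect_equal(one$share_pct[one$class == "beta"], 100)
})

test_that("fractions are invariant under genome relabeling", {
  out <- generate_synthetic(synth_config(
    n_genomes = 6, genes_per_genome = 150,
    class_counts = c(alpha = 3, beta = 1, gamma = 1, delta = 1),
    family_size = 8, family_class_counts = c(alpha = 4, beta = 2, gamma = 1, delta = 1),
    n_cueo = 2, n_ftsp = 2,
    n_decoys = c(small_no_motif = 4, motif_domain = 4, motif_outside = 4,
                 large_motif = 4), seed = 72))
  gs <- out$genomes; tr <- out$truth
  v1 <- c(neighbor_fraction(gs, tr$anchor_ids, tr$family_ids),
          genome_cooccurrence(gs, tr$anchor_ids, tr$family_ids))
  gs2 <- gs
  relabel <- function(x) paste0("X", x)
  gs2$genes$genome_id <- relabel(gs2$genes$genome_id)
  names(gs2$taxonomy) <- relabel(names(gs2$taxonomy))
  v2 <- c(neighbor_fraction(gs2, tr$anchor_ids, tr$family_ids),
          genome_cooccurrence(gs2, tr$anchor_ids, tr$family_ids))
  expect_equal(v1, v2)
})

test_that("planted co-occurrence rates are recovered exactly", {
  out <- generate_synthetic(synth_config(
    n_genomes = 10, genes_per_genome = 150,
    class_counts = c(alpha = 5, beta = 2, gamma = 2, delta = 1),
    family_size = 12, family_class_counts = c(alpha = 6, beta = 3, gamma = 2, delta = 1),
    n_cueo = 4, n_ftsp = 2,
    n_decoys = c(small_no_motif = 8, motif_domain = 8, motif_outside = 8,
                 large_motif = 8), seed = 73))
  gs <- out$genomes; tr <- out$truth; e <- tr$expected
  expect_identical(neighbor_fraction(gs, tr$anchor_ids, tr$family_ids),
                   e$neighbor_fraction)
  expect_identical(genome_cooccurrence(gs, tr$anchor_ids, tr$family_ids),
                   e$genome_fraction)
  expect_identical(multi_family_cooccurrence(gs, tr$anchor_ids, tr$family_ids,
                                             tr$cutg_ids),
                   e$both_families_fraction)
  expect_identical(neighborhood_annotation_fraction(gs, tr$family_ids,
                                                    tr$annotation_ids),
                   e$annotation_fraction)
  mco <- c(tr$anchor_ids, tr$cueo_ids, tr$ftsp_ids)
  expect_identical(family_gene_assoc_fraction(gs, tr$family_ids, mco),
                   e$assoc_fraction)
  # a window neighbor implies genome co-occurrence
  expect_lte(neighbor_fraction(gs, tr$anchor_ids, tr$family_ids),
             genome_cooccurrence(gs, tr$anchor_ids, tr$family_ids))
})

test_that("the report writer emits consistent TSV and JSON", {
  gs <- cooc_fixture()
  rep <- cooccurrence_report(gs, c("A_g15", "B_g15"), c("A_g16", "C_g05"),
                             family_b = "A_g02", annotation = "A_g14")
  expect_equal(rep$neighbor_fraction, 0.5)
  expect_equal(rep$genome_fraction, 0.5)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cooccurrence_report(rep, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(tab$value[tab$statistic == "neighbor_fraction"], 0.5)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$genome_fraction, 0.5)
})
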