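test_that("motif scanning reports 1-based, overlapping matches", {
  spec <- motif_spec("CXXXC", region = NULL)
  m <- scan_motif("MACAAHCR", spec)          # C at 3, H may be an X
  expect_equal(m$start, 3L)
  expect_equal(nrow(scan_motif("AAAA", spec)), 0)
  expect_equal(scan_motif("CCCCCC", spec)$start, c(1L, 2L))  # overlapping
})

test_that("X in the protein never matches a literal, but wildcards do", {
  spec <- motif_spec("CXXC", region = NULL)
  expect_equal(scan_motif("CAXC", spec)$start, 1L)   # X under a wildcard
  expect_equal(nrow(scan_motif("XAAC", spec)), 0)    # X under a literal C
})

test_that("motif scanner agrees with the sliding-window oracle", {
  set.seed(21)
  specs <- list(motif_spec("CXXXC", region = NULL),
                motif_spec("CXXC", region = NULL),
                motif_spec("PP", region = NULL))
  for (i in 1:200) {
    p <- rand_protein(sample(5:60, 1), alphabet = c("A", "C", "P", "G"))
    for (spec in specs) {
      got <- scan_motif(p, spec)$start
      expect_identical(got, brute_motif_positions(p, spec$patterns[1]),
                       info = paste(spec$patterns[1], p))
    }
  }
})

test_that("motif pattern validation requires two literals", {
  expect_error(motif_spec("CXXX"), "2 literal")
  expect_error(motif_spec("CXB1C"), "invalid character")
})

test_that("C-terminal PP detection is restricted to the tail", {
  expect_true(has_cterm_pp("MAAPEPEGPPPRL"))            # PP in last 15
  expect_false(has_cterm_pp(paste0("PP", strrep("A", 18))))  # PP only at N-term
  expect_false(has_cterm_pp("AP"))
  expect_true(has_cterm_pp("PP"))
  expect_error(has_cterm_pp("APPA", tail_len = 1))
})

test_that("the signal-peptide heuristic detects the tripartite structure", {
  sp <- predict_signal_peptide(paste0("MKKLLLALLALLAVSAQA", strrep("D", 30)))
  expect_true(sp$has_sp)
  expect_equal(sp$cleavage_pos, 18L)
  expect_gte(sp$score, 1.6)
  # no charge, no hydrophobic core
  expect_false(predict_signal_peptide(strrep("D", 60))$has_sp)
  # too short to call
  short <- predict_signal_peptide(strrep("A", 20))
  expect_false(short$has_sp)
  expect_equal(short$score, 0)
  # charged but no h-region
  expect_false(predict_signal_peptide(paste0("MKK", strrep("D", 40)))$has_sp)
})

test_that("planted signal peptides are detected with high sensitivity", {
  out <- generate_synthetic(synth_config(
    n_genomes = 6, genes_per_genome = 150,
    class_counts = c(alpha = 3, beta = 1, gamma = 1, delta = 1),
    family_size = 10, family_class_counts = c(alpha = 5, beta = 3, gamma = 1, delta = 1),
    n_cueo = 2, n_ftsp = 2,
    n_decoys = c(small_no_motif = 5, motif_domain = 5, motif_outside = 5,
                 large_motif = 5), seed = 31))
  calls <- predict_signal_peptides(out$genomes, out$truth$family_ids)
  expect_gte(mean(calls$has_sp), 0.9)
})

test_that("apply_rules conjugates the five flags", {
  set.seed(23)
  # the CutF archetype: 118 aa, signal, central CXXXC, C-terminal PP, no domain
  body <- rand_protein(86, alphabet = c("A", "D", "E", "G"))
  archetype <- paste0("MKKLLLALLALLAVSAQA",        # 18-residue signal
                      substr(body, 1, 40), "CAAHC", substr(body, 41, 86),
                      "PEPEGPPPR")                 # 118 aa total
  expect_equal(nchar(archetype), 118)
  big <- paste0(archetype, rand_protein(52, alphabet = "A"))  # 170 aa
  genes <- data.frame(
    gene_id = c("arch", "arch_dom", "big"), genome_id = "G", contig_id = "c",
    start = c(0, 1000, 2000), end = c(500, 1500, 2500), strand = "+",
    protein = c(archetype, archetype, big), stringsAsFactors = FALSE)
  gs <- genome_set(genes, domain_hits = data.frame(
    gene_id = "arch_dom", domain_acc = "PF12345", evalue = 1e-10))
  dec <- apply_rules(gs)
  dec <- dec[match(c("arch", "arch_dom", "big"), dec$gene_id), ]
  expect_true(dec$passed[1])
  # any domain hit at the ceiling fails the no-known-domain rule
  expect_false(dec$no_known_domain[2]); expect_false(dec$passed[2])
  # 170 aa fails the strict <170 size rule even with all else intact
  expect_false(dec$size_ok[3]); expect_false(dec$passed[3])
  expect_identical(dec$passed, dec$size_ok & dec$no_known_domain &
                     dec$signal_ok & dec$internal_motif_ok & dec$cterm_pp_ok)
})

test_that("adding a domain hit is monotone: it can only revoke a pass", {
  out <- generate_synthetic(synth_config(
    n_genomes = 6, genes_per_genome = 150,
    class_counts = c(alpha = 3, beta = 1, gamma = 1, delta = 1),
    family_size = 10, family_class_counts = c(alpha = 5, beta = 3, gamma = 1, delta = 1),
    n_cueo = 2, n_ftsp = 2,
    n_decoys = c(small_no_motif = 5, motif_domain = 5, motif_outside = 5,
                 large_motif = 5), seed = 32))
  gs <- out$genomes
  ids <- c(out$truth$family_ids, sample(gs$genes$gene_id, 20))
  before <- apply_rules(gs, ids)
  gs2 <- add_domain_hits(gs, data.frame(gene_id = ids, domain_acc = "PFX",
                                        evalue = 1e-9))
  after <- apply_rules(gs2, ids)
  expect_true(all(!after$passed))
  expect_true(all(after$passed <= before$passed))
})

test_that("external signal calls take precedence over the heuristic", {
  gs <- tiny_genome_set()
  ids <- gs$genes$gene_id[1:3]
  ext <- data.frame(gene_id = ids, has_sp = TRUE)
  dec <- apply_rules(gs, ids, signal_calls = ext)
  expect_true(all(dec$signal_ok))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(ext, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_signal_table(f)
  expect_identical(tab$has_sp, rep(TRUE, 3))
})

test_that("the motif region restriction rejects terminal motifs", {
  prot <- paste0("CAAHC", strrep("A", 108), "CAAHC")  # motifs only at ends
  genes <- data.frame(gene_id = "g", genome_id = "G", contig_id = "c",
                      start = 0, end = 400, strand = "+", protein = prot,
                      stringsAsFactors = FALSE)
  gs <- genome_set(genes)
  dec <- apply_rules(gs, signal_calls = data.frame(gene_id = "g", has_sp = TRUE))
  expect_false(dec$internal_motif_ok)
  dec2 <- apply_rules(gs, signal_calls = data.frame(gene_id = "g", has_sp = TRUE),
                      spec = motif_spec(c("CXXXC", "CXXC"), region = NULL))
  expect_true(dec2$internal_motif_ok)
})
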