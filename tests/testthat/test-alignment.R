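test_that("local alignment scores match simple closed forms", {
  expect_equal(smith_waterman("AAA", "AAA")$score, 12)  # 3 x BLOSUM62 A:A
  expect_equal(smith_waterman("AAA", "TTT")$score, 0)   # empty local alignment
  expect_error(smith_waterman("ABZ", "AAA"), "invalid residue")
  # global self-alignment equals the diagonal substitution sum
  set.seed(41)
  for (i in 1:10) {
    s <- rand_protein(sample(5:30, 1))
    chars <- strsplit(s, "")[[1]]
    b62 <- coppermine:::.blosum62()
    expect_equal(needleman_wunsch(s, s)$score,
                 sum(b62[cbind(chars, chars)]))
  }
})

test_that("local alignment is symmetric and non-negative", {
  set.seed(42)
  for (i in 1:50) {
    a <- rand_protein(sample(3:25, 1))
    b <- rand_protein(sample(3:25, 1))
    sab <- smith_waterman(a, b)$score
    expect_gte(sab, 0)
    expect_equal(sab, smith_waterman(b, a)$score)
  }
})

test_that("local alignment equals the exhaustive path-enumeration oracle", {
  set.seed(43)
  b62 <- coppermine:::.blosum62()
  for (i in 1:25) {
    a <- rand_protein(sample(1:3, 1))
    b <- rand_protein(sample(1:3, 1))
    expect_equal(smith_waterman(a, b)$score, brute_local_score(a, b, b62),
                 info = paste(a, b))
  }
})

test_that("pairwise scores agree with Biostrings as independent oracle", {
  set.seed(44)
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (i in 1:40) {
    a <- rand_protein(sample(2:6, 1))
    b <- rand_protein(sample(2:6, 1))
    loc <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = env$BLOSUM62,
                                         gapOpening = 11, gapExtension = 1,
                                         type = "local", scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b)$score, max(loc, 0), info = paste(a, b))
    glob <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = env$BLOSUM62,
                                          gapOpening = 11, gapExtension = 1,
                                          type = "global", scoreOnly = TRUE)
    expect_equal(needleman_wunsch(a, b)$score, glob, info = paste(a, b))
  }
})

test_that("alignment rows degap to their inputs", {
  set.seed(45)
  for (i in 1:20) {
    a <- rand_protein(sample(4:20, 1)); b <- rand_protein(sample(4:20, 1))
    g <- needleman_wunsch(a, b)
    expect_equal(gsub("-", "", g$rows[["a"]]), a)
    expect_equal(gsub("-", "", g$rows[["b"]]), b)
    l <- smith_waterman(a, b)
    expect_true(grepl(gsub("-", "", l$rows[["a"]]), a, fixed = TRUE))
    expect_true(grepl(gsub("-", "", l$rows[["b"]]), b, fixed = TRUE))
  }
})

test_that("percent identity counts gaps in the denominator", {
  expect_equal(percent_identity(needleman_wunsch("ACDEF", "ACDEF")), 100)
  aln <- structure(list(rows = c(a = "AAAA", b = "AAAT"), score = 0,
                        kind = "global"), class = "alignment")
  expect_equal(percent_identity(aln), 75)
  expect_equal(percent_identity(needleman_wunsch("AA", "AAAA")), 50)
  empty <- structure(list(rows = c(a = "", b = ""), score = 0, kind = "local"),
                     class = "alignment")
  expect_error(percent_identity(empty), "zero-length")
})

test_that("k-mer distance equals the set-arithmetic oracle", {
  expect_equal(kmer_distance("ACDEFG", "ACDEFG"), 0)
  expect_equal(kmer_distance("AAAAAA", "CDCDCD"), 1)   # disjoint k-mer sets
  expect_equal(kmer_distance("AC", "AD"), 1)           # below k, unequal
  expect_equal(kmer_distance("AC", "AC"), 0)
  set.seed(46)
  km <- function(s, k) unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  for (i in 1:100) {
    a <- rand_protein(sample(3:15, 1), alphabet = c("A", "C", "D"))
    b <- rand_protein(sample(3:15, 1), alphabet = c("A", "C", "D"))
    ka <- km(a, 3); kb <- km(b, 3)
    want <- if (identical(a, b)) 0 else
      1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
    expect_equal(kmer_distance(a, b), want)
  }
})

test_that("progressive alignment handles identical and near-identical inputs", {
  m <- progressive_msa(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
  expect_false(any(grepl("-", m)))
  expect_equal(unname(nchar(m)), rep(5L, 3))
  # single-deletion pair aligns with one gap column
  m2 <- progressive_msa(c(x = "ACDEFG", y = "ACEFG"))
  expect_equal(unname(m2["x"]), "ACDEFG")
  expect_equal(unname(m2["y"]), "AC-EFG")
})

test_that("MSA rows always degap to their inputs", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    base <- rand_protein(sample(20:40, 1))
    seqs <- setNames(vapply(1:n, function(j)
      mutate_member(base, 0.2), character(1)), paste0("s", 1:n))
    m <- progressive_msa(seqs)
    expect_equal(unique(nchar(m)), nchar(m[[1]]))
    for (nm in names(seqs))
      expect_equal(gsub("-", "", m[[nm]]), unname(seqs[nm]))
  }
})

test_that("motif-column curation removes rows lacking the conserved Cys", {
  rows <- c(ok1 = "ACDACG", ok2 = "ACDACG", mut = "AADAAG")
  cur <- curate_by_motif_columns(as_msa(rows))
  expect_equal(cur$removed_ids, "mut")
  expect_setequal(names(cur$msa), c("ok1", "ok2"))
  # rows removed never contain the residue in both top columns
  all_c <- as_msa(c(a = "CAC", b = "CGC", c = "CTC"))
  cur2 <- curate_by_motif_columns(all_c)
  expect_length(cur2$removed_ids, 0)
  expect_equal(unclass(cur2$msa), unclass(all_c))
})

test_that("column information content matches closed forms", {
  m1 <- as_msa(setNames(rep("A", 10), paste0("s", 1:10)))
  expect_equal(column_information(m1), log2(20))
  m2 <- as_msa(setNames(c(rep("A", 10), rep("V", 10)), paste0("s", 1:20)))
  expect_equal(column_information(m2), log2(20) - 1)
  m3 <- as_msa(setNames(AA, paste0("s", 1:20)))  # uniform over all residues
  expect_equal(column_information(m3), log2(20) - log2(20))
  m4 <- as_msa(setNames(c("A-", "A-"), c("x", "y")))
  expect_equal(column_information(m4), c(log2(20), 0))  # all-gap column -> 0
})

test_that("aligned FASTA round trips through the MSA object", {
  m <- progressive_msa(c(a = "ACDEFGHIK", b = "ACDEGHIK", c = "ACDEFGHIW"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(m, f)
  m2 <- read_msa_fasta(f)
  expect_equal(unclass(m2), unclass(m))
})
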