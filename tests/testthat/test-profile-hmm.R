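# small random MSA helper for model-construction tests
rand_msa <- function(n_rows, len, divergence = 0.2, gap_frac = 0) {
  base <- rand_protein(len)
  rows <- vapply(seq_len(n_rows), function(i) {
    s <- mutate_member(base, divergence)
    if (gap_frac > 0) {
      chars <- strsplit(s, "")[[1]]
      chars[runif(len) < gap_frac] <- "-"
      s <- paste(chars, collapse = "")
    }
    s
  }, character(1))
  as_msa(setNames(rows, paste0("s", seq_len(n_rows))))
}

test_that("match states follow the gap-fraction rule", {
  m <- as_msa(c(a = "ACDEF", b = "ACDEF"))
  expect_equal(build_hmm(m)$M, 5)
  # a column with 60% gaps is an insert column at the 50% threshold
  m2 <- as_msa(c(a = "A-C", b = "A-C", c = "AGC", d = "AGC", e = "A-C"))
  h2 <- build_hmm(m2)
  expect_equal(h2$M, 2)
  expect_equal(h2$match_columns, c(1L, 3L))
  expect_error(build_hmm(as_msa(c(a = "-", b = "-"))), "no column")
})

test_that("emission and transition groups are normalized distributions", {
  set.seed(51)
  for (i in 1:10) {
    h <- build_hmm(rand_msa(sample(2:8, 1), sample(5:30, 1),
                            gap_frac = runif(1, 0, 0.3)))
    expect_equal(rowSums(h$match_emissions), rep(1, h$M), tolerance = 1e-9)
    expect_equal(rowSums(h$insert_emissions), rep(1, h$M + 1), tolerance = 1e-9)
    expect_equal(rowSums(h$transitions$tm), rep(1, h$M + 1), tolerance = 1e-9)
    expect_equal(rowSums(h$transitions$ti), rep(1, h$M + 1), tolerance = 1e-9)
    expect_equal(rowSums(h$transitions$td), rep(1, h$M + 1), tolerance = 1e-9)
  }
})

test_that("a single pure match state scores log2(20) bits", {
  h <- build_hmm(as_msa(c(s1 = "A", s2 = "A")), pseudocount = 0)
  expect_equal(viterbi_score(h, "A"), log2(20))
  expect_equal(forward_score(h, "A"), log2(20))
})

test_that("forward and viterbi match brute-force path enumeration", {
  set.seed(52)
  for (i in 1:30) {
    msa <- rand_msa(sample(2:4, 1), sample(1:3, 1), divergence = 0.5,
                    gap_frac = if (i %% 3 == 0) 0.3 else 0)
    h <- try(build_hmm(msa), silent = TRUE)
    if (inherits(h, "try-error")) next
    for (L in 1:4) {
      s <- rand_protein(L)
      oracle <- brute_hmm_scores(h, s)
      expect_equal(forward_score(h, s), oracle$forward, tolerance = 1e-8,
                   info = paste("fwd", i, s))
      expect_equal(viterbi_score(h, s), oracle$viterbi, tolerance = 1e-8,
                   info = paste("vit", i, s))
    }
  }
})

test_that("forward dominates viterbi on random model/sequence pairs", {
  set.seed(53)
  for (i in 1:25) {
    h <- build_hmm(rand_msa(3, sample(4:12, 1), divergence = 0.4))
    for (j in 1:20) {
      s <- rand_protein(sample(2:20, 1))
      expect_gte(forward_score(h, s), viterbi_score(h, s) - 1e-9)
    }
  }
})

test_that("Gumbel calibration refuses tiny samples and yields sane E-values", {
  h <- build_hmm(rand_msa(4, 20, divergence = 0.2))
  expect_error(calibrate(h, n_random = 50), "unstable")
  hc <- calibrate(h, n_random = 400, seed = 9)
  mu <- hc$calibration[["mu"]]
  # P(S >= mu) = 1 - 1/e at the fitted location, so E(mu, N = 1) ~ 0.632
  expect_equal(hmm_evalue(hc, mu, 1), 1 - exp(-1), tolerance = 1e-9)
  # E-values are monotone decreasing in score
  sc <- seq(mu, mu + 30, length.out = 40)
  expect_true(all(diff(hmm_evalue(hc, sc, 100)) < 0))
})

test_that("maximum-likelihood Gumbel fit recovers known parameters", {
  set.seed(54)
  u <- runif(3000)
  x <- 3 - log(-log(u)) / 0.7          # Gumbel(mu = 3, lambda = 0.7)
  fit <- coppermine:::.fit_gumbel(x)
  expect_lt(abs(fit[["mu"]] - 3) / 3, 0.05)
  expect_lt(abs(fit[["lambda"]] - 0.7) / 0.7, 0.05)
})

test_that("database search recovers the seeds and demands calibration", {
  set.seed(55)
  base <- rand_protein(60)
  fam <- setNames(vapply(1:6, function(i) mutate_member(base, 0.15),
                         character(1)), paste0("m", 1:6))
  h <- build_hmm(progressive_msa(fam))
  expect_error(search_hmm(h, fam), "calibrate")
  hc <- calibrate(h, n_random = 400, seed = 10)
  db <- c(fam, setNames(vapply(1:50, function(i)
    rand_protein(sample(40:90, 1)), character(1)), paste0("bg", 1:50)))
  hits <- search_hmm(hc, db)
  expect_true(all(names(fam) %in% hits$target_id))       # self-recovery
  expect_true(all(diff(hits$evalue) >= 0))               # sorted by E
  expect_equal(nrow(search_hmm(hc, character(0))), 0)    # empty database
})

test_that("shuffled decoys rarely reach the inclusion threshold", {
  set.seed(56)
  base <- rand_protein(80)
  fam <- setNames(vapply(1:8, function(i) mutate_member(base, 0.2),
                         character(1)), paste0("m", 1:8))
  fp <- 0; total <- 0
  for (run in 1:20) {
    hc <- calibrate(build_hmm(progressive_msa(fam)), n_random = 300,
                    seed = run)
    decoys <- setNames(vapply(1:30, function(i)
      paste(sample(strsplit(base, "")[[1]]), collapse = ""), character(1)),
      paste0("d", 1:30))
    hits <- search_hmm(hc, decoys)
    fp <- fp + nrow(hits); total <- total + length(decoys)
  }
  expect_lte(fp / total, 0.05)
})

test_that("iterative search reaches a fixed point on seeds alone", {
  set.seed(57)
  base <- rand_protein(50)
  fam <- setNames(vapply(1:5, function(i) mutate_member(base, 0.1),
                         character(1)), paste0("m", 1:5))
  res <- iterative_search(progressive_msa(fam), fam, calib_n = 300, seed = 3)
  expect_true(res$converged)
  expect_equal(res$iterations_run, 1)      # first pass adds nothing new
  expect_setequal(res$final_members, names(fam))
})

test_that("iterative membership grows monotonically and is deterministic", {
  set.seed(58)
  base <- rand_protein(60)
  fam <- setNames(vapply(1:12, function(i) mutate_member(base, 0.25),
                         character(1)), paste0("m", 1:12))
  db <- c(fam, setNames(vapply(1:60, function(i)
    rand_protein(sample(40:90, 1)), character(1)), paste0("bg", 1:60)))
  seeds <- progressive_msa(fam[1:4])
  r1 <- iterative_search(seeds, db, calib_n = 300, seed = 7)
  r2 <- iterative_search(seeds, db, calib_n = 300, seed = 7)
  expect_identical(r1$final_members, r2$final_members)
  expect_identical(r1$members_by_iteration, r2$members_by_iteration)
  sizes <- vapply(r1$members_by_iteration, length, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_lte(r1$iterations_run, 11)
})

test_that("members matching a Pfam domain are removed from the final family", {
  set.seed(59)
  base <- rand_protein(50)
  fam <- setNames(vapply(1:6, function(i) mutate_member(base, 0.1),
                         character(1)), paste0("m", 1:6))
  doms <- data.frame(gene_id = "m3", domain_acc = "PF00001", evalue = 1e-20)
  res <- iterative_search(progressive_msa(fam[1:3]), fam, domain_hits = doms,
                          calib_n = 300, seed = 5)
  expect_true("m3" %in% res$members_by_iteration[[res$iterations_run]])
  expect_false("m3" %in% res$final_members)
  expect_equal(res$removed_pfam, "m3")
})

test_that("plain-text HMM serialization round trips", {
  set.seed(60)
  h <- calibrate(build_hmm(rand_msa(4, 15, gap_frac = 0.2)),
                 n_random = 200, seed = 1)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(h, f)
  h2 <- read_hmm(f)
  expect_equal(h2$M, h$M)
  expect_equal(h2$match_emissions, h$match_emissions, ignore_attr = TRUE)
  expect_equal(h2$transitions$tm, h$transitions$tm, ignore_attr = TRUE)
  expect_equal(h2$calibration, h$calibration, tolerance = 1e-12)
  s <- rand_protein(20)
  expect_equal(viterbi_score(h2, s), viterbi_score(h, s))
})
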