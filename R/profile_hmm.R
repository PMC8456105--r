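#' Build a profile HMM from a multiple alignment
#'
#' Columns with a gap fraction below `match_gap_frac` become match states
#' (the textbook 50% rule); all other columns feed the flanking insert
#' states. Emission and transition counts get Laplace pseudocounts and are
#' normalized. The model has match states M1..MM, insert states I0..IM and
#' delete states D1..DM with the transition set
#' \{M->M, M->I, M->D, I->M, I->I, D->M, D->D\}; transitions that cannot
#' exist at the last node carry probability 0.
#'
#' @param msa a `protein_msa` with >= 2 rows.
#' @param match_gap_frac gap-fraction threshold below which a column is a
#'   match column (default 0.5).
#' @param pseudocount Laplace pseudocount for emissions and transitions.
#' @param background length-20 background residue distribution (default
#'   uniform 1/20, removing any data dependency; database frequencies can be
#'   supplied instead).
#' @return A `profile_hmm` object (uncalibrated).
#' @export
build_hmm <- function(msa, match_gap_frac = 0.5, pseudocount = 1.0,
                      background = rep(1 / 20, 20)) {
  stopifnot(inherits(msa, "protein_msa"), length(msa) >= 2)
  stopifnot(length(background) == 20, all(background > 0))
  background <- background / sum(background)
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac < match_gap_frac)
  M <- length(match_cols)
  if (M == 0)
    stop("no column qualifies as a match state at gap fraction < ",
         match_gap_frac)
  is_match <- seq_len(ncol(mat)) %in% match_cols
  # node index (match columns to the left) for each column
  node_of <- cumsum(is_match)

  me <- matrix(pseudocount, M, 20, dimnames = list(NULL, AA20))
  ie <- matrix(pseudocount, M + 1, 20, dimnames = list(NULL, AA20))
  tm <- matrix(pseudocount, M + 1, 3,
               dimnames = list(NULL, c("MM", "MI", "MD")))
  ti <- matrix(pseudocount, M + 1, 2, dimnames = list(NULL, c("IM", "II")))
  td <- matrix(pseudocount, M + 1, 2, dimnames = list(NULL, c("DM", "DD")))

  for (r in seq_len(nrow(mat))) {
    states <- list(c("M", 0L))  # begin
    for (j in seq_len(ncol(mat))) {
      ch <- mat[r, j]
      if (is_match[j]) {
        k <- node_of[j]
        states[[length(states) + 1]] <- c(if (ch == "-") "D" else "M", k)
        if (ch %in% AA20) me[k, ch] <- me[k, ch] + 1
      } else if (ch != "-") {
        k <- node_of[j]
        states[[length(states) + 1]] <- c("I", k)
        if (ch %in% AA20) ie[k + 1, ch] <- ie[k + 1, ch] + 1
      }
    }
    states[[length(states) + 1]] <- c("M", M + 1L)  # end
    for (s in seq_len(length(states) - 1)) {
      from <- states[[s]]; to <- states[[s + 1]]
      k <- as.integer(from[2])
      # transitions outside the allowed set (I<->D) are not counted
      if (from[1] == "M") {
        if (to[1] == "M") tm[k + 1, "MM"] <- tm[k + 1, "MM"] + 1
        else if (to[1] == "I") tm[k + 1, "MI"] <- tm[k + 1, "MI"] + 1
        else tm[k + 1, "MD"] <- tm[k + 1, "MD"] + 1
      } else if (from[1] == "I") {
        if (to[1] == "M") ti[k + 1, "IM"] <- ti[k + 1, "IM"] + 1
        else if (to[1] == "I") ti[k + 1, "II"] <- ti[k + 1, "II"] + 1
      } else {
        if (to[1] == "M") td[k + 1, "DM"] <- td[k + 1, "DM"] + 1
        else if (to[1] == "D") td[k + 1, "DD"] <- td[k + 1, "DD"] + 1
      }
    }
  }
  # impossible transitions at the last node
  tm[M + 1, "MD"] <- 0
  td[M + 1, "DD"] <- 0
  td[1, ] <- c(1, 0)  # row for nonexistent D_0; never used in scoring

  # rows with zero mass (possible at pseudocount 0) stay 0: unreachable states
  norm <- function(m) { r <- rowSums(m); m[r > 0, ] <- m[r > 0, , drop = FALSE] / r[r > 0]; m }
  me <- norm(me); ie <- norm(ie); tm <- norm(tm); ti <- norm(ti); td <- norm(td)

  structure(list(M = M, match_emissions = me, insert_emissions = ie,
                 transitions = list(tm = tm, ti = ti, td = td),
                 background = background, match_columns = match_cols,
                 calibration = NULL, n_seqs = length(msa)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match states, built from %d sequences\n",
              x$M, x$n_seqs))
  if (is.null(x$calibration)) cat("  uncalibrated\n")
  else cat(sprintf("  Gumbel calibration: mu = %.3f, lambda = %.3f (n = %d)\n",
                   x$calibration[["mu"]], x$calibration[["lambda"]],
                   x$calib_n))
  invisible(x)
}

# log2 score parameterization for the C++ kernels
.hmm_logspace <- function(hmm) {
  lg <- function(p) ifelse(p > 0, log2(p), -1e30)
  list(me = lg(sweep(hmm$match_emissions, 2, hmm$background, "/")),
       ie = lg(sweep(hmm$insert_emissions, 2, hmm$background, "/")),
       tm = lg(hmm$transitions$tm), ti = lg(hmm$transitions$ti),
       td = lg(hmm$transitions$td))
}

.hmm_scores <- function(hmm, seqs, forward = FALSE) {
  ls <- .hmm_logspace(hmm)
  enc <- lapply(seqs, .aa_encode)
  as.numeric(.hmm_score_many_cpp(enc, ls$me, ls$ie, ls$tm, ls$ti, ls$td,
                                 forward))
}

#' Viterbi score of a sequence under a profile HMM
#'
#' Log-odds score in bits of the best state path versus the background
#' model.
#'
#' @param hmm a `profile_hmm`.
#' @param seq protein string.
#' @return numeric bit score.
#' @export
viterbi_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nzchar(seq))
  .hmm_scores(hmm, seq, forward = FALSE)
}

#' Forward score of a sequence under a profile HMM
#'
#' Log-odds bits summed over all state paths; always >= the Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return numeric bit score.
#' @export
forward_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nzchar(seq))
  .hmm_scores(hmm, seq, forward = TRUE)
}

# maximum-likelihood Gumbel fit (location mu, rate lambda = 1/scale)
.fit_gumbel <- function(x) {
  b0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * b0
  nll <- function(p) {
    b <- exp(p[2])
    z <- (x - p[1]) / b
    length(x) * p[2] + sum(z + exp(-z))
  }
  fit <- optim(c(mu0, log(b0)), nll, method = "BFGS")
  c(mu = fit$par[1], lambda = 1 / exp(fit$par[2]))
}

#' Calibrate a profile HMM for E-values
#'
#' Scores `n_random` sequences sampled from the background model (lengths
#' drawn from `length_model`) with Viterbi, and fits a Gumbel
#' location/rate (mu, lambda) to the score distribution by maximum
#' likelihood. The fit is stored on the model and drives all E-values.
#'
#' @param hmm a `profile_hmm`.
#' @param n_random number of null sequences (>= 100; the fit is unstable
#'   below that).
#' @param length_model integer vector of lengths to sample from. The
#'   default draws lengths within 20% of the model length: the glocal-style
#'   score is strongly length-dependent (inserted residues pay transition
#'   costs), so a length-matched null keeps the Gumbel fit sharp; longer
#'   database targets then score conservatively low.
#' @param seed RNG seed for the null sample.
#' @return The calibrated `profile_hmm`.
#' @export
calibrate <- function(hmm, n_random = 1000, length_model = NULL, seed = 1) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_random < 100)
    stop("n_random must be >= 100: the Gumbel fit is unstable on fewer samples")
  if (is.null(length_model))
    length_model <- max(20, round(0.8 * hmm$M)):round(1.2 * hmm$M)
  scores <- .with_seed(seed, {
    lens <- sample(length_model, n_random, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = hmm$background),
            collapse = ""), character(1))
    .hmm_scores(hmm, seqs, forward = FALSE)
  })
  hmm$calibration <- .fit_gumbel(scores)
  hmm$calib_n <- as.integer(n_random)
  hmm
}

#' E-value of a bit score under the fitted Gumbel null
#'
#' `E = N * P(S >= s)` with `P(S >= s) = 1 - exp(-exp(-lambda (s - mu)))`.
#'
#' @param hmm a calibrated `profile_hmm`.
#' @param score bit score(s).
#' @param n_targets database size N.
#' @return numeric E-value(s).
#' @export
hmm_evalue <- function(hmm, score, n_targets) {
  if (is.null(hmm$calibration))
    stop("model is uncalibrated; run calibrate() first")
  mu <- hmm$calibration[["mu"]]; lambda <- hmm$calibration[["lambda"]]
  n_targets * (-expm1(-exp(-lambda * (score - mu))))
}

#' Search a protein database with a profile HMM
#'
#' Viterbi-scores every database protein and reports hits with
#' `E <= evalue_include`, sorted by E-value (ties by target id).
#'
#' @param hmm a calibrated `profile_hmm`.
#' @param database a `genome_set` or named character vector of proteins.
#' @param evalue_include inclusion threshold (default 0.01).
#' @return data.frame `target_id`, `bit_score`, `evalue`.
#' @export
search_hmm <- function(hmm, database, evalue_include = 0.01) {
  if (is.null(hmm$calibration))
    stop("model is uncalibrated; run calibrate() before search_hmm()")
  prots <- if (inherits(database, "genome_set")) .proteins_of(database)
           else database
  if (length(prots) == 0)
    return(data.frame(target_id = character(0), bit_score = numeric(0),
                      evalue = numeric(0)))
  scores <- .hmm_scores(hmm, prots, forward = FALSE)
  ev <- hmm_evalue(hmm, scores, length(prots))
  keep <- which(ev <= evalue_include)
  out <- data.frame(target_id = names(prots)[keep], bit_score = scores[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out[order(out$evalue, out$target_id), , drop = FALSE]
}

#' Iterative profile-HMM family expansion
#'
#' The jackhmmer-style loop: build a model from the current alignment,
#' calibrate, search the database, add new hits, re-align the cumulative
#' member set with [progressive_msa()], and repeat until no new members are
#' found or `max_iter` is reached. After the loop, any member carrying a
#' Pfam-style domain annotation (at the E-value ceiling) is removed from the
#' final family.
#'
#' @param seed_msa curated `protein_msa` of the seed members (ids matching
#'   database entries where applicable).
#' @param database a `genome_set` (domain hits used for the removal rule)
#'   or named character vector of proteins.
#' @param domain_hits optional domain-hit data.frame when `database` is a
#'   plain vector.
#' @param max_iter maximum iterations (default 11).
#' @param evalue_include per-iteration inclusion threshold (default 0.01).
#' @param seed master RNG seed; per-iteration calibration seeds derive from
#'   it, so runs are reproducible.
#' @param calib_n null-sample size per calibration.
#' @param domain_evalue_max ceiling for a domain hit to trigger removal.
#' @param length_model passed to [calibrate()].
#' @return A `family_set`: list with `members_by_iteration` (cumulative,
#'   pre-removal), `final_members`, `removed_pfam`, `iteration_found`,
#'   `converged`, `iterations_run`, the final `msa`, `hmm` and hit table.
#' @export
iterative_search <- function(seed_msa, database, domain_hits = NULL,
                             max_iter = 11, evalue_include = 0.01, seed = 1,
                             calib_n = 1000, domain_evalue_max = 1e-5,
                             length_model = NULL) {
  stopifnot(inherits(seed_msa, "protein_msa"))
  if (inherits(database, "genome_set")) {
    prots <- .proteins_of(database)
    if (is.null(domain_hits)) domain_hits <- database$domain_hits
  } else prots <- database
  seed_prots <- setNames(gsub("-", "", unclass(seed_msa), fixed = TRUE),
                         names(seed_msa))
  all_prots <- c(prots, seed_prots[setdiff(names(seed_prots), names(prots))])

  members <- names(seed_msa)
  iteration_found <- setNames(rep(0L, length(members)), members)
  members_by_iteration <- list()
  msa <- seed_msa
  converged <- FALSE
  iterations_run <- 0L
  hits <- NULL
  hmm <- NULL
  for (it in seq_len(max_iter)) {
    iterations_run <- it
    hmm <- build_hmm(msa)
    hmm <- calibrate(hmm, n_random = calib_n, seed = (seed * 131 + it) %% 2147483647,
                     length_model = length_model)
    hits <- search_hmm(hmm, prots, evalue_include)
    new <- setdiff(hits$target_id, members)
    if (length(new) == 0) {
      members_by_iteration[[it]] <- members
      converged <- TRUE
      break
    }
    iteration_found[new] <- it
    members <- c(members, new)
    members_by_iteration[[it]] <- members
    if (it < max_iter)
      msa <- progressive_msa(all_prots[members])
  }
  h <- domain_hits
  with_dom <- if (is.null(h)) character(0)
              else unique(h$gene_id[h$evalue <= domain_evalue_max])
  removed <- intersect(members, with_dom)
  final <- setdiff(members, removed)
  structure(list(members_by_iteration = members_by_iteration,
                 final_members = final, removed_pfam = removed,
                 iteration_found = iteration_found, converged = converged,
                 iterations_run = iterations_run, msa = msa, hmm = hmm,
                 hits = hits),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("<family_set> %d final members (%d pre-removal), %d iteration(s), %s\n",
              length(x$final_members),
              length(x$members_by_iteration[[x$iterations_run]]),
              x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Write a profile HMM as a plain-text table
#'
#' One line per state row: `MATCH k <20 probs>`, `INSERT k <20 probs>`,
#' `TRANS_M|TRANS_I|TRANS_D k <probs>`, plus `BACKGROUND` and `CALIBRATION`
#' header lines.
#'
#' @param hmm a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("coppermine-hmm 1"), sprintf("M %d", hmm$M),
               paste("BACKGROUND", fmt(hmm$background)),
               if (is.null(hmm$calibration)) "CALIBRATION none"
               else paste("CALIBRATION", fmt(hmm$calibration))), con)
  for (k in seq_len(hmm$M))
    writeLines(paste("MATCH", k, fmt(hmm$match_emissions[k, ])), con)
  for (k in 0:hmm$M) {
    writeLines(paste("INSERT", k, fmt(hmm$insert_emissions[k + 1, ])), con)
    writeLines(paste("TRANS_M", k, fmt(hmm$transitions$tm[k + 1, ])), con)
    writeLines(paste("TRANS_I", k, fmt(hmm$transitions$ti[k + 1, ])), con)
    writeLines(paste("TRANS_D", k, fmt(hmm$transitions$td[k + 1, ])), con)
  }
  invisible(path)
}

#' Read a plain-text profile HMM written by [write_hmm()]
#' @param path input path.
#' @return A `profile_hmm`.
#' @export
read_hmm <- function(path) {
  ln <- readLines(path)
  if (!grepl("^coppermine-hmm", ln[1])) stop("not a coppermine HMM file: ", path)
  M <- as.integer(strsplit(ln[2], " ")[[1]][2])
  nums <- function(line) as.numeric(strsplit(line, " ")[[1]][-(1:2)])
  bg <- as.numeric(strsplit(ln[3], " ")[[1]][-1])
  calib_f <- strsplit(ln[4], " ")[[1]][-1]
  calibration <- if (identical(calib_f, "none")) NULL
                 else setNames(as.numeric(calib_f), c("mu", "lambda"))
  grab <- function(tag) {
    rows <- ln[grepl(paste0("^", tag, " "), ln)]
    do.call(rbind, lapply(rows, nums))
  }
  me <- grab("MATCH"); colnames(me) <- AA20
  ie <- grab("INSERT"); colnames(ie) <- AA20
  tm <- grab("TRANS_M"); colnames(tm) <- c("MM", "MI", "MD")
  ti <- grab("TRANS_I"); colnames(ti) <- c("IM", "II")
  td <- grab("TRANS_D"); colnames(td) <- c("DM", "DD")
  structure(list(M = M, match_emissions = me, insert_emissions = ie,
                 transitions = list(tm = tm, ti = ti, td = td),
                 background = bg, match_columns = NULL,
                 calibration = calibration,
                 calib_n = NA_integer_, n_seqs = NA_integer_),
            class = "profile_hmm")
}
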