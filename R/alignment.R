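#' Local (Smith-Waterman) pairwise alignment
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (a gap of length
#' k costs `gap_open + k * gap_extend`, the BLASTp 11/1 convention).
#' Traceback ties are broken diagonal > up > left, so the output is
#' deterministic.
#'
#' @param a,b uppercase protein strings (20 amino acids plus X).
#' @param gap_open,gap_extend affine gap parameters (defaults 11 and 1).
#' @return An `alignment` object: list with `rows` (two gap-extended
#'   strings), `score`, `kind = "local"` and the 1-based subject/query
#'   start/end coordinates. The empty alignment at score 0 is allowed.
#' @export
smith_waterman <- function(a, b, gap_open = 11, gap_extend = 1) {
  .pairwise(a, b, gap_open, gap_extend, local = TRUE)
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' @inheritParams smith_waterman
#' @return An `alignment` object with `kind = "global"`; degapped rows equal
#'   the input sequences.
#' @export
needleman_wunsch <- function(a, b, gap_open = 11, gap_extend = 1) {
  .pairwise(a, b, gap_open, gap_extend, local = FALSE)
}

.pairwise <- function(a, b, gap_open, gap_extend, local) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ia <- .aa_encode(a, "sequence a")
  ib <- .aa_encode(b, "sequence b")
  res <- .pairwise_align_cpp(ia, ib, .blosum62(), gap_open, gap_extend, local)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ra <- character(0); rb <- character(0)
  i <- res$a_start; j <- res$b_start
  for (op in res$ops) {
    if (op == 0L) { ra <- c(ra, ca[i]); rb <- c(rb, cb[j]); i <- i + 1; j <- j + 1 }
    else if (op == 1L) { ra <- c(ra, ca[i]); rb <- c(rb, "-"); i <- i + 1 }
    else { ra <- c(ra, "-"); rb <- c(rb, cb[j]); j <- j + 1 }
  }
  structure(list(rows = c(a = paste(ra, collapse = ""),
                          b = paste(rb, collapse = "")),
                 score = res$score, kind = if (local) "local" else "global",
                 a_start = res$a_start, a_end = res$a_end,
                 b_start = res$b_start, b_end = res$b_end),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<%s alignment> score %.1f, %d columns\n", x$kind, x$score,
              nchar(x$rows[1])))
  cat(" ", x$rows[1], "\n ", x$rows[2], "\n")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' 100 x identical columns / alignment length; gapped columns count in the
#' denominator (the conservative convention used for 90% node collapsing).
#'
#' @param aln an `alignment`.
#' @return numeric in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  n <- nchar(aln$rows[1])
  if (n == 0) stop("percent identity is undefined for a zero-length alignment")
  a <- strsplit(aln$rows[[1]], "")[[1]]
  b <- strsplit(aln$rows[[2]], "")[[1]]
  unname(100 * sum(a == b & a != "-") / n)
}

#' k-mer distance between two sequences
#'
#' `1 - |shared k-mers| / |k-mers of the smaller set|`, on k-mer sets
#' (not multisets). Identical sequences have distance 0; sequences shorter
#' than k have distance 1 unless equal. Used for guide-tree construction.
#'
#' @param a,b protein strings.
#' @param k word length (default 3).
#' @return numeric in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 3) {
  if (identical(a, b)) return(0)
  if (nchar(a) < k || nchar(b) < k) return(1)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

# frequency profile (20 x L) of a set of gapped rows; gaps and X contribute
# nothing, frequencies are relative to the number of rows
.msa_profile <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(mat)
  prof <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = AA20))
    prof[, j] <- as.numeric(tab) / nrow(mat)
  }
  prof
}

.apply_ops <- function(rows1, rows2, ops) {
  m1 <- do.call(rbind, strsplit(rows1, ""))
  m2 <- do.call(rbind, strsplit(rows2, ""))
  n_out <- length(ops)
  o1 <- matrix("-", nrow(m1), n_out)
  o2 <- matrix("-", nrow(m2), n_out)
  i <- 1L; j <- 1L
  for (c_out in seq_len(n_out)) {
    op <- ops[c_out]
    if (op != 2L) { o1[, c_out] <- m1[, i]; i <- i + 1L }
    if (op != 1L) { o2[, c_out] <- m2[, j]; j <- j + 1L }
  }
  c(setNames(apply(o1, 1, paste, collapse = ""), names(rows1)),
    setNames(apply(o2, 1, paste, collapse = ""), names(rows2)))
}

#' Progressive multiple sequence alignment
#'
#' UPGMA guide tree on [kmer_distance()], profiles merged by global affine
#' profile-profile alignment under BLOSUM62 expected-score columns.
#' Deterministic given input order (ties in the guide tree and tracebacks
#' are broken by fixed rules). An explicit stand-in for heavier aligners;
#' externally computed alignments can be substituted via
#' [read_msa_fasta()].
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param gap_open,gap_extend affine gap parameters for the profile merge.
#' @return A `protein_msa`: named character vector of equal-length,
#'   gap-extended rows (one per input, input order preserved).
#' @export
progressive_msa <- function(seqs, gap_open = 11, gap_extend = 1) {
  if (length(seqs) < 2) stop("progressive_msa needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must have unique names")
  for (i in seq_along(seqs)) .check_protein(seqs[i], names(seqs)[i])
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]])
  hc <- hclust(as.dist(D), method = "average")
  clusters <- lapply(seq_len(n), function(i) setNames(seqs[i], names(seqs)[i]))
  merged <- vector("list", nrow(hc$merge))
  getc <- function(k) if (k < 0) clusters[[-k]] else merged[[k]]
  for (r in seq_len(nrow(hc$merge))) {
    r1 <- getc(hc$merge[r, 1]); r2 <- getc(hc$merge[r, 2])
    res <- .profile_align_cpp(.msa_profile(r1), .msa_profile(r2),
                              .blosum62()[1:20, 1:20], gap_open, gap_extend)
    merged[[r]] <- .apply_ops(r1, r2, res$ops)
  }
  out <- merged[[nrow(hc$merge)]][names(seqs)]
  structure(out, class = "protein_msa")
}

#' Construct an MSA object from pre-aligned rows
#' @param rows named character vector of equal-length gapped sequences.
#' @return A `protein_msa`.
#' @export
as_msa <- function(rows) {
  rows <- unlist(rows)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("MSA rows must have unique names")
  if (length(unique(nchar(rows))) != 1)
    stop("MSA rows must have equal length")
  structure(rows, class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d rows x %d columns\n", length(x), nchar(x[1])))
  show <- head(x, 6)
  for (i in seq_along(show))
    cat(sprintf("  %-12s %s\n", names(show)[i],
                if (nchar(show[i]) > 60) paste0(substr(show[i], 1, 60), "...") else show[i]))
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Remove rows lacking the conserved motif residues
#'
#' Automation of the motif-alignment curation step: the `n_cols` alignment
#' columns with the highest frequency of `residue` (ties broken leftmost)
#' are taken as the motif columns; rows lacking `residue` in any of them are
#' removed. Columns left all-gap by the removal are dropped.
#'
#' @param msa a `protein_msa`.
#' @param residue the conserved residue (default `"C"`).
#' @param n_cols number of motif columns (default 2).
#' @return list with `msa` (pruned) and `removed_ids`.
#' @export
curate_by_motif_columns <- function(msa, residue = "C", n_cols = 2) {
  stopifnot(inherits(msa, "protein_msa"))
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  freq <- colMeans(mat == residue)
  if (all(freq == 0))
    stop("no alignment column contains residue ", sQuote(residue))
  cols <- order(-freq, seq_along(freq))[seq_len(min(n_cols, ncol(mat)))]
  keep <- apply(mat[, cols, drop = FALSE] == residue, 1, all)
  removed <- names(msa)[!keep]
  mat2 <- mat[keep, , drop = FALSE]
  nongap <- colSums(mat2 != "-") > 0
  mat2 <- mat2[, nongap, drop = FALSE]
  pruned <- as_msa(setNames(apply(mat2, 1, paste, collapse = ""),
                            names(msa)[keep]))
  list(msa = pruned, removed_ids = removed)
}

#' Per-column information content
#'
#' `log2(20)` minus the Shannon entropy of the residue frequencies in each
#' column; gaps (and X) are excluded from the counts, and all-gap columns
#' score 0 bits. No pseudocounts: this is a display statistic for sequence
#' logos, not a model.
#'
#' @param msa a `protein_msa`.
#' @return numeric vector of bits per column.
#' @export
column_information <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) return(0)
    p <- table(col) / length(col)
    H <- -sum(p * log2(p))
    log2(20) - H
  }, numeric(1))
}

#' Read an aligned (or plain) protein FASTA
#' @param path FASTA path; gaps as `-`.
#' @return A `protein_msa` if rows are equal length, else a named character
#'   vector of sequences.
#' @export
read_msa_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(rows))) == 1 && length(rows) > 0) as_msa(rows) else rows
}

#' Write sequences or an MSA to FASTA
#' @param seqs named character vector or `protein_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write per-column logo values as TSV
#' @param msa a `protein_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_table <- function(msa, path) {
  ic <- column_information(msa)
  write.table(data.frame(column = seq_along(ic), bits = ic), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
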