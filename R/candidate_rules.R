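#' Motif specification for the candidate filter
#'
#' Patterns are words over the 20 amino acids plus the wildcard `X`; the
#' default covers the CXXXC chaperone motif and its CXXC variation. The
#' optional `region` restricts where (as fractions of protein length) a
#' match must fall; the default keeps matches in the central 20-80% of the
#' protein.
#'
#' @param patterns character vector of motif patterns; each must contain at
#'   least two literal residues.
#' @param region length-2 numeric in `[0,1]` (start/end fraction), or `NULL`
#'   for no restriction.
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(patterns = c("CXXXC", "CXXC"), region = c(0.2, 0.8)) {
  for (p in patterns) {
    chars <- strsplit(p, "")[[1]]
    if (!all(chars %in% c(AA20, "X")))
      stop("invalid character in motif pattern ", sQuote(p))
    if (sum(chars != "X") < 2)
      stop("motif pattern ", sQuote(p), " needs at least 2 literal residues")
  }
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] >= 0, region[2] <= 1,
              region[1] < region[2])
  }
  structure(list(patterns = patterns, region = region), class = "motif_spec")
}

#' Scan a protein for motif matches
#'
#' Reports every (pattern, 1-based start) match; overlapping matches are all
#' reported. The wildcard `X` in a pattern matches any residue; an `X` in
#' the protein never matches a literal pattern residue.
#'
#' @param protein uppercase protein string.
#' @param spec a [motif_spec()].
#' @return data.frame with columns `pattern` and `start` (possibly 0 rows).
#' @export
scan_motif <- function(protein, spec = motif_spec()) {
  .check_protein(protein)
  out <- lapply(spec$patterns, function(p) {
    chars <- strsplit(p, "")[[1]]
    rx <- paste0(ifelse(chars == "X", "[A-Z]", chars), collapse = "")
    m <- gregexpr(paste0("(?=", rx, ")"), protein, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (length(starts) == 0)
      data.frame(pattern = character(0), start = integer(0))
    else data.frame(pattern = p, start = starts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test for a C-terminal PP motif
#'
#' `TRUE` iff the dipeptide `PP` occurs within the last `tail_len` residues.
#'
#' @param protein uppercase protein string.
#' @param tail_len tail length in residues (>= 2; default 15).
#' @return logical.
#' @export
has_cterm_pp <- function(protein, tail_len = 15) {
  stopifnot(tail_len >= 2)
  n <- nchar(protein)
  grepl("PP", substr(protein, max(1L, n - tail_len + 1L), n), fixed = TRUE)
}

#' Heuristic Sec signal-peptide call
#'
#' Deterministic stand-in for a neural signal-peptide predictor, built from
#' the classical tripartite architecture: a positively charged n-region
#' (at least one K/R among residues 2-5), a hydrophobic h-region (some
#' 8-residue window within residues 6..c-4 with mean Kyte-Doolittle
#' hydropathy >= `h_min`), and an A-X-A-type cleavage site (residues c-2 and
#' c both in `{A,G,S,T}`, cleavage after position c) for some c in
#' `[cleavage_range]`. External per-gene calls supplied via
#' [read_signal_table()] take precedence in the pipeline.
#'
#' @param protein uppercase protein string.
#' @param h_min minimum mean hydropathy of the h-region window.
#' @param cleavage_range allowed cleavage positions (last residue of the
#'   signal), default 15..40.
#' @return list with `has_sp` (logical), `cleavage_pos` (smallest valid c,
#'   or `NA`), `score` (best h-window hydropathy, 0 if too short to call).
#' @export
predict_signal_peptide <- function(protein, h_min = 1.6,
                                   cleavage_range = c(15L, 40L)) {
  .check_protein(protein)
  n <- nchar(protein)
  no <- list(has_sp = FALSE, cleavage_pos = NA_integer_, score = 0)
  if (n < 25) return(no)
  chars <- strsplit(protein, "")[[1]]
  kd <- unname(KD_HYDROPATHY[chars])
  # clause (i): positive n-region
  if (!any(chars[2:min(5, n)] %in% c("K", "R"))) return(no)
  cs <- seq(cleavage_range[1], min(cleavage_range[2], n))
  best_score <- 0
  cleavage <- NA_integer_
  for (c_pos in cs) {
    # clause (iii): A-X-A style cleavage site
    if (!(chars[c_pos - 2] %in% c("A", "G", "S", "T") &&
          chars[c_pos] %in% c("A", "G", "S", "T"))) next
    # clause (ii): hydrophobic core window of 8 within residues 6..c-4
    hi <- c_pos - 4
    if (hi - 6 + 1 < 8) next
    means <- vapply(6:(hi - 7), function(s) mean(kd[s:(s + 7)]), numeric(1))
    if (max(means) >= h_min) {
      if (is.na(cleavage)) cleavage <- c_pos
      best_score <- max(best_score, max(means))
    }
  }
  if (is.na(cleavage)) return(no)
  list(has_sp = TRUE, cleavage_pos = cleavage, score = best_score)
}

#' Signal-peptide calls for a genome set
#'
#' @param gs a `genome_set`.
#' @param gene_ids genes to call (default: all).
#' @param ... passed to [predict_signal_peptide()].
#' @return data.frame `gene_id`, `has_sp`, `cleavage_pos`, `score`.
#' @export
predict_signal_peptides <- function(gs, gene_ids = NULL, ...) {
  prots <- .proteins_of(gs, gene_ids)
  calls <- lapply(prots, predict_signal_peptide, ...)
  data.frame(gene_id = names(prots),
             has_sp = vapply(calls, `[[`, logical(1), "has_sp"),
             cleavage_pos = vapply(calls, `[[`, integer(1), "cleavage_pos"),
             score = vapply(calls, `[[`, numeric(1), "score"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read external signal-peptide calls
#'
#' TSV with columns `gene_id`, `has_sp` and optionally `cleavage_pos`,
#' `score`. Imported calls take precedence over the built-in heuristic.
#'
#' @param path TSV path.
#' @return data.frame of calls.
#' @export
read_signal_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "has_sp"), names(tab))
  if (length(miss) > 0)
    stop("signal table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  tab$has_sp <- as.logical(tab$has_sp)
  if (!"cleavage_pos" %in% names(tab)) tab$cleavage_pos <- NA_integer_
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  tab[c("gene_id", "has_sp", "cleavage_pos", "score")]
}

#' Apply the five candidate rules
#'
#' The rule filter defining CutF-like candidates: the protein (1) is smaller
#' than `max_len` residues (strict), (2) matches no known Pfam-style domain
#' at the E-value ceiling, (3) carries a predicted signal peptide, (4)
#' contains a motif match (by default CXXXC/CXXC in the central region), and
#' (5) has the C-terminal PP motif. `passed` is the conjunction of the five
#' flags.
#'
#' @param gs a `genome_set`.
#' @param gene_ids genes to score (default: all genes).
#' @param signal_calls optional data.frame as from [predict_signal_peptides()]
#'   or [read_signal_table()]; genes not covered fall back to the built-in
#'   heuristic.
#' @param spec a [motif_spec()].
#' @param max_len strict size cutoff in residues (default 170).
#' @param domain_evalue_max E-value ceiling for a domain hit to count
#'   (default 1e-5).
#' @param tail_len tail length for the PP rule.
#' @return data.frame with per-rule flags `size_ok`, `no_known_domain`,
#'   `signal_ok`, `internal_motif_ok`, `cterm_pp_ok` and `passed`.
#' @export
apply_rules <- function(gs, gene_ids = NULL, signal_calls = NULL,
                        spec = motif_spec(), max_len = 170,
                        domain_evalue_max = 1e-5, tail_len = 15) {
  prots <- .proteins_of(gs, gene_ids)
  ids <- names(prots)
  lens <- nchar(prots)

  h <- gs$domain_hits
  with_dom <- unique(h$gene_id[h$evalue <= domain_evalue_max])

  sp <- setNames(rep(NA, length(ids)), ids)
  if (!is.null(signal_calls)) {
    m <- match(ids, signal_calls$gene_id)
    sp[!is.na(m)] <- signal_calls$has_sp[m[!is.na(m)]]
  }
  need <- is.na(sp)
  if (any(need))
    sp[need] <- vapply(prots[need],
                       function(p) predict_signal_peptide(p)$has_sp, logical(1))

  motif_ok <- vapply(seq_along(ids), function(i) {
    mm <- scan_motif(prots[i], spec)
    if (nrow(mm) == 0) return(FALSE)
    if (is.null(spec$region)) return(TRUE)
    L <- lens[i]
    ends <- mm$start + nchar(mm$pattern) - 1
    any(mm$start >= spec$region[1] * L & ends <= spec$region[2] * L)
  }, logical(1))

  out <- data.frame(
    gene_id = ids,
    size_ok = lens < max_len,
    no_known_domain = !(ids %in% with_dom),
    signal_ok = as.logical(sp),
    internal_motif_ok = motif_ok,
    cterm_pp_ok = vapply(prots, has_cterm_pp, logical(1), tail_len = tail_len),
    row.names = NULL, stringsAsFactors = FALSE)
  out$passed <- out$size_ok & out$no_known_domain & out$signal_ok &
    out$internal_motif_ok & out$cterm_pp_ok
  stopifnot(identical(out$passed,
                      out$size_ok & out$no_known_domain & out$signal_ok &
                        out$internal_motif_ok & out$cterm_pp_ok))
  out
}
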