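#' Multicopper-oxidase assay configuration
#'
#' Parameters of the spectrophotometric 2,6-dimethoxyphenol (2,6-DMP)
#' oxidation assay read at 468 nm: the molar extinction coefficient of
#' oxidized 2,6-DMP (14,800 per M per cm), the cuvette path length, the
#' reaction volume and the protein amount.
#'
#' @param epsilon molar extinction coefficient in M^-1 cm^-1 (default 14800).
#' @param path_cm optical path length in cm.
#' @param volume_L reaction volume in litres.
#' @param protein_mg protein amount in mg.
#' @return An `assay_config`.
#' @export
assay_config <- function(epsilon = 14800, path_cm = 1, volume_L = 1e-3,
                         protein_mg = 0.05) {
  vals <- c(epsilon = epsilon, path_cm = path_cm, volume_L = volume_L,
            protein_mg = protein_mg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all assay parameters must be positive: ",
         paste(names(vals)[vals <= 0 | !is.finite(vals)], collapse = ", "))
  structure(as.list(vals), class = "assay_config")
}

#' Specific MCO activity from an absorbance slope
#'
#' Beer-Lambert conversion of a ΔA468/min slope to nmol of substrate
#' oxidized per minute per mg protein:
#' `((deltaA / (epsilon * path)) * volume_L * 1e9) / protein_mg`.
#'
#' @param deltaA_per_min absorbance change per minute (>= 0).
#' @param cfg an [assay_config()].
#' @return specific activity in nmol min^-1 mg^-1.
#' @export
specific_activity <- function(deltaA_per_min, cfg = assay_config()) {
  stopifnot(inherits(cfg, "assay_config"))
  if (any(deltaA_per_min < 0)) stop("deltaA_per_min must be >= 0")
  ((deltaA_per_min / (cfg$epsilon * cfg$path_cm)) * cfg$volume_L * 1e9) /
    cfg$protein_mg
}

#' Activity relative to wild type
#'
#' Wild-type mean is set to 100%; the sample mean is expressed on that
#' scale and the sample standard deviation is propagated by the same factor
#' `100 / mean(wt)`.
#'
#' @param sample_values numeric replicate activities of the sample strain.
#' @param wt_values numeric replicate activities of wild type.
#' @return list with `percent` and `sd`.
#' @export
relative_activity <- function(sample_values, wt_values) {
  mw <- mean(wt_values)
  if (mw == 0) stop("wild-type mean activity is zero; relative activity undefined")
  list(percent = 100 * mean(sample_values) / mw,
       sd = 100 * sd(sample_values) / mw)
}

#' Welch (Satterthwaite-corrected) two-sided t-test
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value. Implemented in closed form;
#' `stats::t.test(var.equal = FALSE)` is the independent cross-check in the
#' test suite. With zero variance in both groups and equal means, p = 1 by
#' convention.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t_test needs at least 2 values per group")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Significance stars for a p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise. No multiple-testing correction is applied.
#'
#' @param p p-value(s).
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x <= 0.001) "***"
    else if (x <= 0.01) "**"
    else if (x <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Activity report for a replicate table
#'
#' Input: a data.frame (or TSV path) with columns `strain`, `replicate`,
#' `deltaA_per_min`. Computes specific activities, percent of wild type,
#' Welch p-values against wild type, and star labels.
#'
#' @param activities data.frame or TSV path.
#' @param cfg an [assay_config()].
#' @param wt name of the reference strain (default `"WT"`).
#' @param path optional output TSV path.
#' @return data.frame, one row per strain.
#' @export
activity_report <- function(activities, cfg = assay_config(), wt = "WT",
                            path = NULL) {
  if (is.character(activities) && length(activities) == 1)
    activities <- read.delim(activities, stringsAsFactors = FALSE)
  req <- c("strain", "deltaA_per_min")
  miss <- setdiff(req, names(activities))
  if (length(miss) > 0)
    stop("activity table is missing column(s): ", paste(miss, collapse = ", "))
  if (!wt %in% activities$strain)
    stop("reference strain ", sQuote(wt), " not found in activity table")
  act <- split(specific_activity(activities$deltaA_per_min, cfg),
               activities$strain)
  wt_vals <- act[[wt]]
  out <- do.call(rbind, lapply(names(act), function(s) {
    ra <- relative_activity(act[[s]], wt_vals)
    tt <- if (s == wt || length(act[[s]]) < 2 || length(wt_vals) < 2)
      list(p = NA_real_) else welch_t_test(act[[s]], wt_vals)
    data.frame(strain = s, n = length(act[[s]]),
               specific_activity = mean(act[[s]]),
               pct_wt = ra$percent, pct_wt_sd = ra$sd,
               p_vs_wt = tt$p, stars = significance_stars(tt$p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
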