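# Per-sample glycan-class summaries (TIC-normalized fractions of assigned
# intensity) and the study's statistical comparisons: unpaired two-sample
# t-tests for glycan classes, paired t-tests for expression, with the
# p < 0.05 decision rule.

.profile_classes <- c("oligomannose", "paucimannose", "hybrid", "complex",
                      "branched", "bisect_candidate", "sialylated",
                      "core_fucosylated", "sulfated", "di_sulfated")

#' Glycan-class profile of one sample
#'
#' Summarizes rank-1 annotations into per-class fractions of assigned
#' intensity: each fraction is the summed intensity of assigned peaks in the
#' class divided by the summed intensity of all assigned peaks (TIC
#' normalization over assigned signal).  The four structural categories
#' (oligomannose, paucimannose, hybrid, complex) partition the assigned
#' intensity and sum to 1; the feature classes (branched = antennarity >= 3,
#' bisect_candidate, sialylated = NeuAc >= 1, core_fucosylated,
#' sulfated >= 1, di_sulfated >= 2 sulfates) overlap freely.
#'
#' @param annotations A `glycan_annotations` object, or a list of them (e.g.
#'   the neutral and sulfated fractions of one sample, pooled).
#' @param sample_id Sample identifier.
#' @param group Group label, `"normal"` or `"tumor"`.
#' @return A one-row data frame: `sample_id`, `group`, one column per class
#'   fraction, and `assigned_intensity`.
#' @export
class_profile <- function(annotations, sample_id = "sample",
                          group = c("normal", "tumor")) {
  group <- match.arg(group)
  if (inherits(annotations, "glycan_annotations"))
    annotations <- list(annotations)
  stopifnot(all(vapply(annotations, inherits, logical(1),
                       "glycan_annotations")))
  tab <- do.call(rbind, lapply(annotations, function(a)
    a$table[a$table$assigned, c("intensity", "category", "antennarity",
                                "bisect_candidate", "core_fucosylated",
                                "sialylation_count", "sulfation_count")]))
  if (is.null(tab) || nrow(tab) == 0)
    stop("no assigned peaks; cannot build a class profile")
  total <- sum(tab$intensity)
  frac <- function(sel) sum(tab$intensity[sel]) / total
  out <- data.frame(
    sample_id = sample_id, group = group,
    oligomannose = frac(tab$category == "oligomannose"),
    paucimannose = frac(tab$category == "paucimannose"),
    hybrid = frac(tab$category == "hybrid"),
    complex = frac(tab$category == "complex"),
    branched = frac(!is.na(tab$antennarity) & tab$antennarity >= 3),
    bisect_candidate = frac(tab$bisect_candidate %in% TRUE),
    sialylated = frac(tab$sialylation_count >= 1),
    core_fucosylated = frac(tab$core_fucosylated %in% TRUE),
    sulfated = frac(tab$sulfation_count >= 1),
    di_sulfated = frac(tab$sulfation_count >= 2),
    assigned_intensity = total,
    stringsAsFactors = FALSE
  )
  out
}

.as_test_result <- function(t, df, p) {
  structure(list(statistic = t, df = df, p_value = p,
                 significant = is.finite(p) && p < 0.05),
            class = "glyco_test")
}

#' @export
print.glyco_test <- function(x, ...) {
  cat(sprintf("<glyco_test> t = %.4f, df = %.4g, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) "significant at 0.05" else "ns"))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Classic two-sided two-sample t-test; the default pools variances
#' (equal-variance form), with a Welch option.  Degenerate inputs are
#' handled explicitly: zero variance in both groups with equal means is an
#' error; with unequal means the difference is exact and p is reported as 0
#' with a warning.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param var_equal Pool variances (classic t) or not (Welch).
#' @return A `glyco_test`: `statistic`, `df`, `p_value`, `significant`
#'   (p < 0.05).
#' @export
ttest_unpaired <- function(x, y, var_equal = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      stop("degenerate: zero variance in both groups with equal means")
    warning("zero variance in both groups; exact group difference, p = 0")
    return(.as_test_result(sign(mean(x) - mean(y)) * Inf,
                           length(x) + length(y) - 2, 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal,
                      alternative = "two.sided")
  .as_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Paired expression matrix in RPKM
#'
#' @param rpkm Numeric gene-by-sample matrix (non-negative), rownames =
#'   genes, colnames = sample ids.
#' @param pairing Data frame with columns `patient`, `normal`, `tumor`
#'   giving, per patient, the column names of the paired samples.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(rpkm, pairing) {
  stopifnot(is.matrix(rpkm), is.numeric(rpkm),
            all(c("patient", "normal", "tumor") %in% names(pairing)))
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  if (anyDuplicated(pairing$patient))
    stop("every patient must have exactly one sample per group")
  miss <- setdiff(c(pairing$normal, pairing$tumor), colnames(rpkm))
  if (length(miss))
    stop("pairing refers to missing samples: ", paste(miss, collapse = ", "))
  structure(list(rpkm = rpkm, pairing = pairing),
            class = "expression_matrix")
}

#' Paired two-sample t-test on one gene
#'
#' One-sample two-sided t-test on per-patient tumor-minus-normal
#' differences.  RPKM values are compared untransformed by default; set
#' `log2_transform = TRUE` to test log2(RPKM + 1) differences instead.
#' Degenerate inputs: identical nonzero differences give p = 0 with a
#' warning; all-zero differences are an error.
#'
#' @param matrix An [expression_matrix()].
#' @param gene Gene name (a rowname of the RPKM matrix).
#' @param log2_transform Test log2(x + 1) values instead of raw RPKM.
#' @return A `glyco_test` (positive statistic = higher in tumor).
#' @export
ttest_paired <- function(matrix, gene, log2_transform = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!gene %in% rownames(matrix$rpkm))
    stop("gene not in matrix: ", gene)
  v <- matrix$rpkm[gene, ]
  if (log2_transform) v <- log2(v + 1)
  d <- v[matrix$pairing$tumor] - v[matrix$pairing$normal]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::var(d) == 0) {
    if (all(d == 0))
      stop("degenerate: all paired differences are zero")
    warning("all paired differences identical; exact effect, p = 0")
    return(.as_test_result(sign(d[1]) * Inf, length(d) - 1, 0))
  }
  tt <- stats::t.test(d, alternative = "two.sided")
  .as_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Compare all glycan-class fractions between groups
#'
#' Runs [ttest_unpaired()] on every class fraction of a profile table
#' (normal vs tumor).  No multiple-testing correction is applied by
#' default, matching the per-feature p < 0.05 decision rule; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted significance.
#'
#' @param profiles A data frame of [class_profile()] rows for several
#'   samples.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame: `class`, `t`, `df`, `p`, `significant` (tumor vs
#'   normal; positive t = higher in tumor).
#' @export
compare_class_profiles <- function(profiles, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("group", .profile_classes) %in% names(profiles)))
  res <- lapply(.profile_classes, function(cl) {
    x <- profiles[[cl]][profiles$group == "tumor"]
    y <- profiles[[cl]][profiles$group == "normal"]
    tt <- tryCatch(ttest_unpaired(x, y),
                   error = function(e) .as_test_result(NA_real_, NA_real_,
                                                       NA_real_))
    data.frame(class = cl, t = tt$statistic, df = tt$df, p = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  padj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(padj) & padj < 0.05
  out
}
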