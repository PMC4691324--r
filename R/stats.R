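#' Statistical tests used across the pipeline
#'
#' Thin, uniform wrappers around the classical non-parametric tests the
#' analysis relies on, each returning an `mfhet_test` record stating the
#' statistic, the two-tailed p-value, the sample size and whether an exact or
#' an asymptotic method was used. Exactness cutoffs: Spearman p is an exact
#' permutation value for n <= 9 (ties permitting), otherwise the
#' t-approximation; Wilcoxon signed-rank and rank-sum use the exact
#' distribution for n <= 25 (no ties/zeros permitting) and the normal
#' approximation with continuity correction above; Fisher's test is always
#' exact. Zero differences are dropped for the signed-rank test (Wilcoxon's
#' original treatment).
#'
#' @name mfhet_tests
NULL

new_test_result <- function(test_name, statistic, p_value, n, method_detail,
                            two_tailed = TRUE, estimate = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = min(unname(p_value), 1), n = n,
                 method_detail = method_detail, two_tailed = two_tailed,
                 estimate = estimate),
            class = "mfhet_test")
}

#' @export
print.mfhet_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n = %d, %s, %s)\n",
              x$test_name, x$statistic, x$p_value, x$n, x$method_detail,
              if (x$two_tailed) "two-tailed" else "one-tailed"))
  invisible(x)
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors (>= 3 pairs).
#' @return An `mfhet_test` with `estimate` = rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need >= 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 9L && !has_ties  # exact null distribution available below 10
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  new_test_result("spearman_rho", ct$statistic, ct$p.value, n,
                  if (exact) "exact permutation" else "t approximation",
                  estimate = unname(ct$estimate))
}

#' Wilcoxon signed-rank test for paired data
#'
#' @param x Numeric vector of differences, or first members of pairs when `y`
#'   is given.
#' @param y Optional second members of pairs.
#' @param exact_max Largest n (after dropping zero differences) for which the
#'   exact null distribution is used. Default 25.
#' @return An `mfhet_test`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(new_test_result("wilcoxon_signed_rank", NA_real_, 1, length(d),
                           "all differences zero"))
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = TRUE))
  new_test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value, length(nz),
                  if (exact) "exact" else "normal approximation with continuity correction")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param x,y The two samples.
#' @param exact_max Largest combined n for the exact branch. Default 25.
#' @return An `mfhet_test`.
#' @export
rank_sum <- function(x, y, exact_max = 25L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("arity error: empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  new_test_result("rank_sum", wt$statistic, wt$p.value, length(x) + length(y),
                  if (exact) "exact" else "normal approximation with continuity correction")
}

#' Kruskal-Wallis test
#'
#' @param groups A list of numeric vectors (>= 2 groups).
#' @return An `mfhet_test` (chi-squared approximation with tie correction).
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 0L) == 0L)) stop("arity error: empty group")
  if (length(groups) < 2L) stop("arity error: need >= 2 groups")
  kt <- stats::kruskal.test(groups)
  new_test_result("kruskal_wallis", kt$statistic, kt$p.value,
                  sum(vapply(groups, length, 0L)),
                  "chi-squared approximation with tie correction")
}

#' Fisher's exact test for a 2 x k contingency table
#'
#' @param table A matrix (2 rows, k columns) of counts.
#' @return An `mfhet_test` (statistic is the odds-ratio estimate for 2 x 2
#'   tables, `NA` otherwise; the p-value is the exact hypergeometric value).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) stop("value error: counts required")
  if (any(dim(table) < 2L)) stop("arity error: need a 2 x k table with k >= 2")
  ft <- stats::fisher.test(table)
  est <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
  new_test_result("fisher_exact", est, ft$p.value, sum(table), "exact hypergeometric")
}

#' Assemble the cohort-level report
#'
#' Collects the stage outputs into one deterministic, structured report. A
#' missing optional stage (copy-number / rearrangements) is noted as skipped;
#' a missing mandatory stage is an error listing the absent sections.
#'
#' @param confirmation An `mfhet_confirmation`.
#' @param oncogenicity An `mfhet_oncogenicity`.
#' @param heterogeneity An `mfhet_heterogeneity`.
#' @param af_comparison Result of [private_vs_common_af()], or `NULL`.
#' @param associations Result of [covariate_association()], or `NULL`.
#' @param concordance Result of [platform_concordance()], or `NULL`.
#' @param cn Result of [compare_lesion_genomes()], or `NULL` (section noted
#'   as skipped).
#' @param dir Optional directory; when given, the report TSVs and a plain-text
#'   summary are written there with fixed names.
#' @return An object of class `mfhet_report`.
#' @export
assemble_report <- function(confirmation, oncogenicity, heterogeneity,
                            af_comparison = NULL, associations = NULL,
                            concordance = NULL, cn = NULL, dir = NULL) {
  missing_stages <- c(
    if (missing(confirmation) || is.null(confirmation)) "confirmation",
    if (missing(oncogenicity) || is.null(oncogenicity)) "oncogenicity",
    if (missing(heterogeneity) || is.null(heterogeneity)) "heterogeneity")
  if (length(missing_stages))
    stop("missing stage output(s): ", paste(missing_stages, collapse = ", "))
  rep <- structure(list(
    confirmation = confirmation$summary,
    oncogenicity = attr(oncogenicity, "summary"),
    heterogeneity = heterogeneity$group_summary,
    af_comparison = af_comparison,
    associations = associations,
    concordance = concordance,
    cn = cn,
    cn_skipped = is.null(cn)), class = "mfhet_report")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(confirmation$status_table,
                       file.path(dir, "status.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(oncogenicity),
                       file.path(dir, "oncogenicity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(heterogeneity$patients,
                       file.path(dir, "patients.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(associations))
      utils::write.table(associations, file.path(dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    con <- file(file.path(dir, "summary.txt"), "w")
    sink(con); print(rep); sink(); close(con)
  }
  rep
}

#' @export
print.mfhet_report <- function(x, ...) {
  cat("mfhet cohort report\n")
  s <- x$confirmation
  cat(sprintf("confirmation: %d pairs; %d confirmed, %d present-only, %d not detected, %d assay failed\n",
              s$n_assayed, s$n_confirmed, s$n_present_only, s$n_not_detected,
              s$n_assay_failed))
  o <- x$oncogenicity
  cat(sprintf("oncogenicity: %d/%d unique variants oncogenic in the collapsed sense (%.1f%%)\n",
              o$n_oncogenic_tiered, o$n_variants, 100 * o$fraction))
  g <- x$heterogeneity
  cat(sprintf("heterogeneity: %d homogeneous, %d intermediate, %d heterogeneous (shared fraction %.1f%%)\n",
              g$n_homogeneous, g$n_intermediate, g$n_heterogeneous,
              100 * g$shared_fraction))
  if (!is.null(x$af_comparison))
    cat(sprintf("private vs common AF: medians %.3f vs %.3f, paired signed-rank p = %.4g\n",
                x$af_comparison$median_af_private, x$af_comparison$median_af_common,
                x$af_comparison$test$p_value))
  if (!is.null(x$concordance))
    cat(sprintf("platform concordance: rho = %.3f, ROC AUC = %.2f%%\n",
                x$concordance$spearman$estimate, 100 * x$concordance$roc_auc))
  if (isTRUE(x$cn_skipped)) {
    cat("copy-number / rearrangement section: skipped (no inputs)\n")
  } else if (!is.null(x$cn)) {
    cat(sprintf("rearrangements: mean common fraction %.2f; SCNAs: mean common fraction %.2f\n",
                x$cn$mean_fraction_common_rearrangements,
                x$cn$mean_fraction_common_scna))
  }
  invisible(x)
}
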