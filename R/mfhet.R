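#' mfhet: multifocal breast cancer heterogeneity analysis
#'
#' Pipeline for the genomic comparison of synchronous breast cancer lesions:
#' cross-platform confirmation of somatic mutations, rule-based oncogenicity
#' annotation, patient-level heterogeneity grouping, private-versus-common
#' comparisons of mutations, rearrangements and copy-number segments, and a
#' fully ground-truthed synthetic cohort generator.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full heterogeneity analysis
#'
#' One-stop wrapper tying the stages together: merge the two platform tables,
#' assign validation statuses, index unique variants, classify oncogenicity,
#' group patients, compare private and common allele fractions, test
#' covariate associations, and (when genome-wide inputs are given) compare
#' rearrangements and copy-number profiles between lesions.
#'
#' @param discovery,validation Mutation-call data.frames from the two
#'   platforms ([read_variant_table()]).
#' @param hierarchy A `cohort_hierarchy`.
#' @param recurrence Recurrence table ([read_recurrence_table()] layout).
#' @param roles Gene-role table ([read_gene_role_table()] layout).
#' @param config An [mfhet_config()].
#' @param rearrangements,cn_profiles,focal_regions Optional genome-wide
#'   inputs (see [compare_lesion_genomes()]).
#' @return An object of class `mfhet` with components `calls`, `confirmation`,
#'   `unique_variants`, `oncogenicity`, `heterogeneity`, `af_comparison`,
#'   `associations`, `concordance`, `cn` and `report`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 6, seed = 7))
#' fit <- mfhet(cohort$discovery, cohort$validation, cohort$hierarchy,
#'              cohort$recurrence, cohort$roles)
#' print(fit)
#' @export
mfhet <- function(discovery, validation, hierarchy, recurrence, roles,
                  config = mfhet_config(), rearrangements = NULL,
                  cn_profiles = NULL, focal_regions = NULL) {
  calls <- combine_platforms(discovery, validation)
  confirmation <- confirm_cohort(calls, hierarchy, config)
  uv <- unique_variants(calls)
  onco <- classify_variants(uv, recurrence, roles, config)
  het <- classify_cohort(confirmation, hierarchy, onco, config)
  af_cmp <- tryCatch(private_vs_common_af(het), error = function(e) NULL)
  assoc <- covariate_association(het, hierarchy, config)
  conc <- tryCatch(platform_concordance(confirmation$status_table),
                   error = function(e) NULL)
  cn <- if (!is.null(rearrangements) || !is.null(cn_profiles))
    compare_lesion_genomes(rearrangements, cn_profiles, focal_regions, config)
  else NULL
  report <- assemble_report(confirmation, onco, het, af_cmp, assoc, conc, cn)
  structure(list(calls = calls, confirmation = confirmation,
                 unique_variants = uv, oncogenicity = onco,
                 heterogeneity = het, af_comparison = af_cmp,
                 associations = assoc, concordance = conc, cn = cn,
                 report = report, hierarchy = hierarchy, config = config),
            class = "mfhet")
}

#' @export
print.mfhet <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
summary.mfhet <- function(object, ...) {
  print(object$report)
  cat("\nper-patient grouping:\n")
  print(object$heterogeneity$patients[, c("patient_id", "group",
                                          "n_mutations_total", "n_common",
                                          "n_private", "shares_oncogenic")])
  cat("\ncovariate associations:\n")
  print(object$associations[, c("covariate", "comparison", "test_used", "p")])
  invisible(object)
}

#' Plot a patient's mutation heat map
#'
#' @param x An `mfhet` object.
#' @param patient_id Which patient to draw.
#' @param ... Passed on.
#' @export
plot.mfhet <- function(x, patient_id = x$heterogeneity$patients$patient_id[1L],
                       ...) {
  m <- presence_matrix(x$confirmation$status_table, patient_id, x$hierarchy)
  plot(m, oncogenicity = x$oncogenicity, ...)
}
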