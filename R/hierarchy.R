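#' Cohort hierarchy: patients, lesions, samples
#'
#' A cohort hierarchy maps every sequenced sample to the lesion and patient it
#' was cut from, and carries per-patient clinico-pathological covariates (age
#' group, tumour size, node status, grade, ER/HER2 subtype, in-situ component,
#' lymphovascular invasion, and the largest inter-lesion distance in cm).
#' Multifocality requires at least two lesions per patient; every lesion has at
#' least one sample; sample identifiers are globally unique.
#'
#' @param patients A list; each element is a list with `patient_id` (string),
#'   `lesions` (list of lists with `lesion_id` and character vector `samples`)
#'   and optionally `covariates` (named list; missing entries allowed).
#' @return An object of class `cohort_hierarchy`.
#' @export
cohort_hierarchy <- function(patients) {
  h <- structure(list(patients = patients), class = "cohort_hierarchy")
  validate_hierarchy(h)
  h
}

COVARIATE_FIELDS <- c("age_group", "tumour_size_cm", "n_positive_nodes",
                      "grade", "subtype", "dcis_present", "lvi_present",
                      "max_inter_lesion_distance_cm")

#' @rdname cohort_hierarchy
#' @param h A `cohort_hierarchy`.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "cohort_hierarchy"))
  pids <- vapply(h$patients, function(p) as.character(p$patient_id), "")
  if (anyDuplicated(pids))
    stop("integrity error: duplicate patient_id: ",
         paste(unique(pids[duplicated(pids)]), collapse = ", "))
  all_samples <- character(0)
  for (p in h$patients) {
    if (length(p$lesions) < 2L)
      stop("integrity error: patient ", p$patient_id,
           " has fewer than 2 lesions; multifocality requires >= 2")
    for (les in p$lesions) {
      if (length(les$samples) < 1L)
        stop("integrity error: lesion ", les$lesion_id, " of patient ",
             p$patient_id, " has no samples")
      all_samples <- c(all_samples, as.character(les$samples))
    }
    grade <- p$covariates$grade
    if (!is.null(grade) && !grade %in% c("G1", "G2", "G3"))
      stop("integrity error: patient ", p$patient_id, " has invalid grade ", grade)
    subtype <- p$covariates$subtype
    if (!is.null(subtype) &&
        !subtype %in% c("ER+/HER2-", "ER-/HER2-", "HER2+"))
      stop("integrity error: patient ", p$patient_id, " has invalid subtype ", subtype)
    d <- p$covariates$max_inter_lesion_distance_cm
    if (!is.null(d) && !is.na(d) && d < 0)
      stop("integrity error: negative inter-lesion distance for patient ", p$patient_id)
  }
  if (anyDuplicated(all_samples))
    stop("integrity error: duplicate sample_id: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  invisible(h)
}

#' Flat sample table of a hierarchy
#'
#' @param h A `cohort_hierarchy`.
#' @return A data.frame with columns `patient_id`, `lesion_id`, `sample_id`,
#'   one row per sample, in file order.
#' @export
hierarchy_samples <- function(h) {
  stopifnot(inherits(h, "cohort_hierarchy"))
  rows <- list()
  for (p in h$patients) for (les in p$lesions) for (s in les$samples)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = as.character(p$patient_id),
      lesion_id = as.character(les$lesion_id),
      sample_id = as.character(s),
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Per-patient covariate table
#'
#' @param h A `cohort_hierarchy`.
#' @return A data.frame, one row per patient, with the standard covariate
#'   columns plus `n_lesions` and `n_samples`; missing covariates are `NA`.
#' @export
covariate_table <- function(h) {
  stopifnot(inherits(h, "cohort_hierarchy"))
  rows <- lapply(h$patients, function(p) {
    cov <- p$covariates
    get1 <- function(nm) {
      v <- cov[[nm]]
      if (is.null(v) || length(v) == 0L) NA else v
    }
    data.frame(
      patient_id = as.character(p$patient_id),
      age_group = as.character(get1("age_group")),
      tumour_size_cm = as.numeric(get1("tumour_size_cm")),
      n_positive_nodes = as.numeric(get1("n_positive_nodes")),
      grade = as.character(get1("grade")),
      subtype = as.character(get1("subtype")),
      dcis_present = as.logical(get1("dcis_present")),
      lvi_present = as.logical(get1("lvi_present")),
      max_inter_lesion_distance_cm = as.numeric(get1("max_inter_lesion_distance_cm")),
      n_lesions = length(p$lesions),
      n_samples = sum(vapply(p$lesions, function(l) length(l$samples), 0L)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write the cohort hierarchy
#'
#' The hierarchy is stored as a YAML tree: a top-level `patients` list whose
#' elements hold `patient_id`, an optional `covariates` mapping and a `lesions`
#' list of `{lesion_id, samples}` entries. Reading validates all hierarchy
#' invariants. Validation is independent of the order of patients, lesions and
#' samples in the file.
#'
#' @param path File path.
#' @return `read_hierarchy()` returns a `cohort_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  tree <- yaml::read_yaml(path)
  if (is.null(tree$patients)) stop("format error: hierarchy file lacks a 'patients' key")
  pts <- lapply(tree$patients, function(p) {
    if (is.null(p$patient_id)) stop("format error: patient entry lacks patient_id")
    lesions <- lapply(p$lesions, function(l) {
      list(lesion_id = as.character(l$lesion_id),
           samples = as.character(unlist(l$samples)))
    })
    list(patient_id = as.character(p$patient_id),
         covariates = if (is.null(p$covariates)) list() else p$covariates,
         lesions = lesions)
  })
  cohort_hierarchy(pts)
}

#' @rdname read_hierarchy
#' @param h A `cohort_hierarchy`.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "cohort_hierarchy"))
  yaml::write_yaml(list(patients = h$patients), path)
  invisible(path)
}

#' Check that variant-table samples resolve against the hierarchy
#'
#' Samples referenced by calls but absent from the hierarchy are an error;
#' hierarchy samples with no calls are legitimate (assayed with no mutations,
#' or added only at the validation phase) and produce a warning listing them.
#'
#' @param calls A mutation-call data.frame (see [read_variant_table()]).
#' @param h A `cohort_hierarchy`.
#' @return Invisibly, the character vector of hierarchy samples with no calls.
#' @export
check_sample_resolution <- function(calls, h) {
  hs <- hierarchy_samples(h)
  unknown <- setdiff(unique(calls$sample_id), hs$sample_id)
  if (length(unknown))
    stop("integrity error: sample(s) not in hierarchy: ",
         paste(unknown, collapse = ", "))
  silentless <- setdiff(hs$sample_id, unique(calls$sample_id))
  if (length(silentless))
    warning("hierarchy sample(s) with no calls (treated as assayed with no mutations): ",
            paste(silentless, collapse = ", "))
  invisible(silentless)
}

#' @export
print.cohort_hierarchy <- function(x, ...) {
  hs <- hierarchy_samples(x)
  cat(sprintf("cohort_hierarchy: %d patients, %d lesions, %d samples\n",
              length(x$patients), length(unique(paste(hs$patient_id, hs$lesion_id))),
              nrow(hs)))
  invisible(x)
}
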