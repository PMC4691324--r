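#' Inter-lesion heterogeneity classification
#'
#' From the per-sample presence matrix of validated mutations, each patient is
#' placed in one of three groups: `HOMOGENEOUS` (all samples from all lesions
#' carry the same mutations), `HETEROGENEOUS` (no single mutation in common
#' among all lesions), and `INTERMEDIATE` (both common and private mutations).
#' A variant is *lesion-common* when at least one sample of every lesion
#' carries it; a lesion none of whose assays for a variant were informative
#' (all failed) does not block commonness. Under the default strict reading,
#' homogeneity additionally requires presence in every assay-informative
#' sample, not just every lesion (`strict_homogeneous` in [mfhet_config()]).
#'
#' @name heterogeneity
NULL

#' Presence matrix of one patient
#'
#' @param status_table `status_table` from [confirm_cohort()].
#' @param patient_id The patient.
#' @param hierarchy A `cohort_hierarchy`.
#' @return An object of class `mfhet_presence`: an integer matrix (rows =
#'   variant keys with at least one accepted call, columns = assayed samples
#'   grouped by lesion) with cells 1 (present: status CONFIRMED/PRESENT),
#'   0 (absent: NOT_DETECTED) or `NA` (assay failed). Attributes: `patient_id`,
#'   `lesion_of` (named vector sample -> lesion), `validation_only` (logical
#'   per sample: no discovery AF observed in any variant), `af` (matching
#'   matrix of allele fractions, validation AF preferred), `fallback`
#'   (discovery-screen evidence filling assay-failed cells: used for
#'   lesion-level commonness, not for the strict all-samples criterion) and
#'   `gene_of` (named vector key -> gene).
#' @export
presence_matrix <- function(status_table, patient_id, hierarchy) {
  tab <- status_table[status_table$patient_id == patient_id, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no status rows for patient ", patient_id)
  hs <- hierarchy_samples(hierarchy)
  hs <- hs[hs$patient_id == patient_id, , drop = FALSE]
  samples <- hs$sample_id[hs$sample_id %in% unique(tab$sample_id)]
  keys <- sort(unique(tab$key))
  m <- matrix(NA_integer_, nrow = length(keys), ncol = length(samples),
              dimnames = list(keys, samples))
  afm <- matrix(NA_real_, nrow = length(keys), ncol = length(samples),
                dimnames = list(keys, samples))
  val_only <- vapply(samples, function(s)
    all(is.na(tab$af_discovery[tab$sample_id == s])), TRUE)
  fb <- m  # discovery-screen fallback evidence for failed validation assays
  for (i in seq_len(nrow(tab))) {
    r <- tab$key[i]; c <- tab$sample_id[i]
    if (!c %in% samples) next
    m[r, c] <- switch(tab$status[i],
                      CONFIRMED = 1L, PRESENT = 1L, NOT_DETECTED = 0L,
                      ASSAY_FAILED = NA_integer_)
    # a failed validation assay falls back to the discovery screen (the study
    # retained its unconfirmable mutations in the heat maps): present where
    # the discovery platform called the mutation, absent where that sample
    # was discovery-sequenced but reported no call, non-informative for
    # samples that entered at the validation phase only
    if (tab$status[i] == "ASSAY_FAILED")
      fb[r, c] <- if (!is.na(tab$af_discovery[i]) && tab$af_discovery[i] > 0) 1L
                  else if (!val_only[[c]]) 0L
                  else NA_integer_
    afm[r, c] <- if (!is.na(tab$af_validation[i])) tab$af_validation[i]
                 else tab$af_discovery[i]
  }
  eff <- ifelse(is.na(m), fb, m)
  keep <- rowSums(eff == 1L, na.rm = TRUE) >= 1L
  m <- m[keep, , drop = FALSE]; afm <- afm[keep, , drop = FALSE]
  fb <- fb[keep, , drop = FALSE]
  lesion_of <- stats::setNames(hs$lesion_id, hs$sample_id)[samples]
  gene_of <- stats::setNames(tab$gene_symbol[!duplicated(tab$key)],
                             tab$key[!duplicated(tab$key)])
  structure(m, patient_id = patient_id, lesion_of = lesion_of,
            validation_only = val_only, af = afm, fallback = fb,
            gene_of = gene_of[rownames(m)],
            class = c("mfhet_presence", class(m)))
}

lesion_common_variants <- function(m, lesion_of) {
  lesions <- unique(lesion_of)
  common <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    ok <- TRUE
    for (les in lesions) {
      cells <- m[i, lesion_of == les]
      informative <- cells[!is.na(cells)]
      if (length(informative) && !any(informative == 1L)) { ok <- FALSE; break }
    }
    common[i] <- ok
  }
  rownames(m)[common]
}

#' Classify one patient
#'
#' @param m An [presence_matrix()] (at least 1 variant, 2 lesions).
#' @param oncogenic_keys Character vector of variant keys with the collapsed
#'   oncogenic flag (used for `shares_oncogenic`); may be empty.
#' @param config An [mfhet_config()].
#' @return A list of class `mfhet_patient`: `patient_id, group,
#'   common_variants, private_variants, shares_oncogenic, n_mutations_total,
#'   median_af_common, median_af_private, af_common, af_private` (per-variant
#'   AF medians over carrying samples).
#' @export
classify_patient <- function(m, oncogenic_keys = character(0),
                             config = mfhet_config()) {
  stopifnot(inherits(m, "mfhet_presence"))
  lesion_of <- attr(m, "lesion_of")
  if (length(unique(lesion_of)) < 2L)
    stop("contract violation: need >= 2 lesions to classify")
  if (nrow(m) == 0L)
    stop("patient ", attr(m, "patient_id"),
         " has zero confirmed variants and cannot be grouped")
  fb <- attr(m, "fallback")
  if (is.null(fb)) fb <- matrix(NA_integer_, nrow(m), ncol(m))
  eff <- ifelse(is.na(unclass(m)), unclass(fb), unclass(m))
  dimnames(eff) <- dimnames(m)
  common <- lesion_common_variants(eff, lesion_of)
  private <- setdiff(rownames(m), common)
  # the strict all-samples criterion counts validated cells only; fallback
  # evidence (discovery screen standing in for a failed assay) informs
  # commonness but cannot veto sample-completeness
  all_present <- all(m[!is.na(m)] == 1L)
  group <- if (length(common) == 0L) {
    "HETEROGENEOUS"
  } else if (length(private) == 0L &&
             (all_present || !config$strict_homogeneous)) {
    "HOMOGENEOUS"
  } else {
    "INTERMEDIATE"
  }
  afm <- attr(m, "af")
  per_variant_af <- vapply(rownames(m), function(k) {
    carrying <- which(eff[k, ] == 1L)
    stats::median(afm[k, carrying], na.rm = TRUE)
  }, 0)
  res <- list(
    patient_id = attr(m, "patient_id"), group = group,
    common_variants = common, private_variants = private,
    shares_oncogenic = length(intersect(common, oncogenic_keys)) > 0L,
    has_oncogenic = length(intersect(rownames(m), oncogenic_keys)) > 0L,
    n_mutations_total = nrow(m),
    af_common = per_variant_af[common], af_private = per_variant_af[private],
    median_af_common = if (length(common)) stats::median(per_variant_af[common], na.rm = TRUE) else NA_real_,
    median_af_private = if (length(private)) stats::median(per_variant_af[private], na.rm = TRUE) else NA_real_)
  class(res) <- "mfhet_patient"
  res
}

#' @export
print.mfhet_patient <- function(x, ...) {
  cat(sprintf("patient %s: %s (%d mutations: %d common, %d private%s)\n",
              x$patient_id, x$group, x$n_mutations_total,
              length(x$common_variants), length(x$private_variants),
              if (x$shares_oncogenic) "; shares oncogenic" else ""))
  invisible(x)
}

#' Classify the cohort
#'
#' Classifies every patient with at least one accepted variant; patients with
#' none are excluded with a warning.
#'
#' @param confirmation An [confirm_cohort()] result (or its `status_table`).
#' @param hierarchy A `cohort_hierarchy`.
#' @param oncogenicity An [classify_variants()] result, or `NULL` (then no
#'   oncogenic flags).
#' @param config An [mfhet_config()].
#' @return An object of class `mfhet_heterogeneity`: `patients` (data.frame,
#'   one row per classified patient), `per_patient` (list of `mfhet_patient`),
#'   `group_summary` (counts, shared fraction = (homogeneous + intermediate) /
#'   classified, per-group median mutation counts and shared-oncogenic
#'   counts), `excluded` (patients with zero accepted variants).
#' @export
classify_cohort <- function(confirmation, hierarchy, oncogenicity = NULL,
                            config = mfhet_config()) {
  tab <- if (inherits(confirmation, "mfhet_confirmation"))
    confirmation$status_table else confirmation
  onco_keys <- if (!is.null(oncogenicity))
    oncogenicity$key[oncogenicity$oncogenic] else character(0)
  pids <- unique(tab$patient_id)
  per_patient <- list(); excluded <- character(0)
  for (pid in pids) {
    m <- presence_matrix(tab, pid, hierarchy)
    if (nrow(m) == 0L) {
      warning("patient ", pid, " has zero accepted variants; excluded from grouping")
      excluded <- c(excluded, pid)
      next
    }
    per_patient[[pid]] <- classify_patient(m, onco_keys, config)
  }
  if (!length(per_patient)) stop("no classifiable patients")
  patients <- do.call(rbind, lapply(per_patient, function(r)
    data.frame(patient_id = r$patient_id, group = r$group,
               n_mutations_total = r$n_mutations_total,
               n_common = length(r$common_variants),
               n_private = length(r$private_variants),
               shares_oncogenic = r$shares_oncogenic,
               has_oncogenic = r$has_oncogenic,
               median_af_common = r$median_af_common,
               median_af_private = r$median_af_private,
               stringsAsFactors = FALSE)))
  rownames(patients) <- NULL
  ngrp <- function(g) sum(patients$group == g)
  med <- function(g) stats::median(patients$n_mutations_total[patients$group == g])
  nshare <- function(g) sum(patients$shares_oncogenic[patients$group == g])
  group_summary <- list(
    n_patients = nrow(patients),
    n_homogeneous = ngrp("HOMOGENEOUS"),
    n_intermediate = ngrp("INTERMEDIATE"),
    n_heterogeneous = ngrp("HETEROGENEOUS"),
    shared_fraction = (ngrp("HOMOGENEOUS") + ngrp("INTERMEDIATE")) / nrow(patients),
    median_mutations = stats::median(patients$n_mutations_total),
    median_mutations_homogeneous = med("HOMOGENEOUS"),
    median_mutations_intermediate = med("INTERMEDIATE"),
    median_mutations_heterogeneous = med("HETEROGENEOUS"),
    n_sharing_oncogenic_homogeneous = nshare("HOMOGENEOUS"),
    n_sharing_oncogenic_intermediate = nshare("INTERMEDIATE"))
  structure(list(patients = patients, per_patient = per_patient,
                 group_summary = group_summary, excluded = excluded,
                 config = config),
            class = "mfhet_heterogeneity")
}

#' @export
print.mfhet_heterogeneity <- function(x, ...) {
  g <- x$group_summary
  cat("mfhet heterogeneity grouping\n")
  cat(sprintf("  %d patients: %d homogeneous, %d intermediate, %d heterogeneous\n",
              g$n_patients, g$n_homogeneous, g$n_intermediate, g$n_heterogeneous))
  cat(sprintf("  shared-mutation fraction: %.1f%%\n", 100 * g$shared_fraction))
  cat(sprintf("  median mutations/patient: %.1f (homogeneous %.1f, heterogeneous %.1f)\n",
              g$median_mutations, g$median_mutations_homogeneous,
              g$median_mutations_heterogeneous))
  if (length(x$excluded))
    cat("  excluded (no accepted variants):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Private versus common allele fractions
#'
#' Restricted to intermediate patients (the only group with both sets): pooled
#' medians over per-variant AFs, and a paired Wilcoxon signed-rank test over
#' the per-patient (median private AF, median common AF) pairs.
#'
#' @param het An [classify_cohort()] result.
#' @return A list with `median_af_private`, `median_af_common`, `test`
#'   (an `mfhet_test`) and `n_patients` (pairs contributing).
#' @export
private_vs_common_af <- function(het) {
  inter <- Filter(function(r) r$group == "INTERMEDIATE", het$per_patient)
  pairs <- Filter(function(r) !is.na(r$median_af_private) &&
                    !is.na(r$median_af_common), inter)
  if (length(pairs) < 2L)
    stop("insufficient data: need >= 2 intermediate patients with both AF sets")
  priv <- vapply(pairs, function(r) r$median_af_private, 0)
  comm <- vapply(pairs, function(r) r$median_af_common, 0)
  pooled_priv <- stats::median(unlist(lapply(inter, function(r) r$af_private)), na.rm = TRUE)
  pooled_comm <- stats::median(unlist(lapply(inter, function(r) r$af_common)), na.rm = TRUE)
  list(median_af_private = pooled_priv, median_af_common = pooled_comm,
       test = wilcoxon_signed_rank(priv, comm), n_patients = length(pairs))
}

#' Covariate associations with heterogeneity
#'
#' Continuous covariates are compared across the three groups with
#' Kruskal-Wallis, between the homogeneous and heterogeneous groups and
#' between shared-oncogenic versus private-only-oncogenic patients with
#' rank-sum tests (patients with no oncogenic variant are excluded from the
#' latter); categorical covariates give Fisher's exact test on the
#' covariate-by-group table. Patients missing a covariate are dropped per
#' test; single-level covariates are skipped with a note. Raw two-tailed
#' p-values are reported (the protocol applies no multiplicity correction);
#' set `adjust = TRUE` for an additional Benjamini-Hochberg column.
#'
#' @param het An [classify_cohort()] result.
#' @param hierarchy A `cohort_hierarchy`.
#' @param config An [mfhet_config()].
#' @param adjust Add a BH-adjusted p column (off by default).
#' @return A data.frame with columns `covariate, comparison, test_used,
#'   statistic, p, n, note`.
#' @export
covariate_association <- function(het, hierarchy, config = mfhet_config(),
                                  adjust = FALSE) {
  cov <- covariate_table(hierarchy)
  df <- merge(het$patients, cov, by = "patient_id")
  continuous <- c("tumour_size_cm", "n_positive_nodes",
                  "max_inter_lesion_distance_cm", "n_lesions", "n_samples")
  categorical <- c("age_group", "grade", "subtype", "dcis_present", "lvi_present")
  rows <- list()
  add <- function(covariate, comparison, test_used, statistic, p, n, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = covariate, comparison = comparison, test_used = test_used,
      statistic = statistic, p = p, n = n, note = note,
      stringsAsFactors = FALSE)
  }
  onco_df <- df[df$has_oncogenic, , drop = FALSE]
  for (v in continuous) {
    x <- df[[v]]; ok <- !is.na(x)
    groups <- split(x[ok], df$group[ok])
    groups <- groups[vapply(groups, length, 0L) > 0L]
    if (length(groups) >= 2L && length(unique(x[ok])) > 1L) {
      kt <- kruskal_wallis(groups)
      add(v, "3-group", "kruskal_wallis", kt$statistic, kt$p_value, kt$n)
    } else add(v, "3-group", "kruskal_wallis", NA, NA, sum(ok),
               "skipped: single level or <2 groups")
    hh <- df[ok & df$group %in% c("HOMOGENEOUS", "HETEROGENEOUS"), , drop = FALSE]
    if (length(unique(hh$group)) == 2L && length(unique(hh[[v]])) > 1L) {
      rt <- rank_sum(hh[[v]][hh$group == "HOMOGENEOUS"],
                     hh[[v]][hh$group == "HETEROGENEOUS"])
      add(v, "homogeneous-vs-heterogeneous", "rank_sum", rt$statistic,
          rt$p_value, rt$n)
    }
    so <- onco_df[!is.na(onco_df[[v]]), , drop = FALSE]
    if (length(unique(so$shares_oncogenic)) == 2L &&
        length(unique(so[[v]])) > 1L) {
      rt <- rank_sum(so[[v]][so$shares_oncogenic],
                     so[[v]][!so$shares_oncogenic])
      add(v, "shared-vs-private-oncogenic", "rank_sum", rt$statistic,
          rt$p_value, rt$n)
    }
  }
  for (v in categorical) {
    x <- df[[v]]; ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L || length(unique(df$group[ok])) < 2L) {
      add(v, "3-group", "fisher_exact", NA, NA, sum(ok),
          "skipped: single level")
      next
    }
    tabx <- table(factor(x[ok]), factor(df$group[ok]))
    ft <- fisher_exact(as.matrix(tabx))
    add(v, "3-group", "fisher_exact", ft$statistic, ft$p_value, ft$n)
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Build a presence matrix from components
#'
#' Constructor for hand-built matrices (the usual route is
#' [presence_matrix()] from a status table).
#'
#' @param m Integer matrix (1 present, 0 absent, `NA` non-informative), rows
#'   named by variant key, columns by sample.
#' @param lesion_of Named character vector mapping each sample to its lesion.
#' @param af Optional matching allele-fraction matrix.
#' @param validation_only Optional logical per sample.
#' @param fallback Optional discovery-evidence matrix for `NA` cells.
#' @param patient_id Patient identifier.
#' @return An `mfhet_presence` object.
#' @export
as_presence_matrix <- function(m, lesion_of, af = NULL, validation_only = NULL,
                               fallback = NULL, patient_id = "P") {
  storage.mode(m) <- "integer"
  stopifnot(length(lesion_of) == ncol(m))
  if (is.null(rownames(m)) && nrow(m) > 0L)
    rownames(m) <- paste0("v", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- names(lesion_of) %||% paste0("s", seq_len(ncol(m)))
  if (is.null(af)) af <- matrix(NA_real_, nrow(m), ncol(m),
                                dimnames = dimnames(m))
  dimnames(af) <- dimnames(m)
  if (is.null(validation_only)) validation_only <- rep(FALSE, ncol(m))
  if (is.null(fallback)) fallback <- matrix(NA_integer_, nrow(m), ncol(m))
  dimnames(fallback) <- dimnames(m)
  structure(m, patient_id = patient_id, lesion_of = lesion_of,
            validation_only = stats::setNames(validation_only, names(lesion_of)),
            af = af, fallback = fallback,
            gene_of = stats::setNames(rownames(m), rownames(m)),
            class = c("mfhet_presence", class(m)))
}

#' Export / read a presence matrix
#'
#' Writes the heat-map matrix as a TSV whose cells are `oncogenic-present`,
#' `unknown-present`, `absent` or `no-assay`; two comment header lines carry
#' the lesion of each sample and whether the sample entered only at the
#' validation phase. The export re-parses to the identical matrix.
#'
#' @param m An [presence_matrix()].
#' @param oncogenicity An [classify_variants()] result, or `NULL`.
#' @param path Output path.
#' @export
write_presence_matrix <- function(m, oncogenicity = NULL, path) {
  onco_keys <- if (!is.null(oncogenicity))
    oncogenicity$key[oncogenicity$oncogenic] else character(0)
  cells <- matrix("no-assay", nrow = nrow(m), ncol = ncol(m))
  cells[!is.na(m) & m == 0L] <- "absent"
  present <- !is.na(m) & m == 1L
  onco_row <- rownames(m) %in% onco_keys
  cells[present] <- ifelse(onco_row[row(m)[present]],
                           "oncogenic-present", "unknown-present")
  con <- file(path, "w")
  writeLines(paste(c("#lesion", unname(attr(m, "lesion_of"))), collapse = "\t"), con)
  writeLines(paste(c("#validation_only",
                     unname(attr(m, "validation_only"))), collapse = "\t"), con)
  writeLines(paste(c("variant", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], cells[i, ]), collapse = "\t"), con)
  close(con)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @return `read_presence_matrix()` returns a list with `cells` (character
#'   matrix), `lesion_of` and `validation_only`.
#' @export
read_presence_matrix <- function(path) {
  lines <- readLines(path)
  lesion <- strsplit(lines[1L], "\t")[[1L]][-1L]
  val_only <- as.logical(strsplit(lines[2L], "\t")[[1L]][-1L])
  samples <- strsplit(lines[3L], "\t")[[1L]][-1L]
  body <- strsplit(lines[-(1:3)], "\t")
  keys <- vapply(body, `[`, "", 1L)
  cells <- t(vapply(body, function(x) x[-1L], character(length(samples))))
  if (length(keys) == 1L) cells <- matrix(cells, nrow = 1L)
  dimnames(cells) <- list(keys, samples)
  list(cells = cells, lesion_of = stats::setNames(lesion, samples),
       validation_only = stats::setNames(val_only, samples))
}

#' Heat-map plot of a presence matrix
#'
#' Base-graphics rendering of the published heat-map style: orange cells are
#' oncogenic mutations, grey cells mutations of unknown significance, white
#' absence; sample labels are greyed when the sample entered only at the
#' validation phase.
#'
#' @param x An [presence_matrix()].
#' @param oncogenicity An [classify_variants()] result, or `NULL`.
#' @param ... Ignored.
#' @export
plot.mfhet_presence <- function(x, oncogenicity = NULL, ...) {
  onco_keys <- if (!is.null(oncogenicity))
    oncogenicity$key[oncogenicity$oncogenic] else character(0)
  code <- matrix(0L, nrow(x), ncol(x))  # 0 absent/no-assay, 1 unknown, 2 oncogenic
  present <- !is.na(x) & x == 1L
  onco_row <- rownames(x) %in% onco_keys
  code[present] <- ifelse(onco_row[row(x)[present]], 2L, 1L)
  lab <- attr(x, "gene_of"); lab[is.na(lab)] <- rownames(x)[is.na(lab)]
  op <- graphics::par(mar = c(6, 8, 2, 1)); on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(x)), seq_len(nrow(x)), t(code[rev(seq_len(nrow(x))), , drop = FALSE]),
                  col = c("white", "grey60", "darkorange"), zlim = c(0, 2),
                  axes = FALSE, xlab = "", ylab = "",
                  main = attr(x, "patient_id"))
  graphics::axis(2, at = seq_len(nrow(x)), labels = rev(lab), las = 2, cex.axis = 0.8)
  col_lab <- ifelse(attr(x, "validation_only"), "grey50", "black")
  graphics::mtext(colnames(x), side = 1, at = seq_len(ncol(x)), las = 2,
                  col = col_lab, cex = 0.8, line = 0.5)
  graphics::box()
  invisible(x)
}
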