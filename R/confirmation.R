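#' Orthogonal-platform validation of somatic mutations
#'
#' Every mutation identified in at least one sample of a patient is
#' re-interrogated by deep resequencing in all samples of that patient. A call
#' is accepted when its validation allele fraction is at least
#' `af_confirm_min` (5%); calls in the rescue window (>= 1% but < 5%) are
#' accepted only when at least one *other* sample of the same patient carries
#' the same variant at >= 5%. Accepted calls that the discovery platform also
#' detected are `CONFIRMED`; accepted calls the discovery platform missed are
#' `PRESENT`. Below-window calls are `NOT_DETECTED`; failed or missing assays
#' are `ASSAY_FAILED` and make no status claim.
#'
#' @name confirmation
NULL

STATUS_LEVELS <- c("CONFIRMED", "PRESENT", "NOT_DETECTED", "ASSAY_FAILED")

#' Assign the validation status of one call
#'
#' @param call A single-row mutation-call data.frame.
#' @param patient_calls All calls of the same patient for the same variant key
#'   (the candidate row may be included; it is never used as its own rescue
#'   support).
#' @param config An [mfhet_config()].
#' @return A list with `status`, `af_validation`, `supporting_sample_id`
#'   (non-`NA` only when the rescue rule decided the status).
#' @export
assign_validation_status <- function(call, patient_calls, config = mfhet_config()) {
  stopifnot(nrow(call) == 1L)
  if (length(unique(variant_key(patient_calls))) > 1L ||
      variant_key(call) != variant_key(patient_calls)[1L])
    stop("contract violation: patient_calls must all share the candidate's variant key")
  if (any(patient_calls$patient_id != call$patient_id))
    stop("contract violation: patient_calls must be from the candidate's patient")
  af <- call$af_validation
  if (!isTRUE(call$assay_ok_validation) || is.na(af))
    return(list(status = "ASSAY_FAILED", af_validation = af,
                supporting_sample_id = NA_character_))
  detected_discovery <- !is.na(call$af_discovery) && call$af_discovery > 0
  accept_status <- if (detected_discovery) "CONFIRMED" else "PRESENT"
  if (af >= config$af_confirm_min)
    return(list(status = accept_status, af_validation = af,
                supporting_sample_id = NA_character_))
  if (af >= config$af_rescue_min) {
    sib <- patient_calls[patient_calls$sample_id != call$sample_id &
                           !is.na(patient_calls$af_validation) &
                           patient_calls$assay_ok_validation &
                           patient_calls$af_validation >= config$af_confirm_min, ,
                         drop = FALSE]
    if (nrow(sib)) {
      best <- sib$sample_id[order(-sib$af_validation, sib$sample_id)][1L]
      return(list(status = accept_status, af_validation = af,
                  supporting_sample_id = best))
    }
  }
  list(status = "NOT_DETECTED", af_validation = af,
       supporting_sample_id = NA_character_)
}

#' Confirm a whole cohort
#'
#' Applies [assign_validation_status()] to every (variant, sample) pair that
#' was interrogated at validation, including pairs the discovery platform
#' never called (the validation platform assays every patient mutation in
#' every sample of that patient). Silent variants are excluded.
#'
#' @param calls Merged mutation-call data.frame (see [combine_platforms()]).
#' @param hierarchy A `cohort_hierarchy`; all call samples must resolve.
#' @param config An [mfhet_config()].
#' @return An object of class `mfhet_confirmation`: a list with
#'   `status_table` (one row per (variant, sample) pair: `patient_id, key,
#'   gene_symbol, sample_id, status, af_discovery, af_validation,
#'   supporting_sample_id`) and `summary` (counts `n_assayed, n_confirmed,
#'   n_present_only, n_not_detected, n_assay_failed`; the counts partition the
#'   interrogated pairs).
#' @export
confirm_cohort <- function(calls, hierarchy, config = mfhet_config()) {
  suppressWarnings(check_sample_resolution(calls, hierarchy))
  calls <- calls[!(calls$variant_class %in% "silent"), , drop = FALSE]
  k <- variant_key(calls)
  pk <- paste(calls$patient_id, k, sep = "|")
  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    grp <- calls[pk == pk[i], , drop = FALSE]
    st <- assign_validation_status(calls[i, , drop = FALSE], grp, config)
    rows[[i]] <- data.frame(
      patient_id = calls$patient_id[i], key = k[i],
      gene_symbol = calls$gene_symbol[i], sample_id = calls$sample_id[i],
      status = st$status, af_discovery = calls$af_discovery[i],
      af_validation = calls$af_validation[i],
      supporting_sample_id = st$supporting_sample_id,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$patient_id, tab$key, tab$sample_id), , drop = FALSE]
  rownames(tab) <- NULL
  n <- function(s) sum(tab$status == s)
  summary <- list(n_assayed = nrow(tab),
                  n_confirmed = n("CONFIRMED"),
                  n_present_only = n("PRESENT"),
                  n_not_detected = n("NOT_DETECTED"),
                  n_assay_failed = n("ASSAY_FAILED"))
  structure(list(status_table = tab, summary = summary, config = config),
            class = "mfhet_confirmation")
}

#' @export
print.mfhet_confirmation <- function(x, ...) {
  s <- x$summary
  cat("mfhet cross-platform confirmation\n")
  cat(sprintf("  (variant, sample) pairs interrogated: %d\n", s$n_assayed))
  cat(sprintf("  confirmed: %d   present (validation-only): %d\n",
              s$n_confirmed, s$n_present_only))
  cat(sprintf("  not detected: %d   assay failed: %d\n",
              s$n_not_detected, s$n_assay_failed))
  invisible(x)
}

#' Cross-platform concordance of allele fractions
#'
#' Spearman rank correlation over (discovery AF, validation AF) pairs, and an
#' ROC analysis in which the positive label is validation status
#' `CONFIRMED`/`PRESENT` versus `NOT_DETECTED` (assay failures excluded) and
#' the score is the discovery AF (0 when the discovery platform made no call).
#' The AUC confidence interval is the DeLong asymptotic interval.
#'
#' @param status_table The `status_table` of an [confirm_cohort()] result.
#' @param confirmed_only If `TRUE`, restrict the correlation to
#'   `CONFIRMED`/`PRESENT` pairs.
#' @return A list with `spearman` (an `mfhet_test`), `n_pairs`, `roc_auc`,
#'   `auc_ci95` (length-2 vector) and `n_roc`.
#' @export
platform_concordance <- function(status_table, confirmed_only = FALSE) {
  tab <- status_table
  pairs <- tab[!is.na(tab$af_discovery) & !is.na(tab$af_validation), , drop = FALSE]
  if (confirmed_only)
    pairs <- pairs[pairs$status %in% c("CONFIRMED", "PRESENT"), , drop = FALSE]
  if (nrow(pairs) < 3L)
    stop("insufficient data: need >= 3 pairs with both allele fractions")
  sp <- spearman_rho(pairs$af_discovery, pairs$af_validation)
  roc_tab <- tab[tab$status != "ASSAY_FAILED", , drop = FALSE]
  label <- roc_tab$status %in% c("CONFIRMED", "PRESENT")
  score <- ifelse(is.na(roc_tab$af_discovery), 0, roc_tab$af_discovery)
  if (length(unique(label)) < 2L)
    stop("insufficient data: ROC needs both detected and undetected pairs")
  r <- pROC::roc(response = label, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  # ci.auc warns when the AUC is degenerate (exactly 1); the interval is
  # still well-defined for reporting
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  list(spearman = sp, n_pairs = nrow(pairs),
       roc_auc = as.numeric(pROC::auc(r)), auc_ci95 = ci[c(1L, 3L)],
       n_roc = nrow(roc_tab))
}
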