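#' @title Mutation-call tables
#' @description
#' Mutation calls are held in a plain data.frame with one row per
#' (variant, sample) observation and the columns
#' `patient_id, sample_id, gene_symbol, chrom, pos, ref_allele, alt_allele,
#' variant_class, protein_change, af_discovery, depth_discovery,
#' af_validation, depth_validation, assay_ok_validation`.
#' `variant_class` takes one of `missense, nonsense, frameshift_ins,
#' frameshift_del, inframe_ins, inframe_del, splice, silent`. Coordinates are
#' 1-based inclusive (VCF convention); alleles are left-normalised before any
#' variant-identity comparison, so variant identity is the genomic key
#' (chrom, pos, ref, alt) and the protein change is annotation only.
#' @name mutation_calls
NULL

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_ins", "frameshift_del",
                     "inframe_ins", "inframe_del", "splice", "silent")
NONSILENT_CLASSES <- setdiff(VARIANT_CLASSES, "silent")
SUBSTITUTION_CLASSES <- c("missense", "nonsense")
INDEL_CLASSES <- c("frameshift_ins", "frameshift_del", "inframe_ins", "inframe_del")

CALL_COLUMNS <- c("patient_id", "sample_id", "gene_symbol", "chrom", "pos",
                  "ref_allele", "alt_allele", "variant_class", "protein_change",
                  "af_discovery", "depth_discovery", "af_validation",
                  "depth_validation", "assay_ok_validation")

empty_calls <- function() {
  data.frame(patient_id = character(0), sample_id = character(0),
             gene_symbol = character(0), chrom = character(0),
             pos = integer(0), ref_allele = character(0),
             alt_allele = character(0), variant_class = character(0),
             protein_change = character(0), af_discovery = numeric(0),
             depth_discovery = integer(0), af_validation = numeric(0),
             depth_validation = integer(0), assay_ok_validation = logical(0),
             stringsAsFactors = FALSE)
}

#' Left-normalise an allele pair
#'
#' Trims the longest shared suffix, then the longest shared prefix, adjusting
#' the position, so that the same indel written with redundant padding on two
#' platforms compares equal. At least one base is kept on each allele
#' (empty-allele indels are kept anchored, as in VCF).
#'
#' @param pos 1-based position vector.
#' @param ref,alt Allele character vectors.
#' @return A list with normalised `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  for (i in seq_along(pos)) {
    r <- strsplit(ref[i], "")[[1]]; a <- strsplit(alt[i], "")[[1]]
    # trim shared suffix
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    # trim shared prefix
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]; a <- a[-1L]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Variant identity key
#'
#' @param calls A mutation-call data.frame (or any data.frame with `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`).
#' @return Character vector `chrom:pos:ref:alt` after allele normalisation.
#' @export
variant_key <- function(calls) {
  nz <- normalize_alleles(calls$pos, calls$ref_allele, calls$alt_allele)
  paste(calls$chrom, nz$pos, nz$ref, nz$alt, sep = ":")
}

validate_calls <- function(df, path = "<data>") {
  bad <- which(df$alt_allele == df$ref_allele)
  if (length(bad))
    stop("value error: alt equals ref at row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  for (afcol in c("af_discovery", "af_validation")) {
    af <- df[[afcol]]
    bad <- which(!is.na(af) & (af < 0 | af > 1))
    if (length(bad))
      stop("value error: ", afcol, " outside [0,1] at row(s) ",
           paste(bad, collapse = ", "), " of ", path)
    dpcol <- sub("af_", "depth_", afcol)
    bad <- which(!is.na(af) & is.na(df[[dpcol]]))
    if (length(bad))
      stop("value error: ", afcol, " present without ", dpcol, " at row(s) ",
           paste(bad, collapse = ", "), " of ", path)
  }
  bad <- which(!df$variant_class %in% VARIANT_CLASSES & !is.na(df$variant_class))
  if (length(bad))
    stop("value error: unknown variant_class at row(s) ",
         paste(bad, collapse = ", "), " of ", path)
  df
}

#' Read a per-sample somatic variant table
#'
#' Reads either a TSV with header columns
#' `patient, sample, gene, chrom, pos, ref, alt, variant_class,
#' protein_change, af, depth` (an `assay_ok` logical column is honoured for
#' validation tables) or a VCF 4.x file with per-sample `AD`/`DP` (or `AF`)
#' FORMAT fields. The platform tag decides whether the allele fraction and
#' depth populate the discovery or the validation slots.
#'
#' @param path Path to a TSV or VCF file (VCF recognised by extension `.vcf`
#'   or a `##fileformat=VCF` first line).
#' @param platform `"discovery"` or `"validation"`.
#' @param patient_of_sample Only for VCF input: named character vector mapping
#'   sample names to patient ids (VCF carries no patient column).
#' @return A mutation-call data.frame (see [mutation_calls]). Silent variants
#'   are retained here and filtered downstream.
#' @export
read_variant_table <- function(path, platform = c("discovery", "validation"),
                               patient_of_sample = NULL) {
  platform <- match.arg(platform)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    grepl("^##fileformat=VCF", readLines(path, n = 1L, warn = FALSE))
  if (is_vcf) return(read_variant_vcf(path, platform, patient_of_sample))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", colClasses = "character")
  required <- c("patient", "sample", "gene", "chrom", "pos", "ref", "alt", "af", "depth")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("format error: missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(empty_calls())
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "NA", "."), NA, x)))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("format error: non-integer pos at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  out <- data.frame(
    patient_id = df$patient, sample_id = df$sample, gene_symbol = df$gene,
    chrom = df$chrom, pos = pos,
    ref_allele = toupper(df$ref), alt_allele = toupper(df$alt),
    variant_class = if ("variant_class" %in% names(df)) df$variant_class else NA_character_,
    protein_change = if ("protein_change" %in% names(df))
      ifelse(df$protein_change %in% c("", "NA", "."), NA, df$protein_change) else NA_character_,
    af_discovery = NA_real_, depth_discovery = NA_integer_,
    af_validation = NA_real_, depth_validation = NA_integer_,
    assay_ok_validation = TRUE, stringsAsFactors = FALSE)
  af <- num_or_na(df$af); depth <- as.integer(round(num_or_na(df$depth)))
  if (platform == "discovery") {
    out$af_discovery <- af; out$depth_discovery <- depth
  } else {
    out$af_validation <- af; out$depth_validation <- depth
    if ("assay_ok" %in% names(df))
      out$assay_ok_validation <- toupper(df$assay_ok) %in% c("TRUE", "T", "1", "YES")
    out$assay_ok_validation <- out$assay_ok_validation & !is.na(af)
  }
  validate_calls(out, path)
}

read_variant_vcf <- function(path, platform, patient_of_sample) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1L,
                                     dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  samples <- colnames(v@gt)[-1L]
  if (is.null(patient_of_sample))
    stop("format error: VCF input requires patient_of_sample mapping")
  gene <- rep(NA_character_, n_var); vclass <- rep(NA_character_, n_var)
  pchg <- rep(NA_character_, n_var)
  info_field <- function(key) {
    m <- regmatches(v@fix[, "INFO"],
                    regexec(paste0("(?:^|;)", key, "=([^;]+)"),
                            v@fix[, "INFO"], perl = TRUE))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  gene <- info_field("GENE"); vclass <- info_field("CLASS"); pchg <- info_field("PCHG")
  safe_gt <- function(el, ...) {
    m <- tryCatch(vcfR::extract.gt(v, el, ...), error = function(e) NULL)
    if (is.null(m) || all(is.na(m))) NULL else m
  }
  ad <- safe_gt("AD")
  dp <- safe_gt("DP")
  afm <- safe_gt("AF", as.numeric = TRUE)
  rows <- list()
  for (j in seq_along(samples)) {
    s <- samples[j]
    depth <- if (!is.null(dp)) suppressWarnings(as.integer(dp[, s])) else NA_integer_
    if (!is.null(afm)) {
      af <- afm[, s]
    } else if (!is.null(ad)) {
      alt_n <- suppressWarnings(as.numeric(vapply(strsplit(ad[, s], ","),
                                                  function(x) x[2L], "")))
      af <- ifelse(depth > 0, alt_n / depth, NA_real_)
    } else stop("format error: VCF lacks both AF and AD FORMAT fields")
    keep <- !is.na(af)
    if (!any(keep)) next
    pid <- patient_of_sample[[s]]
    if (is.null(pid)) stop("integrity error: no patient mapping for VCF sample ", s)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid, sample_id = s, gene_symbol = gene[keep],
      chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref_allele = toupper(fix$REF[keep]), alt_allele = toupper(fix$ALT[keep]),
      variant_class = vclass[keep], protein_change = pchg[keep],
      af_discovery = NA_real_, depth_discovery = NA_integer_,
      af_validation = NA_real_, depth_validation = NA_integer_,
      assay_ok_validation = TRUE, stringsAsFactors = FALSE)
    k <- length(rows)
    if (platform == "discovery") {
      rows[[k]]$af_discovery <- af[keep]; rows[[k]]$depth_discovery <- depth[keep]
    } else {
      rows[[k]]$af_validation <- af[keep]; rows[[k]]$depth_validation <- depth[keep]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_calls()
  validate_calls(out, path)
}

#' Write a variant table
#'
#' Writes the TSV layout [read_variant_table()] reads; the round trip is
#' lossless for valid inputs.
#'
#' @param calls Mutation-call data.frame.
#' @param path Output path.
#' @param platform Which platform's AF/depth columns to serialise.
#' @export
write_variant_table <- function(calls, path, platform = c("discovery", "validation")) {
  platform <- match.arg(platform)
  df <- data.frame(
    patient = calls$patient_id, sample = calls$sample_id, gene = calls$gene_symbol,
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref_allele,
    alt = calls$alt_allele, variant_class = calls$variant_class,
    protein_change = calls$protein_change, stringsAsFactors = FALSE)
  if (platform == "discovery") {
    df$af <- calls$af_discovery; df$depth <- calls$depth_discovery
  } else {
    df$af <- calls$af_validation; df$depth <- calls$depth_validation
    df$assay_ok <- calls$assay_ok_validation
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge discovery and validation calls
#'
#' Joins two platform tables on (patient, sample, variant key). Pairs present
#' only at discovery keep a missing validation AF; pairs present only at
#' validation (samples added at the validation phase, or mutations the
#' discovery caller missed) keep a missing discovery AF.
#'
#' @param discovery,validation Mutation-call data.frames from the two
#'   platforms.
#' @return A single merged mutation-call data.frame.
#' @export
combine_platforms <- function(discovery, validation) {
  key <- function(df) paste(df$patient_id, df$sample_id, variant_key(df), sep = "|")
  dk <- key(discovery); vk <- key(validation)
  if (anyDuplicated(dk)) stop("integrity error: duplicate (sample, variant) rows in discovery table")
  if (anyDuplicated(vk)) stop("integrity error: duplicate (sample, variant) rows in validation table")
  merged <- discovery
  m <- match(dk, vk)
  merged$af_validation <- validation$af_validation[m]
  merged$depth_validation <- validation$depth_validation[m]
  merged$assay_ok_validation <- ifelse(is.na(m), FALSE, validation$assay_ok_validation[m])
  only_v <- validation[!(vk %in% dk), , drop = FALSE]
  anno_keep <- function(x, y) ifelse(is.na(x), y, x)
  out <- rbind(merged, only_v)
  # harmonise annotation (gene, class, protein change) across platforms by key
  pk <- paste(out$patient_id, variant_key(out), sep = "|")
  for (col in c("gene_symbol", "variant_class", "protein_change")) {
    ref_val <- tapply(out[[col]], pk, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) x[1L] else NA_character_
    })
    out[[col]] <- anno_keep(out[[col]], unname(ref_val[pk]))
  }
  rownames(out) <- NULL
  out
}

#' Per-patient unique variants
#'
#' Groups calls by normalised genomic key within patient, excluding silent
#' variants. Substitutions and indels are counted separately.
#'
#' @param calls Mutation-call data.frame.
#' @return A data.frame of class `mfhet_unique_variants` with one row per
#'   (patient, variant): `patient_id, key, gene_symbol, variant_class,
#'   protein_change, n_observations, sample_ids` plus attributes
#'   `n_nonsilent_calls`, `n_substitutions`, `n_indels` and
#'   `cohort_recurrence` (distinct patients per key across the cohort).
#' @export
unique_variants <- function(calls) {
  calls <- calls[!(calls$variant_class %in% "silent"), , drop = FALSE]
  if (nrow(calls) == 0L) {
    out <- data.frame(patient_id = character(0), key = character(0),
                      gene_symbol = character(0), variant_class = character(0),
                      protein_change = character(0), n_observations = integer(0),
                      sample_ids = character(0), stringsAsFactors = FALSE)
    attr(out, "n_nonsilent_calls") <- 0L
    attr(out, "n_substitutions") <- 0L
    attr(out, "n_indels") <- 0L
    attr(out, "cohort_recurrence") <- integer(0)
    class(out) <- c("mfhet_unique_variants", "data.frame")
    return(out)
  }
  k <- variant_key(calls)
  gene_by_key <- tapply(calls$gene_symbol, k, function(g) unique(g[!is.na(g)]))
  conflict <- names(gene_by_key)[vapply(gene_by_key, length, 0L) > 1L]
  if (length(conflict))
    stop("integrity error: conflicting gene_symbol for variant key(s): ",
         paste(conflict, collapse = ", "))
  pk <- paste(calls$patient_id, k, sep = "|")
  first <- !duplicated(pk)
  out <- data.frame(
    patient_id = calls$patient_id[first],
    key = k[first],
    gene_symbol = calls$gene_symbol[first],
    variant_class = calls$variant_class[first],
    protein_change = calls$protein_change[first],
    n_observations = as.integer(table(pk)[pk[first]]),
    sample_ids = vapply(pk[first], function(g)
      paste(sort(calls$sample_id[pk == g]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_nonsilent_calls") <- nrow(calls)
  attr(out, "n_substitutions") <- sum(out$variant_class %in% SUBSTITUTION_CLASSES, na.rm = TRUE)
  attr(out, "n_indels") <- sum(out$variant_class %in% INDEL_CLASSES, na.rm = TRUE)
  rec <- tapply(out$patient_id, out$key, function(p) length(unique(p)))
  attr(out, "cohort_recurrence") <- rec
  class(out) <- c("mfhet_unique_variants", "data.frame")
  out
}

#' Read a COSMIC-like recurrence table
#'
#' @param path TSV with columns `gene`, `protein_change`,
#'   `cosmic_confirmed_samples` and optionally a logical `in_cluster` column
#'   marking entries lying in a catalogue mutation cluster.
#' @return A data.frame with unique (gene, protein_change) rows.
#' @export
read_recurrence_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "protein_change", "cosmic_confirmed_samples")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("gene", "protein_change")]))
    stop("integrity error: duplicate (gene, protein_change) rows in recurrence table")
  df$cosmic_confirmed_samples <- as.integer(df$cosmic_confirmed_samples)
  if (any(df$cosmic_confirmed_samples < 0)) stop("value error: negative recurrence count")
  df
}

#' Read a gene-role table
#'
#' @param path TSV with columns `gene`, `role`; role is one of `oncogene`,
#'   `tumour_suppressor`, `other_cancer_gene`, `not_cancer_gene`. Genes absent
#'   from the table default to `not_cancer_gene` downstream.
#' @return A data.frame.
#' @export
read_gene_role_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  miss <- setdiff(c("gene", "role"), names(df))
  if (length(miss)) stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("integrity error: duplicate gene in role table")
  ok <- c("oncogene", "tumour_suppressor", "other_cancer_gene", "not_cancer_gene")
  if (any(!df$role %in% ok))
    stop("value error: unknown role(s): ", paste(setdiff(df$role, ok), collapse = ", "))
  df
}
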